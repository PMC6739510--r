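#' Cardiac cycle policy
#'
#' The per-beat schedule: stimulus frequency, the prescribed diastolic
#' refill in-flow and its trigger, and the end-diastolic length target.
#' Refill starts once the valve is closed and the active stress has fallen
#' below `refill_trigger_fraction` of the previous beat's peak, and stops
#' (clipped, never overshooting) when the muscle is back at
#' `end_diastolic_length`.
#'
#' @param stim_hz Stimulus frequency, Hz (1 and 5 Hz are the conventional
#'   room- and body-temperature rates).
#' @param refill_rate_uL_per_s Volume in-flow rate, uL/s. `NULL` (default)
#'   selects it automatically at simulation time as two resting chamber
#'   volumes per beat period, which restores even a near-complete ejection
#'   comfortably within diastole for all the protocols shipped here.
#' @param refill_trigger_fraction Active-stress fraction of the previous
#'   beat's peak below which refill may start. Default 0.05.
#' @param end_diastolic_length_mm Target length at refill completion, mm;
#'   `NULL` defaults to the muscle's optimal length at simulation time.
#' @return An object of class `cycle_policy`.
#' @export
cycle_policy <- function(stim_hz = 1, refill_rate_uL_per_s = NULL,
                         refill_trigger_fraction = 0.05,
                         end_diastolic_length_mm = NULL) {
  if (!is.finite(stim_hz) || stim_hz <= 0)
    abort("stim_hz must be positive", class = "wkloop_invalid_policy")
  if (!is.null(refill_rate_uL_per_s) &&
      (!is.finite(refill_rate_uL_per_s) || refill_rate_uL_per_s < 0))
    abort("refill_rate_uL_per_s must be non-negative",
          class = "wkloop_invalid_policy")
  if (!is.finite(refill_trigger_fraction) || refill_trigger_fraction < 0 ||
      refill_trigger_fraction > 1)
    abort("refill_trigger_fraction must be in [0, 1]",
          class = "wkloop_invalid_policy")
  structure(
    list(stim_hz = stim_hz,
         refill_rate = if (is.null(refill_rate_uL_per_s)) NULL
                       else refill_rate_uL_per_s * UL,
         refill_trigger_fraction = refill_trigger_fraction,
         end_diastolic_length = if (is.null(end_diastolic_length_mm)) NULL
                                else end_diastolic_length_mm * MM),
    class = "cycle_policy"
  )
}

#' Beat onset times
#'
#' `t_k = k / stim_hz` for `k = 0, 1, ...`, truncated strictly below
#' `duration`; the beat count is `floor(duration * stim_hz)` (up to
#' floating-point ties).
#'
#' @param policy A [cycle_policy()].
#' @param duration Run duration, s (> 0).
#' @return Numeric vector of onset times, s.
#' @export
stimulus_times <- function(policy, duration) {
  stopifnot(inherits(policy, "cycle_policy"))
  if (!is.finite(duration) || duration <= 0)
    abort("duration must be positive")
  n <- floor(duration * policy$stim_hz + 1e-9)
  k <- seq_len(n) - 1
  t <- k / policy$stim_hz
  t[t < duration]
}

#' Update the aortic valve state
#'
#' Hybrid-event logic for the ideal diode: a closed valve opens on strict
#' `P > Pa` (ties stay closed, avoiding zero-gradient chattering); an open
#' valve closes, with the flow snapping to zero, as soon as the algebraic
#' flow `(P - Pp)/Zc` is non-positive.
#'
#' @param P Ventricular pressure, Pa.
#' @param state A [wk_state()].
#' @param params A [windkessel_params()] (used for the open-valve flow).
#' @return The updated `wk_state`.
#' @export
update_valve <- function(P, state, params) {
  stopifnot(inherits(state, "wk_state"))
  if (!state$valve_open) {
    if (P > state$Pa)
      return(wk_state(Pp = state$Pp, valve_open = TRUE,
                      Q = wk_flow(P, state, params), params = params))
    return(state)
  }
  Q <- wk_flow(P, state, params)
  if (Q <= 0) return(wk_state(Pp = state$Pp, valve_open = FALSE))
  wk_state(Pp = state$Pp, valve_open = TRUE, Q = Q, params = params)
}

#' Diastolic refill increment
#'
#' Prescribed kinematic in-flow: while the valve is closed, the active
#' stress is below the trigger fraction of the previous beat's peak, and
#' the muscle is below its end-diastolic length, volume flows in at
#' `refill_rate`, clipped so the length never overshoots the target.
#'
#' @param V Current chamber volume, m^3.
#' @param active_stress Current active stress, Pa.
#' @param peak_stress_prev_beat Previous beat's peak active stress, Pa.
#' @param policy A [cycle_policy()] with `refill_rate` and
#'   `end_diastolic_length` resolved (non-NULL).
#' @param state A [wk_state()] (must be closed).
#' @param vgeom A [ventricle_geometry()].
#' @param dt Step, s.
#' @return Net inflow volume over the step, m^3.
#' @export
refill_step <- function(V, active_stress, peak_stress_prev_beat, policy,
                        state, vgeom, dt) {
  stopifnot(inherits(policy, "cycle_policy"), inherits(state, "wk_state"))
  if (state$valve_open)
    abort("refill must never occur while the valve is open",
          class = "wkloop_logic_error")
  if (is.null(policy$refill_rate) || is.null(policy$end_diastolic_length))
    abort("policy must have refill_rate and end_diastolic_length resolved")
  if (active_stress >= policy$refill_trigger_fraction * peak_stress_prev_beat)
    return(0)
  V_ED <- radius_to_volume(length_to_radius(policy$end_diastolic_length, vgeom))
  if (V >= V_ED) return(0)
  min(policy$refill_rate * dt, V_ED - V)
}
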