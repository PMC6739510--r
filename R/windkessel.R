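#' Three-element Windkessel parameters
#'
#' The arterial impedance triplet: peripheral resistance `Rp`, arterial
#' compliance `C`, and characteristic aortic impedance `Zc`. Arguments are
#' in the units conventional in the work-loop literature (and used in
#' configuration files); the returned object stores strict SI values.
#'
#' @param Rp_GPa_s_per_m3 Peripheral resistance, GPa s m^-3.
#' @param C_pm3_per_Pa Arterial compliance, pm^3 Pa^-1.
#' @param Zc_GPa_s_per_m3 Characteristic aortic impedance, GPa s m^-3.
#' @return An object of class `wk_params` with SI fields `Rp` (Pa s m^-3),
#'   `C` (m^3 Pa^-1), `Zc` (Pa s m^-3).
#' @examples
#' p <- windkessel_params(14.5, 32, 0.5)  # normotensive rat
#' wk_time_constant(p)                     # 0.464 s
#' @export
windkessel_params <- function(Rp_GPa_s_per_m3, C_pm3_per_Pa,
                              Zc_GPa_s_per_m3) {
  vals <- c(Rp = Rp_GPa_s_per_m3, C = C_pm3_per_Pa, Zc = Zc_GPa_s_per_m3)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad))
    abort(paste0("windkessel_params: non-positive or non-finite: ",
                 paste(names(vals)[bad], collapse = ", ")),
          class = "wkloop_invalid_params")
  if (Zc_GPa_s_per_m3 >= Rp_GPa_s_per_m3)
    warn("Zc >= Rp: characteristic impedance should be small relative to peripheral resistance")
  structure(
    list(Rp = Rp_GPa_s_per_m3 * GPA_S_M3,
         C = C_pm3_per_Pa * PM3_PA,
         Zc = Zc_GPa_s_per_m3 * GPA_S_M3),
    class = "wk_params"
  )
}

#' @export
print.wk_params <- function(x, ...) {
  cat(sprintf(
    "<wk_params> Rp = %.4g GPa s m^-3, C = %.4g pm^3 Pa^-1, Zc = %.4g GPa s m^-3 (tau = %.3g s)\n",
    x$Rp / GPA_S_M3, x$C / PM3_PA, x$Zc / GPA_S_M3, wk_time_constant(x)))
  invisible(x)
}

# registry of literature parameter sets; paper-unit triplets
.wk_presets <- list(
  normotensive = list(Rp = 14.5, C = 32, Zc = 0.5,
    note = "reference rat systemic circulation (body conditions)"),
  hypertensive = list(Rp = 21.4, C = 15, Zc = 0.76,
    note = "raised resistance / stiffened arteries disease load"),
  hypotensive = list(Rp = 9.18, C = 42, Zc = 0.31,
    note = "lowered resistance / compliant arteries disease load"),
  room_temp_base = list(Rp = 150, C = 32, Zc = 5,
    note = "base load for 1 Hz room-temperature work-loops")
)

#' Windkessel parameter presets
#'
#' Named literature parameter sets used throughout the simulated protocols.
#' `wk_preset()` returns one triplet as a [windkessel_params()] object;
#' `wk_presets()` lists the registry as a tibble (paper units).
#'
#' @param name One of `"normotensive"`, `"hypertensive"`, `"hypotensive"`,
#'   `"room_temp_base"`.
#' @return A `wk_params` object, or a tibble for `wk_presets()`.
#' @export
wk_preset <- function(name) {
  if (!is.character(name) || length(name) != 1 || !name %in% names(.wk_presets))
    abort(paste0("unknown preset '", paste(name, collapse = ","),
                 "'; available: ",
                 paste(names(.wk_presets), collapse = ", ")),
          class = "wkloop_unknown_preset")
  p <- .wk_presets[[name]]
  out <- windkessel_params(p$Rp, p$C, p$Zc)
  attr(out, "preset") <- name
  out
}

#' @rdname wk_preset
#' @export
wk_presets <- function() {
  purrr::map_dfr(names(.wk_presets), function(nm) {
    p <- .wk_presets[[nm]]
    tibble(preset = nm, Rp_GPa_s_per_m3 = p$Rp, C_pm3_per_Pa = p$C,
           Zc_GPa_s_per_m3 = p$Zc, tau_s = p$Rp * p$C * 1e-3,
           note = p$note)
  })
}

#' Windkessel state
#'
#' Instantaneous state of the arterial circuit: peripheral pressure `Pp`,
#' aortic pressure `Pa`, aortic flow `Q` and valve state. Invariants:
#' `Q >= 0`; valve closed implies `Q = 0` and `Pa = Pp`; valve open implies
#' `Pa = Pp + Q * Zc`.
#'
#' @param Pp Peripheral pressure, Pa.
#' @param valve_open Logical.
#' @param Q Aortic flow, m^3/s (only meaningful when open).
#' @param params A [windkessel_params()] (needed to place `Pa` when open).
#' @return An object of class `wk_state`.
#' @export
wk_state <- function(Pp = 0, valve_open = FALSE, Q = 0, params = NULL) {
  if (!is.finite(Pp) || Pp < 0)
    abort("Pp must be finite and non-negative", class = "wkloop_invalid_state")
  if (Q < 0) abort("Q must be non-negative", class = "wkloop_invalid_state")
  if (!valve_open && Q != 0)
    abort("closed valve requires Q = 0", class = "wkloop_invalid_state")
  Pa <- if (valve_open) {
    if (is.null(params)) abort("params needed to compute Pa for an open valve")
    Pp + Q * params$Zc
  } else Pp
  structure(list(Pp = Pp, Pa = Pa, Q = Q, valve_open = valve_open),
            class = "wk_state")
}

#' Input impedance of the 3-element Windkessel
#'
#' \eqn{Z(s) = Z_c + R_p / (1 + s R_p C)}. At `s = 0` this is `Rp + Zc`
#' (the DC resistance of the circuit); as `|s| -> Inf` it tends to `Zc`
#' (the compliance shorts the peripheral branch).
#'
#' @param params A [windkessel_params()].
#' @param s Complex (or real) frequency, rad/s; vectorised.
#' @return Complex impedance, Pa s m^-3.
#' @export
wk_input_impedance <- function(params, s) {
  stopifnot(inherits(params, "wk_params"))
  params$Zc + params$Rp / (1 + s * params$Rp * params$C)
}

#' Diastolic decay time constant
#'
#' With the valve closed the stored arterial pressure discharges through the
#' peripheral resistance, decaying exponentially with time constant
#' `Rp * C`.
#'
#' @param params A [windkessel_params()].
#' @return Time constant, s.
#' @export
wk_time_constant <- function(params) {
  stopifnot(inherits(params, "wk_params"))
  params$Rp * params$C
}

#' Advance the closed-valve (diastolic) state
#'
#' Exact exponential integrator of `dPp/dt = -Pp/(Rp C)`; with
#' `method = "trapezoidal"` the implicit-midpoint rule used on the
#' open-valve path is applied to the same decay ODE instead (useful for
#' verifying the discretisation error of the 50 us grid).
#'
#' @param state A [wk_state()] with the valve closed.
#' @param params A [windkessel_params()].
#' @param dt Step, s (> 0).
#' @param method `"exact"` (default) or `"trapezoidal"`.
#' @return The advanced `wk_state`.
#' @export
wk_step_closed <- function(state, params, dt,
                           method = c("exact", "trapezoidal")) {
  stopifnot(inherits(state, "wk_state"), inherits(params, "wk_params"))
  method <- match.arg(method)
  if (state$valve_open) abort("valve must be closed", class = "wkloop_invalid_step")
  if (!is.finite(dt) || dt <= 0)
    abort("dt must be positive", class = "wkloop_invalid_step")
  tau <- params$Rp * params$C
  Pp <- if (method == "exact") {
    state$Pp * exp(-dt / tau)
  } else {
    w <- dt / tau
    state$Pp * (1 - w / 2) / (1 + w / 2)
  }
  wk_state(Pp = Pp, valve_open = FALSE)
}

#' Advance the open-valve (ejection) state
#'
#' The flow is algebraic, `Q = (P - Pp)/Zc` (from `Pa = Pp + Q Zc` with the
#' ideal valve pinning `Pa = P`); `Pp` is advanced by
#' `C dPp/dt = Q - Pp/Rp` using the trapezoidal (implicit midpoint) rule
#' with the ventricular pressure `P` held constant over the step.
#'
#' @param state A [wk_state()] with the valve open.
#' @param P Ventricular pressure over the step, Pa.
#' @param params A [windkessel_params()].
#' @param dt Step, s (> 0).
#' @return The advanced `wk_state` (flow and `Pa` recomputed at the new
#'   `Pp`).
#' @export
wk_step_open <- function(state, P, params, dt) {
  stopifnot(inherits(state, "wk_state"), inherits(params, "wk_params"))
  if (!state$valve_open) abort("valve must be open", class = "wkloop_invalid_step")
  if (!is.finite(dt) || dt <= 0)
    abort("dt must be positive", class = "wkloop_invalid_step")
  if (params$Zc <= 0)
    abort("Zc must be positive (2-element behaviour: pass a small Zc explicitly)",
          class = "wkloop_division_guard")
  a <- P / (params$Zc * params$C)
  b <- (1 / params$Zc + 1 / params$Rp) / params$C
  Pp_new <- ((1 - b * dt / 2) * state$Pp + a * dt) / (1 + b * dt / 2)
  Q_new <- (P - Pp_new) / params$Zc
  if (Q_new <= 0) return(wk_state(Pp = Pp_new, valve_open = FALSE))
  wk_state(Pp = Pp_new, valve_open = TRUE, Q = Q_new, params = params)
}

#' Discrete-time Windkessel admittance
#'
#' Bilinear (Tustin) transform of the circuit admittance
#' \eqn{Y(s) = 1/Z(s) = (1 + s R_p C) / ((R_p + Z_c) + s R_p C Z_c)}
#' at sample interval `dt`. Applying the returned filter to a ventricular
#' pressure sequence yields the aortic flow sequence; the DC gain matches
#' `1/(Rp + Zc)` exactly and the single pole lies strictly inside the unit
#' circle for all valid parameters.
#'
#' @param params A [windkessel_params()].
#' @param dt Sample interval, s (default 50 us).
#' @return An object of class `wk_admittance`: coefficient vectors `b`
#'   (numerator) and `a` (denominator, leading coefficient 1), plus `dt`.
#' @export
discretize_admittance <- function(params, dt = 5e-5) {
  stopifnot(inherits(params, "wk_params"))
  if (!is.finite(dt) || dt <= 0) abort("dt must be positive")
  T_ <- params$Rp * params$C
  k <- 2 * T_ / dt
  b0 <- 1 + k
  b1 <- 1 - k
  a0 <- (params$Rp + params$Zc) + k * params$Zc
  a1 <- (params$Rp + params$Zc) - k * params$Zc
  structure(list(b = c(b0, b1) / a0, a = c(1, a1 / a0), dt = dt,
                 params = params),
            class = "wk_admittance")
}

#' Apply a discrete admittance filter to a pressure sequence
#'
#' @param adm A [discretize_admittance()] result.
#' @param P Numeric vector of ventricular pressures, Pa, sampled at
#'   `adm$dt`.
#' @return Flow sequence, m^3/s.
#' @export
apply_admittance <- function(adm, P) {
  stopifnot(inherits(adm, "wk_admittance"))
  as.numeric(signal::filter(adm$b, adm$a, P))
}

#' Instantaneous aortic flow through the open valve
#'
#' `Q = (P - Pp)/Zc`, the algebraic flow through the characteristic
#' impedance given ventricular pressure `P` and the current peripheral
#' pressure. Negative values indicate the valve should close.
#'
#' @param P Ventricular pressure, Pa.
#' @param state A [wk_state()].
#' @param params A [windkessel_params()].
#' @return Flow, m^3/s (may be negative; the valve logic clips it).
#' @export
wk_flow <- function(P, state, params) {
  stopifnot(inherits(state, "wk_state"), inherits(params, "wk_params"))
  (P - state$Pp) / params$Zc
}
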