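#' Synthesise a twitch-force trace
#'
#' Double-exponential waveform
#' \eqn{a (e^{-t/\tau_{fall}} - e^{-t/\tau_{rise}})}, scaled so its maximum
#' equals `peak`. This emulates the recorded isometric twitch used as the
#' prescribed force input in replay ("dry run") simulations; the default
#' amplitude of 3.5 mN corresponds to a trabecula of typical dimensions
#' (optimal length 1.8 mm, diameter 0.26 mm). The analytic time of the
#' maximum is `t* = tr tf/(tf - tr) log(tf/tr)`; when `t_rise == t_fall`
#' the limiting form `t exp(-t/tau)` is used.
#'
#' @param peak_mN Peak force, mN (>= 0).
#' @param t_rise,t_fall Rise and fall time constants, s (> 0).
#' @param period Beat period, s.
#' @param dt Sample interval, s.
#' @return A tibble of class `twitch_trace` with columns `time_s`,
#'   `force_N`, and attributes `peak` (N), `period`, `dt`.
#' @examples
#' tw <- synthesize_twitch(3.5, 0.03, 0.08, period = 1)
#' max(tw$force_N) * 1e3  # 3.5
#' @export
synthesize_twitch <- function(peak_mN = 3.5, t_rise = 0.03, t_fall = 0.08,
                              period = 1, dt = 5e-5) {
  if (!is.finite(peak_mN) || peak_mN < 0) abort("peak_mN must be >= 0")
  if (t_rise <= 0 || t_fall <= 0) abort("time constants must be positive")
  if (period <= dt) abort("period must exceed dt")
  tt <- seq(0, period - dt / 2, by = dt)
  peak <- peak_mN * MN
  if (abs(t_rise - t_fall) < 1e-12) {
    tau <- t_fall
    shape <- tt * exp(-tt / tau)
    smax <- tau * exp(-1)  # analytic max of t exp(-t/tau) at t = tau
  } else {
    shape <- exp(-tt / t_fall) - exp(-tt / t_rise)
    tstar <- t_rise * t_fall / (t_fall - t_rise) * log(t_fall / t_rise)
    smax <- exp(-tstar / t_fall) - exp(-tstar / t_rise)
  }
  f <- peak * shape / smax
  out <- tibble(time_s = tt, force_N = f)
  structure(out, peak = peak, period = period, dt = dt,
            class = c("twitch_trace", class(out)))
}

#' Evaluate a twitch trace at arbitrary times
#'
#' Linear interpolation within the beat; times outside `[0, period)` wrap
#' periodically. The replayed force is by construction independent of
#' muscle length and shortening velocity.
#'
#' @param t Times, s (vectorised).
#' @param trace A [synthesize_twitch()] result (or any `twitch_trace`).
#' @return Force, N.
#' @export
twitch_force <- function(t, trace) {
  stopifnot(inherits(trace, "twitch_trace"))
  period <- attr(trace, "period")
  tb <- t %% period
  # append the wrap-around point so interpolation covers [0, period)
  xs <- c(trace$time_s, period)
  ys <- c(trace$force_N, trace$force_N[1])
  approx(xs, ys, xout = tb, method = "linear", rule = 2)$y
}

#' Read / write twitch traces as two-column delimited text
#'
#' Plain text with a header line `time_s  force_N` (tab-separated), the
#' interchange format for recorded twitches.
#'
#' @param path File path.
#' @param trace A `twitch_trace` (for writing).
#' @param period Beat period, s; defaults to the trace span plus one
#'   sample interval.
#' @return A `twitch_trace` tibble (reading), or `path` invisibly.
#' @export
read_twitch_trace <- function(path, period = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    time_s = readr::col_double(), force_N = readr::col_double()))
  if (nrow(df) < 2) abort("twitch trace needs at least two samples")
  dt <- stats::median(diff(df$time_s))
  if (is.null(period)) period <- max(df$time_s) + dt
  out <- tibble(time_s = df$time_s, force_N = df$force_N)
  structure(out, peak = max(df$force_N), period = period, dt = dt,
            class = c("twitch_trace", class(out)))
}

#' @rdname read_twitch_trace
#' @export
write_twitch_trace <- function(trace, path) {
  stopifnot(inherits(trace, "twitch_trace"))
  readr::write_tsv(tibble(time_s = trace$time_s, force_N = trace$force_N),
                   path)
  invisible(path)
}

#' Hill-type muscle fixture parameters
#'
#' A deliberately simple active-muscle surrogate that lets the simulated
#' preparation adapt across beats when the load changes: total stress is
#' `activation * sigma_max * fl(L) * fv(v) + passive(L)` with a parabolic
#' force-length factor, a Hill hyperbola force-velocity factor (linearly
#' capped on the lengthening limb), an exponential passive curve, and a
#' normalised double-exponential activation drive. It is a fixture, not a
#' biophysical model: it has no memory beyond the Windkessel state, so
#' slow intrinsic restitution of living muscle is outside its scope.
#'
#' @param sigma_max_kPa Peak isometric active stress at `L0`, kPa. The
#'   default 66 kPa matches a 3.5 mN twitch in a 0.26 mm-diameter muscle.
#' @param fl_width Half-width of the force-length parabola, fraction of
#'   `L0`.
#' @param v_max_L0_per_s Maximum unloaded shortening velocity, optimal
#'   lengths per second.
#' @param a_curv Hill force-velocity curvature (a/F0).
#' @param passive_k_kPa,passive_beta Exponential passive-stress scale (kPa)
#'   and steepness.
#' @param slack_frac Passive slack length, fraction of `L0`.
#' @param t_rise,t_fall Activation rise/decay time constants, s.
#' @param fv_lengthening_cap Cap on the lengthening force-velocity factor
#'   (prevents unphysical force spikes during re-stretch).
#' @param temperature Convenience kinetics presets: `"body"` (37 C, fast
#'   kinetics compatible with 5 Hz pacing), `"warm"` (32 C), `"room"`
#'   (24 C, slow kinetics for 1 Hz). Overridden by explicit `t_rise` /
#'   `t_fall`.
#' @return An object of class `hill_params` (SI internally; stresses Pa).
#' @export
hill_params <- function(sigma_max_kPa = 66, fl_width = 0.35,
                        v_max_L0_per_s = 3, a_curv = 0.25,
                        passive_k_kPa = 0.25, passive_beta = 25,
                        slack_frac = 0.9, t_rise = NULL, t_fall = NULL,
                        fv_lengthening_cap = 1.1,
                        temperature = c("body", "warm", "room")) {
  temperature <- match.arg(temperature)
  kin <- switch(temperature,
                body = c(0.012, 0.035),
                warm = c(0.030, 0.090),
                room = c(0.055, 0.150))
  t_rise <- t_rise %||% kin[1]
  t_fall <- t_fall %||% kin[2]
  vals <- c(sigma_max_kPa = sigma_max_kPa, fl_width = fl_width,
            v_max_L0_per_s = v_max_L0_per_s, a_curv = a_curv,
            passive_beta = passive_beta, slack_frac = slack_frac,
            t_rise = t_rise, t_fall = t_fall,
            fv_lengthening_cap = fv_lengthening_cap)
  bad <- !is.finite(vals) | vals <= 0
  if (any(bad) || passive_k_kPa < 0)
    abort(paste0("hill_params: invalid: ",
                 paste(names(vals)[bad], collapse = ", ")),
          class = "wkloop_invalid_params")
  if (abs(t_rise - t_fall) < 1e-9)
    abort("t_rise and t_fall must differ (the activation drive is a double exponential)")
  structure(
    list(sigma_max = sigma_max_kPa * KPA, fl_width = fl_width,
         v_max_L0_per_s = v_max_L0_per_s, a_curv = a_curv,
         passive_k = passive_k_kPa * KPA, passive_beta = passive_beta,
         slack_frac = slack_frac, t_rise = t_rise, t_fall = t_fall,
         fv_cap = fv_lengthening_cap, temperature = temperature),
    class = "hill_params"
  )
}

# peak of the unnormalised double exponential, used to scale activation to 1
act_norm <- function(t_rise, t_fall) {
  tstar <- t_rise * t_fall / (t_fall - t_rise) * log(t_fall / t_rise)
  exp(-tstar / t_fall) - exp(-tstar / t_rise)
}

#' Activation drive of the Hill fixture
#'
#' Normalised double exponential, 0 at the stimulus, peak 1 at the analytic
#' argmax, decaying back towards 0 within the beat.
#'
#' @param t_in_beat Time since the beat onset, s (vectorised).
#' @param params A [hill_params()].
#' @return Activation in `[0, 1]`.
#' @export
hill_activation <- function(t_in_beat, params) {
  stopifnot(inherits(params, "hill_params"))
  a <- exp(-t_in_beat / params$t_fall) - exp(-t_in_beat / params$t_rise)
  pmax(a, 0) / act_norm(params$t_rise, params$t_fall)
}

#' Total stress of the Hill fixture
#'
#' `sigma = activation * sigma_max * fl(L) * fv(v) + passive(L)` with
#' `fl = max(0, 1 - ((L - L0)/(fl_width L0))^2)`,
#' `fv = (1 - v/v_max)/(1 + v/(a_curv v_max))` for shortening velocities
#' `0 <= v < v_max` (0 beyond), linearly capped at `fv_lengthening_cap`
#' for lengthening (`v < 0`), and
#' `passive = passive_k (exp(passive_beta (L - slack)/L0) - 1)` above the
#' slack length.
#'
#' @param L Muscle length, m (vectorised).
#' @param v Shortening velocity, m/s (positive = shortening).
#' @param activation Activation in `[0, 1]`.
#' @param params A [hill_params()].
#' @param geom A [trabecula_geometry()] (provides `L0`).
#' @return Total stress, Pa.
#' @export
hill_stress <- function(L, v, activation, params, geom) {
  stopifnot(inherits(params, "hill_params"),
            inherits(geom, "trabecula_geometry"))
  if (any(L <= 0)) abort("L must be positive", class = "wkloop_invalid_state")
  L0 <- geom$L0
  vmax <- params$v_max_L0_per_s * L0
  x <- (L - L0) / (params$fl_width * L0)
  fl <- pmax(0, 1 - x^2)
  fv <- ifelse(v >= 0,
               ifelse(v >= vmax, 0,
                      (1 - v / vmax) / (1 + v / (params$a_curv * vmax))),
               pmin(params$fv_cap,
                    1 + (params$fv_cap - 1) * (-v) / (0.1 * vmax)))
  slack <- params$slack_frac * L0
  pass <- ifelse(L > slack,
                 params$passive_k * expm1(params$passive_beta *
                                            (L - slack) / L0),
                 0)
  activation * params$sigma_max * fl * fv + pass
}

#' Peak isometric force of the Hill fixture at a given length
#'
#' Closed form: the activation drive peaks at 1, so the peak isometric
#' total force at length `L` is
#' `area * (sigma_max * fl(L) + passive(L))`. Used to place isotonic
#' afterloads within the developed force range.
#'
#' @param L Muscle length, m.
#' @param params A [hill_params()].
#' @param geom A [trabecula_geometry()].
#' @return Force, N.
#' @export
hill_peak_isometric_force <- function(L, params, geom) {
  geom$area * hill_stress(L, 0, 1, params, geom)
}
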