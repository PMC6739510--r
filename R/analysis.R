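#' Signed area of a closed sampled path (shoelace formula)
#'
#' The path is closed by joining the last sample back to the first. The
#' sign follows the traversal orientation (counter-clockwise positive); for
#' a work-loop traversed in time in the (length, force) plane the signed
#' area equals the mechanical work done by the muscle per cycle,
#' \eqn{-\oint F\,dL}.
#'
#' @param x,y Coordinates, at least 3 samples.
#' @return Signed area.
#' @examples
#' loop_area(c(0, 1, 1, 0), c(0, 0, 1, 1))  # unit square, ccw: +1
#' @export
loop_area <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3)
    abort("a closed path needs at least 3 samples",
          class = "wkloop_undefined_area")
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Per-beat work-loop and pressure-volume metrics
#'
#' `beat_metrics()` reduces one beat of a record to its loop metrics;
#' `beats_metrics()` maps over all analysed beats (burn-in dropped by
#' default). End-systole is the valve-closure sample of the beat's last
#' ejection (for isotonic records, the end of the shortening phase); beats
#' with no ejection are flagged isometric with zero work, shortening and
#' stroke volume.
#'
#' @param record A `wk_record`.
#' @param beat Beat number (as in `record$beat`).
#' @param discard_burn_in Drop burn-in beats first (default `TRUE`).
#' @return A tibble (one row per beat) with columns `beat`, `work_J`
#'   (\eqn{|\oint F\,dL|}), `stress_length_area_Pa_m` (\eqn{\oint\sigma\,dL},
#'   the figure-axis convention), `stroke_work_J` (\eqn{\oint P\,dV}),
#'   `peak_stress_Pa`, `end_systolic_stress_Pa`, `end_systolic_length_m`,
#'   `shortening_extent` ((L_ED - L_min)/L0), `stroke_volume_m3`,
#'   `fitted_tau_s` (diastolic aortic decay; `NA` for isotonic beats) and
#'   `isometric` flag.
#' @export
beat_metrics <- function(record, beat) {
  stopifnot(inherits(record, "wk_record"))
  sl <- record[record$beat == beat, , drop = FALSE]
  if (!nrow(sl)) abort(sprintf("no samples for beat %d", beat))
  config <- attr(record, "config")
  L0 <- config$geometry$L0
  mode <- attr(record, "mode")
  dt <- attr(record, "dt_log")

  ejecting <- if (mode == "isotonic") sl$phase == 1 else sl$valve_open
  iso <- !any(ejecting)
  L_ED <- sl$length_m[1]
  peak_stress <- max(sl$stress_Pa)

  if (iso) {
    return(tibble(
      beat = beat, work_J = 0, stress_length_area_Pa_m = 0,
      stroke_work_J = 0, peak_stress_Pa = peak_stress,
      end_systolic_stress_Pa = peak_stress, end_systolic_length_m = L_ED,
      shortening_extent = 0, stroke_volume_m3 = 0,
      fitted_tau_s = NA_real_, isometric = TRUE))
  }

  i_es <- max(which(ejecting))  # valve closure / end of shortening
  work <- abs(loop_area(sl$length_m, sl$force_N))
  sla <- abs(loop_area(sl$length_m, sl$stress_Pa))
  sw <- abs(loop_area(sl$V_m3, sl$P_Pa))
  sv <- sl$V_m3[1] - min(sl$V_m3)

  tau <- NA_real_
  if (mode != "isotonic") {
    dia <- sl[seq_len(nrow(sl)) > i_es & !sl$valve_open & !sl$refilling, ]
    if (nrow(dia) >= 10 && all(dia$Pa_Pa > 0)) {
      tau <- suppressWarnings(
        fit_diastolic_decay(dia$time_s, dia$Pa_Pa)$tau)
    }
  }

  tibble(
    beat = beat, work_J = work, stress_length_area_Pa_m = sla,
    stroke_work_J = sw, peak_stress_Pa = peak_stress,
    end_systolic_stress_Pa = sl$stress_Pa[i_es],
    end_systolic_length_m = sl$length_m[i_es],
    shortening_extent = (L_ED - min(sl$length_m)) / L0,
    stroke_volume_m3 = sv, fitted_tau_s = tau, isometric = FALSE)
}

#' @rdname beat_metrics
#' @export
beats_metrics <- function(record, discard_burn_in = TRUE) {
  stopifnot(inherits(record, "wk_record"))
  rec <- if (discard_burn_in) discard_burn_in(record) else record
  purrr::map_dfr(sort(unique(rec$beat)), function(b)
    beat_metrics(record, b))
}

#' Fit the diastolic aortic pressure decay
#'
#' Least-squares fit of `log(Pa)` against time over a closed-valve
#' interval; the decay constant is `tau = -1/slope`, which for the
#' 3-element Windkessel equals `Rp * C`. The fit is invariant to uniform
#' pressure rescaling and to time-origin shifts. A (numerically) constant
#' signal yields `tau = Inf` with `flag = "constant"`; a span shorter than
#' `0.2 * tau` keeps the best-effort estimate but warns and flags it.
#'
#' @param t Sample times, s (>= 10 samples).
#' @param Pa Aortic pressures, Pa (strictly positive).
#' @return An object of class `wk_decay_fit`: `tau` (s), `slope`,
#'   `log_P0`, `n`, `span_s`, `flag` (`"ok"`, `"constant"` or
#'   `"short_span"`), and the underlying `lm` fit.
#' @export
fit_diastolic_decay <- function(t, Pa) {
  if (length(t) != length(Pa)) abort("t and Pa must have equal length")
  if (length(t) < 10)
    abort("need at least 10 samples for a decay fit",
          class = "wkloop_insufficient_data")
  if (any(Pa <= 0))
    abort("pressures must be strictly positive for a log-linear fit",
          class = "wkloop_invalid_state")
  fit <- lm(log(Pa) ~ t)
  slope <- unname(coef(fit)[2])
  span <- max(t) - min(t)
  flag <- "ok"
  if (!is.finite(slope) || abs(slope) * span < 1e-12) {
    tau <- Inf
    flag <- "constant"
  } else {
    tau <- -1 / slope
    if (is.finite(tau) && tau > 0 && span < 0.2 * tau) {
      flag <- "short_span"
      warn(sprintf(
        "decay-fit span (%.3g s) is below 0.2 * fitted tau (%.3g s); best-effort estimate",
        span, tau))
    }
  }
  structure(list(tau = tau, slope = slope,
                 log_P0 = unname(coef(fit)[1]), n = length(t),
                 span_s = span, flag = flag, fit = fit),
            class = "wk_decay_fit")
}

#' @export
print.wk_decay_fit <- function(x, ...) {
  cat(sprintf("<wk_decay_fit> tau = %.4g s (n = %d, span = %.3g s, %s)\n",
              x$tau, x$n, x$span_s, x$flag))
  invisible(x)
}

#' @rdname fit_diastolic_decay
#' @param x A `wk_decay_fit`.
#' @param ... Unused.
#' @export
tidy.wk_decay_fit <- function(x, ...) {
  tibble(term = c("tau_s", "slope", "log_P0"),
         estimate = c(x$tau, x$slope, x$log_P0))
}

#' @rdname fit_diastolic_decay
#' @export
glance.wk_decay_fit <- function(x, ...) {
  r2 <- suppressWarnings(summary(x$fit)$r.squared)  # exact fits warn
  tibble(tau_s = x$tau, r.squared = r2,
         nobs = x$n, span_s = x$span_s, flag = x$flag)
}

#' Work vs end-systolic stress across loading modes
#'
#' Combines per-mode sweep metrics into the work-afterload relation and
#' (optionally, via [fit_work_afterload()]) the degree-2 polynomial fit
#' constrained through the origin used to summarise it: zero afterload and
#' the isometric limit both produce zero external work, with an interior
#' maximum between them.
#'
#' @param sweeps A named list of `wk_sweep` tibbles (names become the
#'   `mode` column), or a single sweep.
#' @return A tibble of class `work_afterload`, sorted by mode and
#'   end-systolic stress.
#' @export
work_afterload_table <- function(sweeps) {
  if (inherits(sweeps, "wk_sweep")) sweeps <- list(sweep = sweeps)
  out <- purrr::imap_dfr(sweeps, function(sw, nm)
    tibble(mode = nm, value = sw$value,
           end_systolic_stress_Pa = sw$end_systolic_stress_Pa,
           work_J = sw$work_J,
           stress_length_area_Pa_m = sw$stress_length_area_Pa_m,
           steady = sw$steady)) |>
    dplyr::arrange(.data$mode, .data$end_systolic_stress_Pa)
  structure(out, class = c("work_afterload", class(out)))
}

#' Origin-constrained quadratic fit of the work-afterload relation
#'
#' Per mode, fits `work = b1 * ess + b2 * ess^2` (no intercept, so the fit
#' passes exactly through the origin), mirroring the polynomial lines of
#' best fit conventionally drawn through work-afterload data.
#'
#' @param table A [work_afterload_table()] result.
#' @return An object of class `wk_workfit` with one `lm` per mode and a
#'   `predict` helper; `tidy()` returns the coefficients, `glance()` the
#'   per-mode fit summaries.
#' @export
fit_work_afterload <- function(table) {
  stopifnot(inherits(table, "work_afterload"))
  fits <- table |>
    dplyr::group_by(.data$mode) |>
    dplyr::group_map(function(df, key) {
      if (nrow(df) < 2)
        abort("need at least 2 entries per mode for the constrained fit")
      list(mode = key$mode[[1]],
           fit = lm(work_J ~ 0 + end_systolic_stress_Pa +
                      I(end_systolic_stress_Pa^2), data = df))
    })
  names(fits) <- purrr::map_chr(fits, "mode")
  structure(list(fits = fits, table = table), class = "wk_workfit")
}

#' Evaluate a fitted work-afterload curve
#'
#' @param object A `wk_workfit`.
#' @param ess End-systolic stresses, Pa.
#' @param mode Mode name (defaults to the first fitted mode).
#' @param ... Unused.
#' @return Predicted work, J (exactly 0 at `ess = 0`).
#' @export
predict.wk_workfit <- function(object, ess, mode = NULL, ...) {
  mode <- mode %||% names(object$fits)[1]
  if (!mode %in% names(object$fits))
    abort(paste0("no fit for mode '", mode, "'"))
  b <- coef(object$fits[[mode]]$fit)
  unname(b[1] * ess + b[2] * ess^2)
}

#' @rdname fit_work_afterload
#' @param x A `wk_workfit`.
#' @param ... Unused.
#' @export
tidy.wk_workfit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    b <- coef(f$fit)
    tibble(mode = nm, term = c("ess", "ess^2"), estimate = unname(b))
  })
}

#' @rdname fit_work_afterload
#' @export
glance.wk_workfit <- function(x, ...) {
  purrr::imap_dfr(x$fits, function(f, nm) {
    s <- summary(f$fit)
    tibble(mode = nm, r.squared = s$r.squared,
           nobs = length(f$fit$residuals))
  })
}

#' Windkessel energy audit over beats
#'
#' Discrete energy balance of the arterial circuit per beat: the hydraulic
#' energy delivered through the valve, \eqn{\int P Q\,dt}, must equal the
#' change in compliance storage \eqn{\Delta E_C = \tfrac12 C (P_p^2(end) -
#' P_p^2(start))} plus the dissipation in `Zc` and `Rp`. Integrals are
#' trapezoidal over the logged samples, so run with `decimation = 1` for
#' the tightest audit.
#'
#' @param record A Windkessel-mode `wk_record` (no interventions).
#' @param discard_burn_in Drop burn-in beats (default `TRUE`).
#' @return A tibble per beat: `E_in_J`, `dE_C_J`, `E_Zc_J`, `E_Rp_J`,
#'   `residual_J` and `residual_rel` (residual over `E_in_J`).
#' @export
energy_balance <- function(record, discard_burn_in = TRUE) {
  stopifnot(inherits(record, "wk_record"))
  if (attr(record, "mode") == "isotonic")
    abort("energy_balance() applies to Windkessel-loaded records")
  config <- attr(record, "config")
  if (length(config$interventions))
    abort("energy_balance() assumes constant Windkessel parameters")
  w <- config$windkessel
  rec <- if (discard_burn_in) discard_burn_in(record) else record
  trap <- function(t, y) sum(diff(t) * (utils::head(y, -1) + y[-1]) / 2)
  rec |>
    dplyr::group_by(.data$beat) |>
    dplyr::group_map(function(df, key) {
      E_in <- trap(df$time_s, df$P_Pa * df$Q_m3_s)
      E_Zc <- trap(df$time_s, df$Q_m3_s^2 * w$Zc)
      E_Rp <- trap(df$time_s, df$Pp_Pa^2 / w$Rp)
      dE_C <- 0.5 * w$C *
        (df$Pp_Pa[nrow(df)]^2 - df$Pp_Pa[1]^2)
      res <- E_in - (dE_C + E_Zc + E_Rp)
      tibble(beat = key$beat[[1]], E_in_J = E_in, dE_C_J = dE_C,
             E_Zc_J = E_Zc, E_Rp_J = E_Rp, residual_J = res,
             residual_rel = if (E_in > 0) abs(res) / E_in else NA_real_)
    }) |>
    dplyr::bind_rows()
}
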