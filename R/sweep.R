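#' Steady-state parameter sweep
#'
#' For each value of one Windkessel parameter (or of the isotonic
#' afterload), simulates until periodic steady state — beat-to-beat change
#' of both peak stress and shortening extent below `steady_tol` — and
#' collects the steady beat's work-loop metrics. The number of simulated
#' beats is scaled automatically with the arterial time constant `Rp C`
#' (the slowest state of the system) and capped at `max_beats`; a value
#' whose cap is reached is returned flagged (`steady = FALSE`), not an
#' error.
#'
#' @param config A [sim_config()] (its `n_beats`/`burn_in_beats` set the
#'   minimum run length).
#' @param param `"Rp"`, `"C"`, `"Zc"` (paper units) or `"afterload"` (mN,
#'   isotonic mode).
#' @param values Numeric vector of parameter values.
#' @param steady_tol Relative beat-to-beat tolerance, default 0.005.
#' @param max_beats Cap on simulated beats per value, default 300.
#' @return A tibble of class `wk_sweep`: one row per value with the steady
#'   beat's [beat_metrics()] columns, a `steady` flag, and the steady
#'   beat's record slice in the `record` list-column.
#' @export
run_sweep <- function(config, param, values, steady_tol = 0.005,
                      max_beats = 300) {
  stopifnot(inherits(config, "wk_config"))
  param <- match.arg(param, c("Rp", "C", "Zc", "afterload"))
  if (param == "afterload" && config$mode != "isotonic")
    abort("afterload sweeps require an isotonic-mode configuration",
          class = "wkloop_config_error")
  rows <- purrr::map(values, function(v) {
    cfg <- sweep_config(config, param, v, max_beats)
    rec <- simulate_workloop(cfg)
    met <- beats_metrics(rec)
    st <- steady_beat(met, config$geometry$L0, steady_tol)
    metrics <- met[met$beat == st$beat, ]
    slice <- dplyr::filter(as_tibble(rec), .data$beat == st$beat)
    dplyr::bind_cols(tibble(param = param, value = v, steady = st$steady),
                     metrics, tibble(record = list(slice)))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, config = config, param = param,
            class = c("wk_sweep", class(out)))
}

sweep_config <- function(config, param, value, max_beats) {
  cfg <- config
  if (param == "afterload") {
    cfg$afterload <- value * MN
  } else {
    w <- cfg$windkessel
    paper <- list(Rp = w$Rp / GPA_S_M3, C = w$C / PM3_PA, Zc = w$Zc / GPA_S_M3)
    paper[[param]] <- value
    cfg$windkessel <- suppressWarnings(
      windkessel_params(paper$Rp, paper$C, paper$Zc))
    # run long enough for the arterial state to converge: ~6 time constants
    tau <- wk_time_constant(cfg$windkessel)
    need <- ceiling(6 * tau * cfg$cycle$stim_hz) + 5
    cfg$n_beats <- min(max(cfg$n_beats, need), max_beats)
  }
  cfg
}

# first analysed beat whose peak stress and shortening extent have both
# settled relative to the previous beat
steady_beat <- function(metrics, L0, tol) {
  if (nrow(metrics) < 2)
    return(list(beat = metrics$beat[nrow(metrics)], steady = FALSE))
  pk <- metrics$peak_stress_Pa
  dL <- metrics$shortening_extent * L0
  for (i in 2:nrow(metrics)) {
    d_pk <- abs(pk[i] - pk[i - 1]) / max(pk[i], 1e-12)
    d_dL <- abs(dL[i] - dL[i - 1]) / max(dL[i], 1e-3 * L0)
    if (d_pk < tol && d_dL < tol)
      return(list(beat = metrics$beat[i], steady = TRUE))
  }
  list(beat = metrics$beat[nrow(metrics)], steady = FALSE)
}

#' Abrupt parameter-step protocol
#'
#' Convenience wrapper for the transient-adaptation experiment: run at a
#' low parameter value, then step it abruptly (during the diastole after
#' `step_after_beats` analysed beats, by default) to a high value, and
#' record per-beat metrics across the transient to the new steady state.
#'
#' @param config A Windkessel-mode [sim_config()].
#' @param param `"Rp"`, `"C"` or `"Zc"`.
#' @param from,to Initial and stepped values (paper units).
#' @param step_after_beats Analysed beats before the step (the step time is
#'   the end of that beat; deferral to diastole places it correctly).
#' @param beats_after Beats simulated after the step.
#' @param defer_to_diastole Logical, default `TRUE`.
#' @return A list with the full `wk_record` (`record`), the per-beat
#'   metrics tibble (`metrics`, with `post_step` flag), and the time the
#'   step was applied (`step_applied_s`).
#' @export
run_step_experiment <- function(config, param = "Rp", from = 50, to = 500,
                                step_after_beats = 6, beats_after = 60,
                                defer_to_diastole = TRUE) {
  stopifnot(inherits(config, "wk_config"))
  param <- match.arg(param, c("Rp", "C", "Zc"))
  cfg <- config
  w <- cfg$windkessel
  paper <- list(Rp = w$Rp / GPA_S_M3, C = w$C / PM3_PA, Zc = w$Zc / GPA_S_M3)
  paper[[param]] <- from
  cfg$windkessel <- suppressWarnings(
    windkessel_params(paper$Rp, paper$C, paper$Zc))
  period <- 1 / cfg$cycle$stim_hz
  t_step <- (cfg$burn_in_beats + step_after_beats - 0.5) * period
  cfg$n_beats <- step_after_beats + beats_after
  cfg$interventions <- c(cfg$interventions,
                         list(intervention(t_step, param, to,
                                           defer_to_diastole)))
  rec <- simulate_workloop(cfg)
  met <- beats_metrics(rec)
  applied <- attr(rec, "interventions_applied_s")
  applied <- applied[length(applied)]
  met$post_step <- (met$beat - cfg$burn_in_beats) > step_after_beats
  list(record = rec, metrics = met, step_applied_s = applied)
}

#' Windkessel vs isotonic work-afterload comparison
#'
#' Runs the two loading protocols on the same Hill-fixture muscle: a
#' peripheral-resistance sweep under the Windkessel load and a
#' constant-afterload sweep under the flat-topped isotonic controller,
#' returning the combined work vs end-systolic-stress table (see
#' [work_afterload_table()]).
#'
#' @param config A Windkessel-mode [sim_config()] with a Hill muscle.
#' @param rp_values Peripheral resistances to sweep, GPa s m^-3.
#' @param afterloads_mN Isotonic afterloads, mN; `NULL` spaces six values
#'   between the passive and peak isometric force.
#' @param ... Passed to [run_sweep()].
#' @return A `work_afterload` tibble with a `mode` column
#'   (`"windkessel"` / `"isotonic"`).
#' @export
compare_modes <- function(config, rp_values, afterloads_mN = NULL, ...) {
  stopifnot(inherits(config, "wk_config"))
  if (config$muscle$mode != "hill")
    abort("compare_modes() needs the Hill muscle fixture",
          class = "wkloop_config_error")
  wk <- run_sweep(config, "Rp", rp_values, ...)
  iso_cfg <- config
  iso_cfg$mode <- "isotonic"
  iso_cfg$afterload <- 1 * MN  # placeholder; swept below
  if (is.null(afterloads_mN)) {
    cfg_r <- resolve_config(config)
    geom <- config$geometry
    p <- config$muscle$params
    L_ED <- cfg_r$cycle$end_diastolic_length
    F_pass <- geom$area * hill_stress(L_ED, 0, 0, p, geom)
    F_peak <- hill_peak_isometric_force(L_ED, p, geom)
    afterloads_mN <- seq(F_pass + 0.06 * (F_peak - F_pass),
                         F_pass + 0.97 * (F_peak - F_pass),
                         length.out = 6) / MN
  }
  iso <- run_sweep(iso_cfg, "afterload", afterloads_mN, ...)
  work_afterload_table(list(windkessel = wk, isotonic = iso))
}
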