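#' Run the coupled muscle-Windkessel simulation
#'
#' Advances the full hybrid system on a fixed grid (default 50 us, i.e. the
#' 20 kHz control-loop rate): per step, (1) muscle force from the active
#' mode, (2) wall stress and ventricular pressure via the Laplace sphere,
#' (3) valve event logic, (4) Windkessel flow/pressure update, (5) diastolic
#' refill inflow, (6) volume and length update, (7) logging. The engine is
#' fully deterministic: identical configurations give bit-identical output.
#'
#' @param config A [sim_config()].
#' @return A tibble of class `wk_record` with columns `time_s`, `force_N`,
#'   `stress_Pa`, `length_m`, `P_Pa` (ventricular), `Pa_Pa` (aortic),
#'   `Pp_Pa` (peripheral), `Q_m3_s`, `V_m3`, `valve_open`, `refilling`,
#'   `beat` (1-based; the first `burn_in_beats` are the settling beats) and,
#'   in isotonic mode, `phase`. Attributes: `config`, `mode`, `dt_log`,
#'   `burn_in_beats`, `interventions_applied_s`.
#' @examples
#' \donttest{
#' rec <- simulate_workloop(sim_config(n_beats = 2, burn_in_beats = 3))
#' beat_metrics(rec, beat = max(rec$beat))
#' }
#' @export
simulate_workloop <- function(config) {
  stopifnot(inherits(config, "wk_config"))
  cfg <- resolve_config(config)
  if (cfg$mode == "isotonic") return(simulate_isotonic_run(cfg, config))

  geom <- cfg$geometry; vgeom <- cfg$ventricle
  spb <- round(cfg$period / cfg$dt)
  n_steps <- spb * cfg$total_beats

  core <- list(
    dt = cfg$dt, n_steps = as.double(n_steps),
    decim = as.integer(cfg$decimation),
    mode = if (cfg$mode == "isometric") 1L else 0L,
    area = geom$area, r_ref = vgeom$r_ref, h = vgeom$h,
    L_ref = vgeom$L_ref, L0 = geom$L0,
    Rp = cfg$windkessel$Rp, C = cfg$windkessel$C, Zc = cfg$windkessel$Zc,
    period = cfg$period,
    refill_rate = cfg$cycle$refill_rate,
    trigger_frac = cfg$cycle$refill_trigger_fraction,
    L_ED = cfg$cycle$end_diastolic_length,
    Pp0 = cfg$Pp0, L_init = cfg$L_init)

  if (cfg$muscle$mode == "replay") {
    core$muscle <- 0L
    core$trace <- replay_trace_samples(cfg, spb)
    core$trace_mid <- replay_trace_samples(cfg, spb, offset = 0.5)
  } else {
    core$muscle <- 1L
    core <- c(core, hill_core_pars(cfg$muscle$params, geom))
  }

  iv <- expand_interventions(cfg$interventions, cfg$windkessel)
  core$iv_time <- iv$time; core$iv_which <- iv$which
  core$iv_value <- iv$value; core$iv_defer <- iv$defer

  res <- sim_core(core)
  m <- res$log
  out <- tibble(
    time_s = m[, 1], force_N = m[, 2], stress_Pa = m[, 3],
    length_m = m[, 4], P_Pa = m[, 5], Pa_Pa = m[, 6], Pp_Pa = m[, 7],
    Q_m3_s = m[, 8], V_m3 = m[, 9], valve_open = m[, 10] > 0.5,
    refilling = m[, 11] > 0.5, beat = as.integer(m[, 12]) + 1L)
  new_wk_record(out, config, cfg, res$iv_applied)
}

# uniform per-beat force samples for the replay engine (length = steps/beat);
# offset = 0.5 gives the midpoint samples used to centre the Pp drive
replay_trace_samples <- function(cfg, spb, offset = 0) {
  mus <- cfg$muscle
  tw <- mus$twitch %||% synthesize_twitch(
    peak_mN = mus$peak_mN, t_rise = mus$t_rise, t_fall = mus$t_fall,
    period = cfg$period, dt = cfg$dt)
  if (abs(attr(tw, "period") - cfg$period) > 1e-9)
    abort(sprintf(
      "twitch trace period (%g s) does not match the beat period (%g s)",
      attr(tw, "period"), cfg$period), class = "wkloop_config_error")
  twitch_force(seq(offset * cfg$dt, by = cfg$dt, length.out = spb), tw)
}

hill_core_pars <- function(p, geom) {
  list(sigma_max = p$sigma_max, fl_width = p$fl_width,
       v_max = p$v_max_L0_per_s * geom$L0, a_curv = p$a_curv,
       passive_k = p$passive_k, passive_beta = p$passive_beta,
       slack = p$slack_frac * geom$L0, t_rise = p$t_rise,
       t_fall = p$t_fall, act_norm = act_norm(p$t_rise, p$t_fall),
       fv_cap = p$fv_cap)
}

# flatten interventions to parallel vectors; preset swaps expand to three
# simultaneous single-parameter changes (applied in the same step, hence
# atomically)
expand_interventions <- function(ivs, params) {
  time <- numeric(); which <- integer(); value <- numeric(); defer <- logical()
  for (iv in ivs) {
    if (iv$param == "preset") {
      p <- .wk_presets[[iv$value]]
      time <- c(time, rep(iv$time_s, 3))
      which <- c(which, 0L, 1L, 2L)
      value <- c(value, p$Rp * GPA_S_M3, p$C * PM3_PA, p$Zc * GPA_S_M3)
      defer <- c(defer, rep(iv$defer_to_diastole, 3))
    } else {
      time <- c(time, iv$time_s)
      which <- c(which, match(iv$param, c("Rp", "C", "Zc")) - 1L)
      value <- c(value, iv$value * switch(iv$param, Rp = GPA_S_M3,
                                          C = PM3_PA, Zc = GPA_S_M3))
      defer <- c(defer, iv$defer_to_diastole)
    }
  }
  list(time = time, which = which, value = value, defer = defer)
}

simulate_isotonic_run <- function(cfg, config) {
  geom <- cfg$geometry; vgeom <- cfg$ventricle
  p <- cfg$muscle$params
  F_pass <- geom$area *
    hill_stress(cfg$cycle$end_diastolic_length, 0, 0, p, geom)
  F_peak <- hill_peak_isometric_force(cfg$cycle$end_diastolic_length, p, geom)
  if (cfg$afterload <= F_pass)
    abort(sprintf(
      "afterload (%.3g mN) must exceed the passive force at end-diastolic length (%.3g mN)",
      cfg$afterload / MN, F_pass / MN), class = "wkloop_config_error")
  flagged <- cfg$afterload > F_peak
  if (flagged)
    warn(sprintf(
      "afterload (%.3g mN) exceeds peak isometric force (%.3g mN): beats will remain fully isometric",
      cfg$afterload / MN, F_peak / MN))

  spb <- round(cfg$period / cfg$dt)
  core <- c(
    list(dt = cfg$dt, n_steps = as.double(spb * cfg$total_beats),
         decim = as.integer(cfg$decimation), area = geom$area,
         L0 = geom$L0, period = cfg$period,
         trigger_frac = cfg$cycle$refill_trigger_fraction,
         L_ED = cfg$cycle$end_diastolic_length,
         afterload = cfg$afterload, relength_frac = 0.7,
         L_init = cfg$L_init),
    hill_core_pars(p, geom))
  res <- isotonic_core(core)
  m <- res$log
  L <- m[, 4]
  r <- length_to_radius(L, vgeom)
  out <- tibble(
    time_s = m[, 1], force_N = m[, 2], stress_Pa = m[, 3], length_m = L,
    P_Pa = stress_to_pressure(m[, 3], vgeom, r),
    Pa_Pa = NA_real_, Pp_Pa = NA_real_, Q_m3_s = NA_real_,
    V_m3 = radius_to_volume(r),
    valve_open = FALSE, refilling = m[, 5] == 3,
    beat = as.integer(m[, 6]) + 1L, phase = as.integer(m[, 5]))
  rec <- new_wk_record(out, config, cfg, numeric())
  attr(rec, "isometric_flagged") <- flagged
  rec
}

new_wk_record <- function(out, config, cfg, iv_applied) {
  structure(out,
            config = config, mode = cfg$mode,
            dt_log = cfg$dt * cfg$decimation,
            burn_in_beats = cfg$burn_in_beats,
            interventions_applied_s = iv_applied,
            class = c("wk_record", class(out)))
}

#' @export
print.wk_record <- function(x, ...) {
  cat(sprintf("<wk_record> mode = %s, %d samples, %d beats (%d burn-in), logged at %g kHz\n",
              attr(x, "mode"), nrow(x), max(x$beat),
              attr(x, "burn_in_beats"), 1e-3 / attr(x, "dt_log")))
  NextMethod()
}

#' Drop the burn-in beats from a record
#'
#' @param record A `wk_record`.
#' @return The record restricted to analysed beats.
#' @export
discard_burn_in <- function(record) {
  b <- attr(record, "burn_in_beats")
  out <- dplyr::filter(record, .data$beat > b)
  attrs <- attributes(record)
  for (a in c("config", "mode", "dt_log", "burn_in_beats",
              "interventions_applied_s"))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(record)
  out
}

#' Label the cardiac-cycle phase of every sample
#'
#' For Windkessel-loaded records, classifies each sample from the valve and
#' refill flags: `"isovolumic_rise"` (valve closed, before the beat's first
#' ejection), `"ejection"` (valve open), `"isovolumic_relaxation"` (closed,
#' after ejection, not refilling) and `"refill"`. Beats with no ejection
#' are labelled `"isometric"` throughout.
#'
#' @param record A `wk_record` from a Windkessel-mode run.
#' @return The record with an added `phase` character column.
#' @export
classify_phases <- function(record) {
  stopifnot(inherits(record, "wk_record"))
  out <- as_tibble(record) |>
    dplyr::group_by(.data$beat) |>
    dplyr::mutate(
      ever_open_ = cumsum(.data$valve_open) > 0,
      post_ej_ = rev(cumsum(rev(.data$valve_open))) == 0 & .data$ever_open_,
      phase = dplyr::case_when(
        !any(.data$valve_open) ~ "isometric",
        .data$valve_open ~ "ejection",
        .data$refilling ~ "refill",
        .data$post_ej_ ~ "isovolumic_relaxation",
        TRUE ~ "isovolumic_rise")) |>
    dplyr::ungroup() |>
    dplyr::select(-"ever_open_", -"post_ej_")
  attrs <- attributes(record)
  for (a in c("config", "mode", "dt_log", "burn_in_beats",
              "interventions_applied_s"))
    attr(out, a) <- attrs[[a]]
  class(out) <- class(record)
  out
}

#' Write a time-series record as CSV
#'
#' One header line naming columns and SI units, decimated as configured;
#' pair with [write_run_metadata()] for a reproducible run bundle.
#'
#' @param record A `wk_record`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_record_csv <- function(record, path) {
  readr::write_csv(as_tibble(record), path)
  invisible(path)
}
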