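#' Muscle blocks for a simulation configuration
#'
#' `replay_muscle()` prescribes the force: a recorded (or synthesised)
#' isometric twitch is replayed identically every beat, invariant with
#' shortening — the "dry run" validation mode. `hill_muscle()` supplies the
#' closed-loop Hill fixture whose force responds to length and velocity,
#' enabling adaptation across beats when the load changes.
#'
#' @param twitch A `twitch_trace` to replay, or `NULL` to synthesise one at
#'   simulation time from the remaining arguments.
#' @param peak_mN,t_rise,t_fall Synthesised twitch amplitude (mN) and time
#'   constants (s).
#' @param params A [hill_params()].
#' @return A muscle block (list) for [sim_config()].
#' @export
replay_muscle <- function(twitch = NULL, peak_mN = 3.5, t_rise = 0.03,
                          t_fall = 0.08) {
  if (!is.null(twitch) && !inherits(twitch, "twitch_trace"))
    abort("`twitch` must be a twitch_trace (see synthesize_twitch())")
  structure(list(mode = "replay", twitch = twitch, peak_mN = peak_mN,
                 t_rise = t_rise, t_fall = t_fall),
            class = "wk_muscle_block")
}

#' @rdname replay_muscle
#' @export
hill_muscle <- function(params = hill_params()) {
  stopifnot(inherits(params, "hill_params"))
  structure(list(mode = "hill", params = params),
            class = "wk_muscle_block")
}

.iv_params <- c("Rp", "C", "Zc", "preset")

#' Mid-run parameter intervention
#'
#' An abrupt change of one Windkessel parameter (or a whole preset swap,
#' applied atomically) at a given time. By default the change is deferred
#' to the next diastole, matching how such steps are applied between beats
#' in experiments; `defer_to_diastole = FALSE` applies it immediately.
#'
#' @param time_s Time at (or after) which the change takes effect, s.
#' @param param `"Rp"`, `"C"`, `"Zc"`, or `"preset"`.
#' @param value New value in paper units (GPa s m^-3 for resistances,
#'   pm^3 Pa^-1 for compliance), or a preset name when `param = "preset"`.
#' @param defer_to_diastole Logical, default `TRUE`.
#' @return An intervention (list) for [sim_config()].
#' @export
intervention <- function(time_s, param, value, defer_to_diastole = TRUE) {
  if (!param %in% .iv_params)
    abort(paste0("unknown intervention parameter '", param, "'; one of: ",
                 paste(.iv_params, collapse = ", ")),
          class = "wkloop_config_error")
  if (param == "preset") {
    if (!value %in% names(.wk_presets))
      abort(paste0("unknown preset '", value, "'"),
            class = "wkloop_config_error")
  } else if (!is.numeric(value) || !is.finite(value) || value <= 0) {
    abort("intervention value must be a positive number",
          class = "wkloop_config_error")
  }
  if (!is.finite(time_s) || time_s < 0)
    abort("intervention time must be non-negative",
          class = "wkloop_config_error")
  list(time_s = time_s, param = param, value = value,
       defer_to_diastole = isTRUE(defer_to_diastole))
}

#' Simulation configuration
#'
#' Assembles the geometry, Windkessel, cycle and muscle blocks plus engine
#' settings into a validated run configuration. Defaults reproduce the
#' replay-mode validation setup: a 3.5 mN twitch in a 1.8 mm x 0.26 mm
#' trabecula loaded by the normotensive Windkessel through a 5 mm /
#' 0.25 mm-wall spherical ventricle, stepped at 50 us with ten discarded
#' burn-in beats.
#'
#' @param mode `"windkessel"` (closed-loop impedance load), `"isometric"`
#'   (length clamped), or `"isotonic"` (flat-topped work-loop controller;
#'   requires a Hill muscle and `afterload_mN`).
#' @param geometry A [trabecula_geometry()].
#' @param ventricle A [ventricle_geometry()]; `NULL` uses the defaults with
#'   `L_ref = L0`.
#' @param windkessel A [windkessel_params()] or preset name.
#' @param cycle A [cycle_policy()].
#' @param muscle A [replay_muscle()] or [hill_muscle()] block.
#' @param n_beats Analysed beats after burn-in.
#' @param burn_in_beats Discarded initial beats (the arterial state charges
#'   from `Pp0` towards its periodic regime during these).
#' @param dt Engine step, s (default 50 us; the beat period must be an
#'   integer multiple of `dt`).
#' @param decimation Logging decimation factor (default 10, i.e. 2 kHz).
#' @param Pp0_kPa Initial peripheral pressure, kPa (default 5, a typical
#'   diastolic aortic pressure; burn-in erases the choice).
#' @param L_init_mm Initial muscle length, mm; `NULL` = end-diastolic
#'   length.
#' @param afterload_mN Isotonic afterload, mN (isotonic mode only).
#' @param interventions List of [intervention()]s.
#' @return An object of class `wk_config`.
#' @export
sim_config <- function(mode = c("windkessel", "isometric", "isotonic"),
                       geometry = trabecula_geometry(),
                       ventricle = NULL,
                       windkessel = wk_preset("normotensive"),
                       cycle = cycle_policy(),
                       muscle = replay_muscle(),
                       n_beats = 10, burn_in_beats = 10,
                       dt = 5e-5, decimation = 10,
                       Pp0_kPa = 5, L_init_mm = NULL,
                       afterload_mN = NULL,
                       interventions = list()) {
  mode <- match.arg(mode)
  if (is.character(windkessel)) windkessel <- wk_preset(windkessel)
  stopifnot(inherits(geometry, "trabecula_geometry"),
            inherits(windkessel, "wk_params"),
            inherits(cycle, "cycle_policy"),
            inherits(muscle, "wk_muscle_block"))
  if (is.null(ventricle))
    ventricle <- ventricle_geometry(L_ref_mm = geometry$L0 / MM)
  stopifnot(inherits(ventricle, "ventricle_geometry"))
  cfg <- structure(
    list(mode = mode, geometry = geometry, ventricle = ventricle,
         windkessel = windkessel, cycle = cycle, muscle = muscle,
         n_beats = n_beats, burn_in_beats = burn_in_beats, dt = dt,
         decimation = decimation, Pp0 = Pp0_kPa * KPA,
         L_init = if (is.null(L_init_mm)) NULL else L_init_mm * MM,
         afterload = if (is.null(afterload_mN)) NULL else afterload_mN * MN,
         interventions = interventions),
    class = "wk_config")
  issues <- validate_config(cfg)
  if (nrow(issues))
    abort(paste0("invalid configuration:\n",
                 paste0("  - [", issues$key, "] ", issues$message,
                        collapse = "\n")),
          class = "wkloop_config_error")
  cfg
}

#' Validate a configuration
#'
#' Checks every invariant and reports all violations at once (key path plus
#' message) rather than failing on the first.
#'
#' @param config A `wk_config` (or a bare list with the same shape).
#' @return A tibble with columns `key`, `message`; zero rows when valid.
#' @export
validate_config <- function(config) {
  issues <- list()
  add <- function(key, msg) issues[[length(issues) + 1]] <<-
      tibble(key = key, message = msg)
  dt <- config$dt
  if (!is.finite(dt) || dt <= 0) add("dt", "must be positive")
  period <- 1 / config$cycle$stim_hz
  if (is.finite(dt) && dt > 0) {
    spb <- period / dt
    if (abs(spb - round(spb)) > 1e-6)
      add("cycle.stim_hz", sprintf(
        "beat period (%g s) must be an integer multiple of dt (%g s)",
        period, dt))
  }
  if (!is.finite(config$n_beats) || config$n_beats < 1)
    add("n_beats", "need at least one analysed beat")
  if (config$burn_in_beats < 0) add("burn_in_beats", "must be >= 0")
  if (config$decimation < 1 || config$decimation != round(config$decimation))
    add("decimation", "must be a positive integer")
  if (config$Pp0 < 0) add("Pp0_kPa", "must be >= 0")
  dur <- (config$n_beats + config$burn_in_beats) * period
  for (i in seq_along(config$interventions)) {
    iv <- config$interventions[[i]]
    if (!is.list(iv) || is.null(iv$time_s) || is.null(iv$param))
      add(sprintf("interventions[%d]", i), "must be built with intervention()")
    else {
      if (!iv$param %in% .iv_params)
        add(sprintf("interventions[%d].param", i),
            paste0("unknown parameter '", iv$param, "'"))
      if (iv$time_s >= dur)
        add(sprintf("interventions[%d].time_s", i),
            sprintf("%g s is beyond the run duration (%g s)", iv$time_s, dur))
    }
  }
  if (config$mode == "isotonic") {
    if (config$muscle$mode != "hill")
      add("muscle.mode", "isotonic mode requires the Hill muscle fixture")
    if (is.null(config$afterload))
      add("afterload_mN", "isotonic mode requires an afterload")
    else if (config$afterload <= 0)
      add("afterload_mN", "must be positive")
  }
  if (config$muscle$mode == "replay" && !is.null(config$muscle$twitch)) {
    tw <- config$muscle$twitch
    if (any(tw$force_N < -1e-12))
      add("muscle.twitch", "twitch force must be non-negative")
  }
  if (length(issues)) dplyr::bind_rows(issues)
  else tibble(key = character(), message = character())
}

#' @export
print.wk_config <- function(x, ...) {
  cat(sprintf("<wk_config> mode = %s, muscle = %s, %g beats (+%g burn-in) at %g Hz, dt = %g us\n",
              x$mode, x$muscle$mode, x$n_beats, x$burn_in_beats,
              x$cycle$stim_hz, x$dt / 1e-6))
  print(x$windkessel)
  invisible(x)
}

# resolve deferred defaults (L_ref, end-diastolic length, refill rate,
# initial length) into plain numbers; returns an augmented copy
resolve_config <- function(config) {
  geom <- config$geometry
  cfg <- config
  cyc <- cfg$cycle
  if (is.null(cyc$end_diastolic_length)) cyc$end_diastolic_length <- geom$L0
  if (is.null(cyc$refill_rate)) {
    # auto: two resting chamber volumes per beat period, so even a
    # near-complete ejection is restored well inside the diastolic window
    V_ref <- radius_to_volume(cfg$ventricle$r_ref)
    cyc$refill_rate <- 2 * V_ref * cyc$stim_hz
  }
  cfg$cycle <- cyc
  if (is.null(cfg$L_init)) cfg$L_init <- cyc$end_diastolic_length
  cfg$period <- 1 / cyc$stim_hz
  cfg$total_beats <- cfg$n_beats + cfg$burn_in_beats
  cfg
}

#' Read / write configurations as YAML
#'
#' The on-disk schema uses the units of the work-loop literature so values
#' can be copied verbatim from published parameter sets: resistances in
#' GPa s m^-3, compliance in pm^3 Pa^-1, lengths in mm, forces in mN,
#' pressures in kPa, refill rates in uL/s, `dt` in us. A round trip
#' (`write_config()` then `load_config()`) reproduces an equivalent
#' configuration.
#'
#' @param path YAML file path.
#' @param config A [sim_config()] result.
#' @return `load_config()` returns a `wk_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) abort(paste0("no such config file: ", path))
  lst <- yaml::read_yaml(path)
  config_from_list(lst)
}

#' @rdname load_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "wk_config"))
  yaml::write_yaml(config_to_list(config), path)
  invisible(path)
}

config_from_list <- function(lst) {
  g <- lst$geometry %||% list()
  geometry <- trabecula_geometry(L0_mm = g$L0_mm %||% 1.8,
                                 diameter_mm = g$diameter_mm %||% 0.26)
  ventricle <- ventricle_geometry(
    r_ref_mm = g$r_ref_mm %||% 5,
    wall_thickness_mm = g$wall_thickness_mm %||% 0.25,
    L_ref_mm = g$L_ref_mm %||% (g$L0_mm %||% 1.8))
  w <- lst$windkessel %||% list(preset = "normotensive")
  windkessel <- if (!is.null(w$preset)) wk_preset(w$preset)
  else windkessel_params(w$Rp_GPa_s_per_m3, w$C_pm3_per_Pa,
                         w$Zc_GPa_s_per_m3)
  cy <- lst$cycle %||% list()
  rr <- cy$refill_rate_uL_per_s
  if (is.character(rr) && identical(rr, "auto")) rr <- NULL
  cycle <- cycle_policy(
    stim_hz = cy$stim_hz %||% 1,
    refill_rate_uL_per_s = rr,
    refill_trigger_fraction = cy$refill_trigger_fraction %||% 0.05,
    end_diastolic_length_mm = cy$end_diastolic_length_mm)
  m <- lst$muscle %||% list(mode = "replay")
  muscle <- if (identical(m$mode, "hill")) {
    hill_muscle(hill_params(
      sigma_max_kPa = m$sigma_max_kPa %||% 66,
      fl_width = m$fl_width %||% 0.35,
      v_max_L0_per_s = m$v_max_L0_per_s %||% 3,
      a_curv = m$a_curv %||% 0.25,
      passive_k_kPa = m$passive_k_kPa %||% 0.25,
      passive_beta = m$passive_beta %||% 25,
      slack_frac = m$slack_frac %||% 0.9,
      t_rise = if (is.null(m$t_rise_ms)) NULL else m$t_rise_ms / 1e3,
      t_fall = if (is.null(m$t_fall_ms)) NULL else m$t_fall_ms / 1e3,
      temperature = m$temperature %||% "body"))
  } else {
    tw <- if (!is.null(m$twitch_file)) read_twitch_trace(m$twitch_file)
    replay_muscle(twitch = tw,
                  peak_mN = m$peak_mN %||% 3.5,
                  t_rise = (m$t_rise_ms %||% 30) / 1e3,
                  t_fall = (m$t_fall_ms %||% 80) / 1e3)
  }
  s <- lst$sim %||% list()
  ivs <- purrr::map(lst$interventions %||% list(), function(iv)
    intervention(iv$time_s, iv$param, iv$value,
                 iv$defer_to_diastole %||% TRUE))
  sim_config(mode = lst$mode %||% "windkessel",
             geometry = geometry, ventricle = ventricle,
             windkessel = windkessel, cycle = cycle, muscle = muscle,
             n_beats = s$n_beats %||% 10,
             burn_in_beats = s$burn_in_beats %||% 10,
             dt = (s$dt_us %||% 50) / 1e6,
             decimation = s$decimation %||% 10,
             Pp0_kPa = s$Pp0_kPa %||% 5,
             L_init_mm = s$L_init_mm,
             afterload_mN = s$afterload_mN,
             interventions = ivs)
}

config_to_list <- function(config) {
  g <- config$geometry; v <- config$ventricle
  cyc <- config$cycle
  m <- config$muscle
  muscle <- if (m$mode == "hill") {
    p <- m$params
    list(mode = "hill", sigma_max_kPa = p$sigma_max / KPA,
         fl_width = p$fl_width, v_max_L0_per_s = p$v_max_L0_per_s,
         a_curv = p$a_curv, passive_k_kPa = p$passive_k / KPA,
         passive_beta = p$passive_beta, slack_frac = p$slack_frac,
         t_rise_ms = p$t_rise * 1e3, t_fall_ms = p$t_fall * 1e3,
         temperature = p$temperature)
  } else {
    list(mode = "replay", peak_mN = m$peak_mN, t_rise_ms = m$t_rise * 1e3,
         t_fall_ms = m$t_fall * 1e3)
  }
  out <- list(
    mode = config$mode,
    geometry = list(L0_mm = g$L0 / MM, diameter_mm = g$diameter / MM,
                    r_ref_mm = v$r_ref / MM, wall_thickness_mm = v$h / MM,
                    L_ref_mm = v$L_ref / MM),
    windkessel = list(Rp_GPa_s_per_m3 = config$windkessel$Rp / GPA_S_M3,
                      C_pm3_per_Pa = config$windkessel$C / PM3_PA,
                      Zc_GPa_s_per_m3 = config$windkessel$Zc / GPA_S_M3),
    cycle = list(stim_hz = cyc$stim_hz,
                 refill_rate_uL_per_s =
                   if (is.null(cyc$refill_rate)) "auto"
                   else cyc$refill_rate / UL,
                 refill_trigger_fraction = cyc$refill_trigger_fraction),
    muscle = muscle,
    sim = list(dt_us = round(config$dt / 1e-6, 9), n_beats = config$n_beats,
               burn_in_beats = config$burn_in_beats,
               decimation = config$decimation,
               Pp0_kPa = config$Pp0 / KPA))
  if (!is.null(cyc$end_diastolic_length))
    out$cycle$end_diastolic_length_mm <- cyc$end_diastolic_length / MM
  if (!is.null(config$L_init)) out$sim$L_init_mm <- config$L_init / MM
  if (!is.null(config$afterload))
    out$sim$afterload_mN <- config$afterload / MN
  if (length(config$interventions))
    out$interventions <- purrr::map(config$interventions, function(iv)
      list(time_s = iv$time_s, param = iv$param, value = iv$value,
           defer_to_diastole = iv$defer_to_diastole))
  out
}

#' Write a run metadata sidecar
#'
#' JSON echo of the configuration plus the package version: enough to
#' reproduce the run.
#'
#' @param record A simulation record (see [simulate_workloop()]).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(record, path) {
  config <- attr(record, "config")
  stopifnot(inherits(config, "wk_config"))
  meta <- list(package = "wkloop",
               version = as.character(utils::packageVersion("wkloop")),
               config = config_to_list(config))
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
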