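#' Plot a simulation record
#'
#' `type = "loop"` draws the stress-length work-loop (kPa vs relative
#' length, the figure convention of the work-loop literature), `"pv"` the
#' equivalent pressure-volume loop (kPa vs uL), `"timecourse"` the state
#' traces (stress, length, and the three pressures with aortic flow).
#'
#' @param object A `wk_record`.
#' @param type `"loop"`, `"pv"` or `"timecourse"`.
#' @param discard_burn_in Drop the settling beats first (default `TRUE`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.wk_record <- function(object, type = c("loop", "pv", "timecourse"),
                               discard_burn_in = TRUE, ...) {
  type <- match.arg(type)
  rec <- if (discard_burn_in) discard_burn_in(object) else object
  config <- attr(object, "config")
  L0 <- config$geometry$L0
  df <- as_tibble(rec)
  if (type == "loop") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$length_m / L0,
                                     y = .data$stress_Pa / KPA,
                                     group = .data$beat)) +
      ggplot2::geom_path(alpha = 0.8) +
      ggplot2::labs(x = "relative length (L/L0)", y = "stress (kPa)",
                    title = "stress-length work-loop") +
      ggplot2::theme_minimal()
  } else if (type == "pv") {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$V_m3 / UL,
                                     y = .data$P_Pa / KPA,
                                     group = .data$beat)) +
      ggplot2::geom_path(alpha = 0.8) +
      ggplot2::labs(x = "volume (uL)", y = "ventricular pressure (kPa)",
                    title = "pressure-volume loop") +
      ggplot2::theme_minimal()
  } else {
    long <- df |>
      dplyr::transmute(time_s = .data$time_s,
                       `stress (kPa)` = .data$stress_Pa / KPA,
                       `length (L/L0)` = .data$length_m / L0,
                       `P (kPa)` = .data$P_Pa / KPA,
                       `Pa (kPa)` = .data$Pa_Pa / KPA,
                       `Pp (kPa)` = .data$Pp_Pa / KPA,
                       `Q (uL/s)` = .data$Q_m3_s / UL) |>
      tidyr::pivot_longer(-"time_s")
    ggplot2::ggplot(long, ggplot2::aes(.data$time_s, .data$value)) +
      ggplot2::geom_line() +
      ggplot2::facet_wrap(~name, scales = "free_y", ncol = 1) +
      ggplot2::labs(x = "time (s)", y = NULL,
                    title = "simulated state traces") +
      ggplot2::theme_minimal()
  }
}

#' Plot a parameter sweep as overlaid steady-state loops
#'
#' @param object A `wk_sweep`.
#' @param ... Unused.
#' @return A ggplot of the steady-beat stress-length loops coloured by
#'   parameter value.
#' @export
autoplot.wk_sweep <- function(object, ...) {
  config <- attr(object, "config")
  L0 <- config$geometry$L0
  param <- attr(object, "param")
  df <- object |>
    dplyr::select("value", "record") |>
    tidyr::unnest("record")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$length_m / L0,
                                   y = .data$stress_Pa / KPA,
                                   colour = factor(.data$value),
                                   group = .data$value)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "relative length (L/L0)", y = "stress (kPa)",
                  colour = param,
                  title = sprintf("steady-state work-loops across %s", param)) +
    ggplot2::theme_minimal()
}

#' Plot the work-afterload relation
#'
#' Work per beat against end-systolic stress, one curve per loading mode,
#' with the origin-constrained quadratic fits overlaid.
#'
#' @param object A `work_afterload` table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.work_afterload <- function(object, ...) {
  wf <- fit_work_afterload(object)
  lines <- purrr::imap_dfr(wf$fits, function(f, nm) {
    ess <- seq(0, max(object$end_systolic_stress_Pa), length.out = 100)
    tibble(mode = nm, end_systolic_stress_Pa = ess,
           work_J = predict(wf, ess, mode = nm))
  })
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$end_systolic_stress_Pa / KPA,
                               y = .data$work_J * 1e6,
                               colour = .data$mode)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = lines, linetype = 2) +
    ggplot2::labs(x = "end-systolic stress (kPa)", y = "work (uJ)",
                  colour = "loading mode",
                  title = "work-afterload relation") +
    ggplot2::theme_minimal()
}
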