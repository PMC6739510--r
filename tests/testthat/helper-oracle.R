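# Independent high-accuracy integration of the hybrid replay-mode system,
# used to cross-check the fixed-step engine. Formulated in (Pp, V) with
# deSolve::lsodar and root-triggered valve events -- deliberately a
# different state basis, integrator and event mechanism from the engine.

oracle_replay_beat <- function(geom, vgeom, params, peak_mN = 3.5,
                               t_rise = 0.012, t_fall = 0.035,
                               period = 0.2, Pp0 = 5e3, L_init = NULL,
                               times = seq(0, period, by = 5e-4),
                               tol = 1e-10) {
  L_init <- L_init %||% geom$L0
  V0 <- radius_to_volume(length_to_radius(L_init, vgeom))
  area <- geom$area
  # continuous closed-form twitch (same waveform the generator samples)
  tstar <- t_rise * t_fall / (t_fall - t_rise) * log(t_fall / t_rise)
  smax <- exp(-tstar / t_fall) - exp(-tstar / t_rise)
  force_fun <- function(t) {
    tb <- t %% period
    peak_mN * 1e-3 * (exp(-tb / t_fall) - exp(-tb / t_rise)) / smax
  }
  P_fun <- function(t, V) {
    r <- (3 * V / (4 * pi))^(1 / 3)
    2 * (force_fun(t) / area) * vgeom$h / r
  }
  Rp <- params$Rp; Cc <- params$C; Zc <- params$Zc

  deriv_closed <- function(t, y, parms) {
    list(c(-y[1] / (Rp * Cc), 0))
  }
  root_closed <- function(t, y, parms) P_fun(t, y[2]) - y[1]
  deriv_open <- function(t, y, parms) {
    Q <- (P_fun(t, y[2]) - y[1]) / Zc
    list(c((Q - y[1] / Rp) / Cc, -Q))
  }
  root_open <- function(t, y, parms) (P_fun(t, y[2]) - y[1]) / Zc

  y <- c(Pp = Pp0, V = V0)
  valve <- FALSE
  t_now <- times[1]
  out <- matrix(NA_real_, nrow = length(times), ncol = 3,
                dimnames = list(NULL, c("Pp", "V", "Q")))
  out[1, ] <- c(y, 0)
  idx <- 2
  while (t_now < max(times) - 1e-12) {
    seg_times <- unique(c(t_now, times[times > t_now + 1e-12]))
    sol <- deSolve::lsodar(
      y = y, times = seg_times,
      func = if (valve) deriv_open else deriv_closed,
      rootfunc = if (valve) root_open else root_closed,
      rtol = tol, atol = c(1e-6, 1e-18))
    t_root <- attr(sol, "troot")
    # keep rows at requested sample times reached before the event
    sol_t <- sol[, 1]
    keep <- which(sol_t > t_now + 1e-12)
    for (kk in keep) {
      tt <- sol_t[kk]
      hit <- which(abs(times - tt) < 1e-9)
      if (length(hit)) {
        Q <- if (valve) (P_fun(tt, sol[kk, 3]) - sol[kk, 2]) / Zc else 0
        out[hit, ] <- c(sol[kk, 2], sol[kk, 3], max(Q, 0))
        idx <- hit + 1
      }
    }
    last <- nrow(sol)
    y <- c(Pp = sol[last, 2], V = sol[last, 3])
    t_end <- sol_t[last]
    if (!is.null(t_root) && length(t_root) && t_end < max(times) - 1e-12) {
      valve <- !valve  # event: flip the valve and restart the integrator
      t_now <- t_end
    } else {
      t_now <- t_end
    }
  }
  tibble::tibble(time_s = times, Pp = out[, "Pp"], V = out[, "V"],
                 Q = out[, "Q"],
                 L = vgeom$L_ref * volume_to_radius(out[, "V"]) / vgeom$r_ref)
}
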