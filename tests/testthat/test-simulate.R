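test_that("the engine is deterministic and volume-length consistent", {
  cfg <- replay_cfg(n_beats = 2, burn_in = 4)
  r1 <- simulate_workloop(cfg)
  r2 <- simulate_workloop(cfg)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  # V = (4/3) pi (r_ref L / L_ref)^3 at every sample, to round-off
  vg <- cfg$ventricle
  V_from_L <- radius_to_volume(length_to_radius(r1$length_m, vg))
  expect_equal(r1$V_m3, V_from_L, tolerance = 1e-13)
})

test_that("logged rows satisfy the circuit and valve invariants", {
  rec <- simulate_workloop(replay_cfg(n_beats = 3, burn_in = 6))
  expect_true(all(rec$Q_m3_s >= 0))
  expect_true(all(rec$Pp_Pa >= 0))
  closed <- !rec$valve_open
  expect_true(all(rec$Q_m3_s[closed] == 0))
  expect_equal(rec$Pa_Pa[closed], rec$Pp_Pa[closed])
  p <- attr(rec, "config")$windkessel
  open <- rec$valve_open
  expect_equal(rec$Pa_Pa[open], rec$Pp_Pa[open] + rec$Q_m3_s[open] * p$Zc)
  # refill never coincides with an open valve
  expect_false(any(rec$refilling & rec$valve_open))
  # valve complementarity: closed implies P <= Pa up to the one-step lag
  # around events; quantify as no closed sample with a large positive gap
  gap <- (rec$P_Pa - rec$Pa_Pa)[closed]
  expect_lt(mean(gap > 0), 0.01)
  # strictly increasing uniform time grid
  expect_equal(unique(round(diff(rec$time_s), 12)),
               attr(rec, "dt_log"), tolerance = 1e-9)
})

test_that("replay beats show the four phases in order", {
  rec <- classify_phases(discard_burn_in(simulate_workloop(
    replay_cfg(n_beats = 3, burn_in = 8))))
  for (b in unique(rec$beat)) {
    ph <- rle(rec$phase[rec$beat == b])$values
    expect_true(all(c("isovolumic_rise", "ejection",
                      "isovolumic_relaxation", "refill") %in% ph))
    expect_lt(which(ph == "ejection")[1],
              which(ph == "isovolumic_relaxation")[1])
    expect_lt(which(ph == "isovolumic_relaxation")[1],
              which(ph == "refill")[1])
  }
})

test_that("isometric mode clamps length, may still open the valve", {
  cfg <- sim_config(mode = "isometric",
                    cycle = cycle_policy(stim_hz = 5),
                    muscle = replay_muscle(t_rise = 0.012, t_fall = 0.035),
                    n_beats = 2, burn_in_beats = 2, Pp0_kPa = 2)
  rec <- simulate_workloop(cfg)
  expect_equal(diff(range(rec$length_m)), 0)
  expect_true(any(rec$valve_open))  # P exceeds the (low) aortic pressure
  m <- beats_metrics(rec)
  expect_equal(m$work_J, rep(0, nrow(m)), tolerance = 1e-15)
})

test_that("volume bookkeeping closes against the discrete flow sums", {
  cfg <- replay_cfg(n_beats = 2, burn_in = 4, decim = 1)
  rec <- simulate_workloop(cfg)
  dt <- attr(rec, "dt_log")
  # the engine integrates V with left sums of Q and the (clipped) inflow;
  # reconstruct the inflow from the V increments on refill steps
  dV <- diff(rec$V_m3)
  out <- -rec$Q_m3_s[-nrow(rec)] * dt
  inflow <- dV - out
  expect_true(all(inflow[!rec$refilling[-nrow(rec)]] < 1e-15))
  expect_equal(rec$V_m3[nrow(rec)] - rec$V_m3[1], sum(dV), tolerance = 1e-12)
  rel <- abs(sum(dV) - (sum(inflow) + sum(out))) / rec$V_m3[1]
  expect_lt(rel, 1e-9)
})

test_that("interventions apply once, deferred to diastole, presets atomically", {
  cfg <- replay_cfg(n_beats = 6, burn_in = 4)
  cfg$interventions <- list(intervention(1.25, "Rp", 50))
  rec <- simulate_workloop(cfg)
  applied <- attr(rec, "interventions_applied_s")
  expect_length(applied, 1)
  expect_gte(applied, 1.25)
  # applied during diastole: at that instant the valve was closed
  i <- which.min(abs(rec$time_s - applied))
  expect_false(rec$valve_open[i])
  # the diastolic decay after the step reflects the new time constant
  m <- beats_metrics(rec)
  tau_new <- 50e9 * 32e-12
  expect_equal(m$fitted_tau_s[nrow(m)], tau_new, tolerance = 1e-2)
  # immediate application happens at the requested time
  cfg2 <- replay_cfg(n_beats = 3, burn_in = 2)
  cfg2$interventions <- list(intervention(0.53, "Zc", 5,
                                          defer_to_diastole = FALSE))
  expect_equal(attr(simulate_workloop(cfg2), "interventions_applied_s"),
               0.53, tolerance = 1e-4)
  # preset swap changes all three parameters at one instant
  cfg3 <- replay_cfg(n_beats = 4, burn_in = 4)
  cfg3$interventions <- list(intervention(1.1, "preset", "hypertensive"))
  rec3 <- simulate_workloop(cfg3)
  expect_equal(length(unique(attr(rec3, "interventions_applied_s"))), 1)
  m3 <- beats_metrics(rec3)
  expect_equal(m3$fitted_tau_s[nrow(m3)], 0.321, tolerance = 1e-2)
})

test_that("empty intervention list leaves parameters constant", {
  rec <- simulate_workloop(replay_cfg(n_beats = 3, burn_in = 6))
  m <- beats_metrics(rec)
  expect_equal(m$fitted_tau_s, rep(0.464, nrow(m)), tolerance = 1e-2)
})

test_that("R-level step functions reproduce the engine's closed-phase path", {
  # cross-implementation check: drive wk_step_closed/exponential decay over
  # a diastolic stretch of a simulated record
  rec <- simulate_workloop(replay_cfg(n_beats = 2, burn_in = 6, decim = 1))
  p <- attr(rec, "config")$windkessel
  dia <- which(!rec$valve_open & !rec$refilling)
  # longest contiguous closed-valve stretch
  runs <- rle(diff(dia) == 1)
  ends <- cumsum(runs$lengths)
  k <- which.max(ifelse(runs$values, runs$lengths, 0))
  idx <- dia[(ends[k] - runs$lengths[k] + 1):(ends[k] + 1)]
  s <- wk_state(Pp = rec$Pp_Pa[idx[1]])
  for (i in idx[-1]) {
    s <- wk_step_closed(s, p, attr(rec, "dt_log"))
    expect_equal(s$Pp, rec$Pp_Pa[i], tolerance = 1e-12)
  }
})

test_that("diverging states abort with a diagnostic", {
  # an absurd refill rate cannot rescue a tiny ventricle from a huge twitch
  cfg <- sim_config(
    ventricle = ventricle_geometry(r_ref_mm = 1.2, wall_thickness_mm = 0.3,
                                   L_ref_mm = 1.8),
    cycle = cycle_policy(stim_hz = 5, refill_rate_uL_per_s = 0),
    muscle = replay_muscle(t_rise = 0.012, t_fall = 0.035),
    n_beats = 3, burn_in_beats = 3, Pp0_kPa = 0.1)
  expect_error(simulate_workloop(cfg), "diverged at t")
})
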