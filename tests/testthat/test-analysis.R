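test_that("shoelace area handles squares, degenerate paths and rectangles", {
  expect_equal(loop_area(c(0, 1, 1, 0), c(0, 0, 1, 1)), 1)   # ccw
  expect_equal(loop_area(c(0, 0, 1, 1), c(0, 1, 1, 0)), -1)  # cw
  expect_equal(loop_area(1:10, rep(3, 10)), 0)
  # idealized flat-top loop: rectangle dF x dL
  dF <- 2.5e-3; dL <- 0.2e-3
  x <- c(0, 0, dL, dL); y <- c(0, dF, dF, 0)
  expect_equal(abs(loop_area(x, y)), dF * dL)
  expect_error(loop_area(c(0, 1), c(0, 1)), class = "wkloop_undefined_area")
})

test_that("beat metrics agree with independent recomputation", {
  rec <- simulate_workloop(replay_cfg(n_beats = 3, burn_in = 8))
  m <- beats_metrics(rec)
  b <- m$beat[nrow(m)]
  sl <- rec[rec$beat == b, ]
  # stroke volume equals the integral of ejected flow over the beat
  dt <- attr(rec, "dt_log")
  sv_q <- sum(sl$Q_m3_s) * dt
  expect_equal(m$stroke_volume_m3[nrow(m)], sv_q, tolerance = 1e-3)
  # end-systole is the valve-closure sample
  i_es <- max(which(sl$valve_open))
  expect_equal(m$end_systolic_length_m[nrow(m)], sl$length_m[i_es])
  # work is positive for an ejecting beat and equals |shoelace|
  expect_gt(m$work_J[nrow(m)], 0)
  expect_equal(m$work_J[nrow(m)], abs(loop_area(sl$length_m, sl$force_N)))
  # the time-ordered (L, F) loop is traversed counter-clockwise:
  # the muscle does net positive boundary work, -closed-integral F dL > 0
  expect_gt(loop_area(sl$length_m, sl$force_N), 0)
})

test_that("diastolic decay fits recover tau with its invariances", {
  t <- seq(0, 0.3, by = 5e-4)
  Pa <- 12e3 * exp(-t / 0.464)
  fit <- fit_diastolic_decay(t, Pa)
  expect_equal(fit$tau, 0.464, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")
  # invariant to uniform pressure rescaling and time-origin shifts
  expect_equal(fit_diastolic_decay(t, 3.7 * Pa)$tau, fit$tau,
               tolerance = 1e-9)
  expect_equal(fit_diastolic_decay(t + 5, Pa)$tau, fit$tau,
               tolerance = 1e-6)
  # constant signal -> flagged infinite tau
  cfit <- fit_diastolic_decay(t, rep(10e3, length(t)))
  expect_identical(cfit$tau, Inf)
  expect_identical(cfit$flag, "constant")
  # short span keeps a best-effort fit but warns
  expect_warning(sfit <- fit_diastolic_decay(t[1:20], Pa[1:20]), "span")
  expect_identical(sfit$flag, "short_span")
  expect_equal(sfit$tau, 0.464, tolerance = 1e-3)
  expect_error(fit_diastolic_decay(t[1:5], Pa[1:5]),
               class = "wkloop_insufficient_data")
  expect_error(fit_diastolic_decay(t, Pa - 20e3),
               class = "wkloop_invalid_state")
  # broom-style accessors
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "tau_s"], fit$tau)
  expect_gt(glance(fit)$r.squared, 0.999)
})

test_that("simulated diastole fits back the Rp*C constant within 1%", {
  rec <- simulate_workloop(replay_cfg(n_beats = 2, burn_in = 8))
  m <- beats_metrics(rec)
  expect_equal(m$fitted_tau_s, rep(0.464, nrow(m)), tolerance = 1e-2)
})

test_that("work-afterload table sorts, fits through the origin", {
  sw <- tibble::tibble(value = c(3, 1, 2),
                       end_systolic_stress_Pa = c(30e3, 10e3, 20e3),
                       work_J = c(2e-8, 4e-8, 5e-8),
                       stress_length_area_Pa_m = c(1, 2, 3),
                       peak_stress_Pa = c(3, 1, 2) * 1e4,
                       steady = TRUE)
  class(sw) <- c("wk_sweep", class(sw))
  tbl <- work_afterload_table(list(flat = sw))
  expect_true(!is.unsorted(tbl$end_systolic_stress_Pa))
  wf <- fit_work_afterload(tbl)
  expect_identical(predict(wf, 0, "flat"), 0)
  # degree-2 through the origin reproduces any 2-point-consistent quadratic
  ess <- tbl$end_systolic_stress_Pa
  pred <- predict(wf, ess, "flat")
  expect_equal(pred, tbl$work_J, tolerance = 1e-6)
  expect_error(predict(wf, 1, "missing-mode"))
  expect_equal(nrow(tidy(wf)), 2)
})

test_that("energy audit closes for steady replay beats", {
  cfg <- replay_cfg(n_beats = 2, burn_in = 10, decim = 1)
  eb <- energy_balance(simulate_workloop(cfg))
  expect_true(all(eb$E_in_J > 0))
  expect_true(all(eb$residual_rel < 0.005))
})
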