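test_that("stimulus times follow the truncation rule", {
  expect_equal(stimulus_times(cycle_policy(1), 6), 0:5)
  expect_equal(stimulus_times(cycle_policy(5), 1), seq(0, 0.8, by = 0.2))
  # non-integer products truncate to floor(duration * frequency)
  expect_length(stimulus_times(cycle_policy(3), 2.5), 7)
  expect_length(stimulus_times(cycle_policy(2.5), 2), 5)
})

test_that("valve logic opens on strict inequality and snaps closed", {
  p <- wk_preset("normotensive")
  closed <- wk_state(Pp = 10e3)
  expect_false(update_valve(0.9 * 10e3, closed, p)$valve_open)
  expect_false(update_valve(10e3, closed, p)$valve_open)  # tie stays closed
  opened <- update_valve(10e3 + 1, closed, p)
  expect_true(opened$valve_open)
  expect_gt(opened$Q, 0)
  # open valve with P below Pp closes with Q exactly 0
  open <- wk_state(Pp = 10e3, valve_open = TRUE, Q = 1e-6, params = p)
  shut <- update_valve(9e3, open, p)
  expect_false(shut$valve_open)
  expect_identical(shut$Q, 0)
  expect_equal(shut$Pa, shut$Pp)
})

test_that("refill respects trigger, target length and clipping", {
  vg <- ref_vgeom()
  pol <- cycle_policy(5, refill_rate_uL_per_s = 100,
                      end_diastolic_length_mm = 1.8)
  closed <- wk_state(Pp = 5e3)
  V_ED <- radius_to_volume(length_to_radius(1.8e-3, vg))
  # at target -> no inflow
  expect_equal(refill_step(V_ED, 0, 60e3, pol, closed, vg, 5e-5), 0)
  # active stress above trigger -> no inflow
  expect_equal(refill_step(0.9 * V_ED, 0.5 * 60e3, 60e3, pol, closed, vg,
                           5e-5), 0)
  # below trigger and short of target -> rate * dt
  expect_equal(refill_step(0.9 * V_ED, 0.01 * 60e3, 60e3, pol, closed, vg,
                           5e-5), 100e-9 * 5e-5)
  # clipping: never overshoot the end-diastolic volume
  gap <- 1e-12
  expect_equal(refill_step(V_ED - gap, 0, 60e3, pol, closed, vg, 5e-5), gap)
  # refill while open is a logic error
  open <- wk_state(Pp = 5e3, valve_open = TRUE, Q = 1e-6,
                   params = wk_preset("normotensive"))
  expect_error(refill_step(0.9 * V_ED, 0, 60e3, pol, open, vg, 5e-5),
               class = "wkloop_logic_error")
})

test_that("zero refill rate degenerates the loop after the first beats", {
  cfg <- sim_config(cycle = cycle_policy(5, refill_rate_uL_per_s = 0),
                    muscle = hill_muscle(hill_params(temperature = "body")),
                    n_beats = 4, burn_in_beats = 4)
  rec <- simulate_workloop(cfg)
  m <- beats_metrics(rec)
  # without refill the muscle never re-lengthens: beat-start lengths and
  # stroke volumes ratchet down monotonically instead of cycling
  starts <- sapply(split(rec$length_m, rec$beat), function(x) x[1])
  expect_true(all(diff(starts) < 0))
  expect_true(all(diff(m$stroke_volume_m3) < 0))
  expect_true(all(diff(sapply(split(rec$length_m, rec$beat), min)) < 1e-12))
})

test_that("with refill active the beat-start length returns to the target", {
  cfg <- replay_cfg(n_beats = 3, burn_in = 6)
  rec <- simulate_workloop(cfg)
  L0 <- attr(rec, "config")$geometry$L0
  starts <- sapply(split(rec$length_m, rec$beat), function(x) x[1])
  kept <- starts[-seq_len(3)]  # after a few settling beats
  expect_true(all(abs(kept - L0) < 1e-6 * L0))
})
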