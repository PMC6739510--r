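test_that("synthesised twitch hits its peak at the analytic argmax", {
  tw <- synthesize_twitch(3.5, 0.03, 0.08, period = 1, dt = 5e-5)
  expect_equal(max(tw$force_N), 3.5e-3, tolerance = 1e-3)
  expect_true(all(tw$force_N >= 0))
  expect_equal(tw$force_N[1], 0)
  tstar <- 0.03 * 0.08 / (0.08 - 0.03) * log(0.08 / 0.03)
  expect_equal(tw$time_s[which.max(tw$force_N)], tstar, tolerance = 2e-3)
  # equal time constants fall back to t*exp(-t/tau), peaking at tau
  twe <- synthesize_twitch(2, 0.05, 0.05, period = 1, dt = 5e-5)
  expect_equal(max(twe$force_N), 2e-3, tolerance = 1e-3)
  expect_equal(twe$time_s[which.max(twe$force_N)], 0.05, tolerance = 2e-3)
  expect_equal(max(synthesize_twitch(0, 0.03, 0.08)$force_N), 0)
})

test_that("twitch interpolation is linear, periodic and trace-faithful", {
  tw <- synthesize_twitch(3.5, 0.03, 0.08, period = 1, dt = 1e-3)
  # midpoint of two samples equals their mean (piecewise linearity)
  i <- 101
  mid <- (tw$time_s[i] + tw$time_s[i + 1]) / 2
  expect_equal(twitch_force(mid, tw),
               (tw$force_N[i] + tw$force_N[i + 1]) / 2, tolerance = 1e-12)
  # periodic wrap: a full period later gives the same value
  expect_equal(twitch_force(0.25, tw), twitch_force(1.25, tw))
  expect_equal(twitch_force(tw$time_s, tw), tw$force_N, tolerance = 1e-12)
})

test_that("twitch traces round-trip through delimited text", {
  tw <- synthesize_twitch(3.5, 0.012, 0.035, period = 0.2, dt = 1e-3)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_twitch_trace(tw, path)
  tw2 <- read_twitch_trace(path)
  expect_equal(tw2$force_N, tw$force_N, tolerance = 1e-9)
  expect_equal(attr(tw2, "period"), attr(tw, "period"), tolerance = 1e-9)
})

test_that("Hill stress obeys its defining identities", {
  p <- hill_params()
  g <- ref_geom()
  L0 <- g$L0
  # no activation at/below slack -> zero stress
  expect_equal(hill_stress(0.89 * L0, 0, 0, p, g), 0)
  # full activation, optimal length, isometric -> sigma_max + passive
  pass_L0 <- p$passive_k * expm1(p$passive_beta * (1 - p$slack_frac))
  expect_equal(hill_stress(L0, 0, 1, p, g), p$sigma_max + pass_L0,
               tolerance = 1e-12)
  # monotone non-increasing in shortening velocity on a grid
  vmax <- p$v_max_L0_per_s * L0
  v <- seq(0, vmax, length.out = 41)
  s <- hill_stress(L0, v, 1, p, g)
  expect_true(all(diff(s) <= 1e-12))
  expect_equal(s[length(s)], pass_L0, tolerance = 1e-9)
  # lengthening capped at fv_lengthening_cap
  expect_lte(hill_stress(L0, -vmax, 1, p, g),
             p$fv_cap * p$sigma_max + pass_L0 + 1e-9)
  # force-length parabola: fl(L0) = 1, zero beyond the half-width
  far <- L0 * (1 - p$fl_width - 0.01)
  expect_equal(hill_stress(far, 0, 1, p, g), 0)  # below slack too
})

test_that("activation drive is normalised and completes within the beat", {
  for (temp in c("body", "warm", "room")) {
    p <- hill_params(temperature = temp)
    tt <- seq(0, 1, by = 1e-4)
    a <- hill_activation(tt, p)
    expect_equal(max(a), 1, tolerance = 1e-4)
    period <- if (temp == "body") 0.2 else 1
    expect_lt(hill_activation(period, p), 0.05)  # diastole completes
  }
})

test_that("isometric Hill twitch peaks at sigma_max plus passive", {
  cfg <- sim_config(mode = "isometric", cycle = cycle_policy(stim_hz = 5),
                    muscle = hill_muscle(hill_params(temperature = "body")),
                    n_beats = 2, burn_in_beats = 1)
  rec <- simulate_workloop(cfg)
  p <- hill_params(temperature = "body")
  pass_L0 <- p$passive_k * expm1(p$passive_beta * (1 - p$slack_frac))
  expect_equal(max(rec$stress_Pa), p$sigma_max + pass_L0, tolerance = 1e-3)
  expect_equal(diff(range(rec$length_m)), 0)
})
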