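norm <- function() wk_preset("normotensive")

test_that("input impedance has the right DC, high-frequency and printed limits", {
  p <- norm()
  expect_equal(Re(wk_input_impedance(p, 0)), p$Rp + p$Zc)
  expect_equal(wk_input_impedance(p, 0), 15e9, tolerance = 1e-12)
  expect_equal(abs(wk_input_impedance(p, 1e9i)), p$Zc, tolerance = 1e-4)
  # magnitude decreases monotonically with frequency for an RC circuit
  w <- 10^seq(-1, 5, length.out = 40)
  expect_true(all(diff(abs(wk_input_impedance(p, 1i * w))) < 0))
})

test_that("time constants reproduce the printed parameter products", {
  expect_equal(wk_time_constant(norm()), 0.464, tolerance = 1e-12)
  expect_equal(wk_time_constant(wk_preset("hypertensive")), 0.321,
               tolerance = 1e-12)
  p2 <- windkessel_params(29, 32, 0.5)
  expect_equal(wk_time_constant(p2), 2 * wk_time_constant(norm()))
  expect_warning(windkessel_params(1, 32, 2), "Zc")
  expect_error(windkessel_params(-1, 32, 0.5), class = "wkloop_invalid_params")
})

test_that("closed-valve decay is exact and has the semigroup property", {
  p <- norm()
  s0 <- wk_state(Pp = 10e3)
  tau <- wk_time_constant(p)
  # one elapsed tau -> 1/e, via many 50 us steps of the exact integrator
  n <- round(tau / 5e-5)
  s <- s0
  for (i in seq_len(n)) s <- wk_step_closed(s, p, 5e-5)
  expect_equal(s$Pp, 10e3 * exp(-n * 5e-5 / tau), tolerance = 1e-12)
  expect_equal(s$Pp, 10e3 / exp(1), tolerance = 1e-9)
  # two half steps equal one full step
  s1 <- wk_step_closed(s0, p, 1e-3)
  s2 <- wk_step_closed(wk_step_closed(s0, p, 5e-4), p, 5e-4)
  expect_equal(s1$Pp, s2$Pp, tolerance = 1e-12)
  expect_equal(s1$Q, 0)
  expect_equal(s1$Pa, s1$Pp)
  expect_error(wk_step_closed(s0, p, 0), class = "wkloop_invalid_step")
})

test_that("open-valve stepping has the algebraic flow and circuit steady state", {
  p <- norm()
  s <- wk_state(Pp = 10e3, valve_open = TRUE, Q = 4e-6, params = p)
  # instantaneous flow from a 2 kPa gradient across Zc = 0.5 GPa s m^-3
  expect_equal(wk_flow(12e3, s, p), 4e-6)
  expect_equal(wk_flow(10e3, s, p), 0)
  # state invariant: Pa = Pp + Q Zc when open
  expect_equal(s$Pa, s$Pp + s$Q * p$Zc)
  # constant P held for >> tau converges to the resistive divider
  P <- 12e3
  st <- wk_state(Pp = 0, valve_open = TRUE, Q = P / p$Zc, params = p)
  dt <- 2e-4
  for (i in seq_len(ceiling(10 * wk_time_constant(p) / dt)))
    st <- wk_step_open(st, P, p, dt)
  expect_equal(st$Q, P / (p$Rp + p$Zc), tolerance = 1e-4)
  expect_equal(st$Pp, P * p$Rp / (p$Rp + p$Zc), tolerance = 1e-4)
})

test_that("discrete admittance matches DC gain, stability and state-space stepping", {
  p <- norm()
  adm <- discretize_admittance(p, 5e-5)
  expect_equal(adm$a[1], 1)
  # pole strictly inside the unit circle across a parameter grid
  for (Rp in c(5, 14.5, 150, 2000)) for (C in c(15, 32, 80))
    for (Zc in c(0.31, 0.5, 5, 15)) {
      a <- suppressWarnings(
        discretize_admittance(windkessel_params(Rp, C, Zc), 5e-5))
      expect_lt(abs(-a$a[2]), 1)
    }
  # all-zero input -> all-zero output
  expect_equal(apply_admittance(adm, rep(0, 100)), rep(0, 100))
  # constant P converges to Q = P/(Rp+Zc)
  P <- 10e3
  n <- ceiling(8 * wk_time_constant(p) / adm$dt)
  Q <- apply_admittance(adm, rep(P, n))
  expect_equal(Q[n], P / (p$Rp + p$Zc), tolerance = 1e-4)
  # step response agrees with the trapezoidal state-space path; the filter
  # output sits at the trapezoidal midpoint of consecutive state samples
  st <- wk_state(Pp = 0, valve_open = TRUE, Q = P / p$Zc, params = p)
  Qs <- numeric(201)
  for (i in 1:201) {
    Qs[i] <- wk_flow(P, st, p)
    st <- wk_step_open(st, P, p, adm$dt)
  }
  mid <- (Qs[1:200] + Qs[2:201]) / 2
  expect_lt(max(abs(Q[6:200] - mid[6:200])) / max(abs(Qs)), 1e-3)
})

test_that("small Zc recovers 2-element behaviour and presets are exact", {
  p <- suppressWarnings(windkessel_params(14.5, 32, 14.5e-6))
  s <- wk_state(Pp = 9.99e3, valve_open = TRUE,
                Q = wk_flow(10e3, wk_state(Pp = 9.99e3), p), params = p)
  expect_equal(s$Pa - s$Pp, s$Q * p$Zc)      # tracks Pp within Zc*Q ...
  expect_lt((s$Pa - s$Pp) / s$Pa, 1.1e-3)    # ... which is tiny
  tbl <- wk_presets()
  expect_setequal(tbl$preset, c("normotensive", "hypertensive",
                                "hypotensive", "room_temp_base"))
  hypo <- wk_preset("hypotensive")
  expect_equal(c(hypo$Rp, hypo$C, hypo$Zc),
               c(9.18e9, 42e-12, 0.31e9), tolerance = 1e-15)
  room <- wk_preset("room_temp_base")
  expect_equal(c(room$Rp, room$C, room$Zc), c(150e9, 32e-12, 5e9),
               tolerance = 1e-15)
  expect_error(wk_preset("atrial"), class = "wkloop_unknown_preset")
})
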