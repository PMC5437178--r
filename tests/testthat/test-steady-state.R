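test_that("planar barrier flux is Fickian", {
  expect_equal(planar_flux(1e-6, 1, 0, 1), 1e-6)
  expect_equal(planar_flux(1e-6, 0.3, 0.3, 2), 0)          # no gradient
  expect_equal(planar_flux(1e-6, 1, 0, 2),
               planar_flux(1e-6, 1, 0, 1) / 2)             # thickness halves flux
  expect_lt(planar_flux(1e-6, 0, 1, 1), 0)                 # sign follows gradient
  expect_error(planar_flux(1e-6, 1, 0, 0), "positive")
})

test_that("saturation quotient has the closed exponential form", {
  expect_equal(steady_state_q(0, aleph = 2), 0)
  expect_equal(steady_state_q(0.5, aleph = 2), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(steady_state_q(1e6, aleph = 2), 1, tolerance = 1e-9)
  expect_equal(steady_state_flux(0, aleph = 2), 1)
  expect_equal(steady_state_flux(0.5, aleph = 2), exp(-1), tolerance = 1e-12)
})

test_that("quotient and relative flux are exactly complementary", {
  set.seed(42)
  aleph <- stats::runif(25, 0.1, 5)
  t <- stats::runif(25, 0, 10)
  kl <- stats::runif(25, 0.2, 3)
  expect_equal(steady_state_q(t, aleph, kl) + steady_state_flux(t, aleph, kl),
               rep(1, 25), tolerance = 1e-15)
})

test_that("quotient is monotone in rate parameters and bounded in [0, 1)", {
  t <- seq(0.01, 5, length.out = 40)
  q <- steady_state_q(t, aleph = 2)
  expect_true(all(diff(q) > 0))
  expect_true(all(q >= 0 & q < 1))
  expect_true(all(steady_state_q(1, seq(0.1, 5, 0.1)) ==
                  cummax(steady_state_q(1, seq(0.1, 5, 0.1)))))
  expect_gt(steady_state_q(1, 2, k_over_l = 2), steady_state_q(1, 2, 1))
})

test_that("flow time inverts the quotient and reproduces the turnover arithmetic", {
  q <- c(1e-4, 3.5e-3, 0.02, 0.3, 0.9)
  expect_equal(steady_state_q(flow_time_for_q(q, 2), 2), q, tolerance = 1e-12)
  # small-Q regime: doubling flow time ~ doubling the albumin quotient
  expect_equal(flow_time_for_q(7e-3, 2) / flow_time_for_q(3.5e-3, 2),
               2.0035, tolerance = 1e-3)
  # reaching 20e-3 from 2e-3 takes ~10x the flow time: ln(0.98)/ln(0.998)
  expect_equal(flow_time_for_q(20e-3, 2) / flow_time_for_q(2e-3, 2),
               log(1 - 20e-3) / log(1 - 2e-3), tolerance = 1e-12)
  expect_equal(flow_time_for_q(20e-3, 2) / flow_time_for_q(2e-3, 2),
               10.09, tolerance = 1e-3)
  expect_equal(flow_time_for_q(0, 2), 0)
  expect_error(flow_time_for_q(1, 2), "saturates")
})

test_that("discrete cascade starts at the single-segment steady state", {
  # first segment: C(E1)/C_blood = aleph/(L v)
  q <- cascade_q(aleph = 0.3, v = 10, n_segments = 1)
  expect_equal(q, 0.3 / 10, tolerance = 1e-12)
  expect_error(cascade_q(0.3, v = 0, n_segments = 5), "positive")
})

test_that("cascade quotients are nondecreasing, bounded, and converge to the closed form", {
  q <- cascade_q(aleph = 2, v = 100, n_segments = 50)
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= 1))
  # fixed total flow time t, refined segmentation: v = n/t
  for (t_total in c(0.25, 0.5, 2)) {
    n <- 1e4
    q_n <- cascade_q(aleph = 2, v = n / t_total, n_segments = n)[n]
    q_exact <- steady_state_q(t_total, aleph = 2)
    expect_lt(abs(q_n - q_exact) / q_exact, 1e-3)
  }
})

test_that("Stokes-Einstein diffusion scales inversely with hydrodynamic radius", {
  r <- c(1, 3.51, 5.29, 12.65)
  d <- stokes_einstein_d(r)
  expect_equal(d * r, rep(d[1] * r[1], 4), tolerance = 1e-12) # D*R constant
  expect_true(all(diff(d) < 0))
  # printed radii give the reference diffusion-coefficient quotients
  expect_equal(stokes_einstein_d(3.51) / stokes_einstein_d(5.29),
               5.29 / 3.51, tolerance = 1e-12)
  expect_equal(stokes_einstein_d(3.51) / stokes_einstein_d(5.29), 1.507,
               tolerance = 1e-3)
  expect_equal(stokes_einstein_d(3.51) / stokes_einstein_d(12.65), 3.604,
               tolerance = 1e-3)
  expect_error(stokes_einstein_d(0), "positive")
})

test_that("barrier quotient factorizes exchange ratios", {
  # albumin/IgG: aleph ratio 2/1.23 against radius ratio 5.29/3.51
  expect_equal(barrier_quotient(2 / 1.23, 5.29 / 3.51), 1.08,
               tolerance = 0.005)
  # albumin/IgM: barrier factors cancel out
  expect_equal(barrier_quotient(2 / 0.55, 12.65 / 3.51), 1.0,
               tolerance = 0.01)
  expect_equal(barrier_quotient(1, 1), 1)
  expect_error(barrier_quotient(-1, 1), "positive")
  # free diffusion: B ratio of 1 makes Q(aleph) the inverse radius quotient
  rhr <- 5.29 / 3.51
  expect_equal(barrier_quotient(rhr, rhr), 1, tolerance = 1e-12)
})

test_that("in-vivo hydrodynamic radius inference inverts the ratio algebra", {
  expect_equal(infer_rh(1, 3.51), 3.51)
  expect_equal(infer_rh(5.29 / 3.51, 3.51), 5.29, tolerance = 1e-12)
  # with the fitted exchange ratio under equal-B the radius comes out high;
  # dividing the barrier quotient back out recovers the measured radius
  r_equal_b <- infer_rh(2 / 1.23, 3.51)
  expect_equal(r_equal_b, 5.71, tolerance = 1e-3)
  b_ratio <- barrier_quotient(2 / 1.23, 5.29 / 3.51)
  expect_equal(infer_rh(2 / 1.23, 3.51, assume_equal_b = FALSE,
                        barrier_ratio = b_ratio), 5.29, tolerance = 1e-12)
  expect_error(infer_rh(1.5, 3.51, assume_equal_b = FALSE),
               "barrier_ratio")
  expect_warning(infer_rh(1.5, 3.51, barrier_ratio = 2), "ignored")
})

test_that("slow/fast quotient gradient rises monotonically toward 1", {
  t <- exp(seq(log(0.01), log(20), length.out = 200))
  ratio <- steady_state_q(t, aleph = 1.23) / steady_state_q(t, aleph = 2)
  expect_true(all(diff(ratio) > 0))
  expect_true(all(ratio < 1))
  expect_equal(ratio[length(ratio)], 1, tolerance = 1e-6)
})
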