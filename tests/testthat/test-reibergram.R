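test_that("hyperbolic curve evaluation matches the closed form", {
  igg_mean <- hyperbolic_params(0.65, 8e-6, 1.4e-3)
  # direct evaluations of (a/b)*sqrt(q^2 + b^2) - c
  expect_equal(hyperbolic_q(0, igg_mean), 0.65 * sqrt(8e-6) - 1.4e-3,
               tolerance = 1e-12)
  expect_equal(hyperbolic_q(0, igg_mean), 4.385e-4, tolerance = 1e-3)
  expect_equal(hyperbolic_q(5e-3, igg_mean),
               0.65 * sqrt(25e-6 + 8e-6) - 1.4e-3, tolerance = 1e-12)
  expect_equal(hyperbolic_q(5e-3, igg_mean), 2.334e-3, tolerance = 1e-3)
  # vectorized
  expect_length(hyperbolic_q(c(0.002, 0.005, 0.01), igg_mean), 3L)
})

test_that("hyperbolic evaluation rejects bad inputs", {
  expect_error(hyperbolic_params(-1, 1e-6, 0), "positive")
  expect_error(hyperbolic_params(1, 0, 0), "positive")
  expect_error(hyperbolic_params(1, 1e-6, -1), "non-negative")
  p <- hyperbolic_params(0.65, 8e-6, 1.4e-3)
  expect_error(hyperbolic_q(-1e-3, p), "non-negative")
  expect_error(hyperbolic_q(NA_real_, p), "finite")
})

test_that("recomputed variation coefficients reproduce the published grid", {
  grid <- variation_grid()
  for (an in c("IgG", "IgA")) {
    recomputed <- variation_coefficient(fams[[an]], grid$q_alb)
    expect_true(all(abs(recomputed - grid[[an]]) <= 0.03),
                info = sprintf("%s: max dev %.3f", an,
                               max(abs(recomputed - grid[[an]]))))
  }
  # IgM entries are printed at coarser precision; agreement holds at
  # integer rounding (e.g. recomputed 3.05 vs printed 3, 2.05 vs 2)
  igm <- variation_coefficient(fams$IgM, grid$q_alb)
  expect_equal(round(igm), round(grid$IgM))
  # spot values at the printed precision
  expect_equal(variation_coefficient(fams$IgG, 2.2e-3), 0.86,
               tolerance = 0.005)
  expect_equal(variation_coefficient(fams$IgA, 2.2e-3), 1.36,
               tolerance = 0.005)
  expect_equal(round(variation_coefficient(fams$IgM, 100e-3)), 2)
})

test_that("hyperbolic curves are strictly increasing in q_alb", {
  qa <- sort(stats::runif(50, 1e-4, 0.2))
  for (an in names(fams))
    for (curve in c("upper", "mean", "lower"))
      expect_true(all(diff(hyperbolic_q(qa, fams[[an]][[curve]])) > 0),
                  info = paste(an, curve))
})

test_that("packaged families keep upper > mean > lower across the window", {
  for (an in names(fams)) {
    fam <- fams[[an]]
    qa <- seq(fam$q_alb_range[1], fam$q_alb_range[2], length.out = 200)
    expect_true(all(hyperbolic_q(qa, fam$upper) > hyperbolic_q(qa, fam$mean)))
    expect_true(all(hyperbolic_q(qa, fam$mean) > hyperbolic_q(qa, fam$lower)))
  }
  # a family violating the ordering is rejected at construction
  expect_error(reibergram_family(
    "bad",
    upper = hyperbolic_params(0.3, 1e-6, 0),
    mean = hyperbolic_params(0.6, 1e-6, 0),
    lower = hyperbolic_params(0.1, 1e-6, 0)), "ordering")
})

test_that("variation coefficient fails on a degenerate (non-positive) mean curve", {
  fam <- reibergram_family(
    "degen",
    upper = hyperbolic_params(1, 1e-6, 0),
    mean = hyperbolic_params(0.5, 1e-6, 0.01),
    lower = hyperbolic_params(0.1, 1e-6, 0.02))
  expect_error(variation_coefficient(fam, 2.2e-3), "non-positive")
})

test_that("classification bands follow the discrimination curves", {
  fam <- fams$IgG
  up <- hyperbolic_q(5e-3, fam$upper)
  mid <- hyperbolic_q(5e-3, fam$mean)
  lo <- hyperbolic_q(5e-3, fam$lower)
  rec <- data.frame(id = c("hi", "on_mean", "low"), q_alb = 5e-3,
                    q_igg = c(1.1 * up, mid, 0.5 * lo))
  res <- classify_quotients(rec)
  expect_s3_class(res, "reibergram_classification")
  got <- res$band[match(c("hi", "on_mean", "low"), res$id)]
  expect_equal(got, c("above_upper", "within_reference", "below_lower"))
  expect_equal(res$ratio_to_mean[res$id == "on_mean"], 1, tolerance = 1e-12)
  expect_true(all(res$limit_q_upper > res$mean_q))
})

test_that("classification is total and explicit about missing analytes", {
  set.seed(1)
  rec <- data.frame(id = sprintf("p%d", 1:30),
                    q_alb = stats::runif(30, 2.5e-3, 0.12),
                    q_igg = stats::runif(30, 1e-4, 0.1),
                    q_igm = c(NA, stats::runif(29, 1e-5, 0.05)))
  res <- classify_quotients(rec)
  expect_true(all(res$band %in%
    c("above_upper", "within_reference", "below_lower", "missing")))
  # every present (record, analyte) pair got exactly one band
  expect_equal(nrow(res), 2L * 30L)  # IgG + IgM rows
  expect_equal(res$band[res$analyte == "IgM" & res$id == "p1"], "missing")
})

test_that("classification outside the calibrated window warns but classifies", {
  rec <- data.frame(id = "x", q_alb = 0.3, q_igg = 0.1)
  expect_warning(res <- classify_quotients(rec), "calibrated range")
  expect_false(res$in_calibrated_range)
  expect_true(res$band %in%
    c("above_upper", "within_reference", "below_lower"))
})
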