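b1_printed <- function() effect_estimate(0.23, se_from_ci(0.14, 0.31, "linear"),
                                         scale = "linear", term = "dose")
b2_printed <- function() effect_estimate(log(0.92), se_from_ci(0.62, 1.38, "log"),
                                         scale = "log_hazard", term = "dose")

test_that("an identity instrument passes the outcome estimate through", {
  b1 <- effect_estimate(1, 0.01, "linear")
  b2 <- effect_estimate(-0.3, 0.15, "log_hazard")
  w <- wald_ratio(b1, b2)
  expect_equal(w$beta3, -0.3)
  expect_equal(w$se3, 0.15)
})

test_that("a null outcome association gives a causal HR of exactly 1", {
  w <- wald_ratio(effect_estimate(0.23, 0.04, "linear"),
                  effect_estimate(0, 0.2, "log_hazard"))
  expect_identical(w$hr, 1)
})

test_that("the delta-method chain reproduces the hand-computed interval", {
  w <- wald_ratio(b1_printed(), b2_printed())
  expect_equal(w$outcome_beta2$se, 0.204112, tolerance = 1e-4)
  expect_equal(w$se3, 0.887443, tolerance = 1e-4)
  expect_equal(w$beta3, log(0.92) / 0.23, tolerance = 1e-12)
  expect_equal(round(w$ci_low, 3), 0.122)
})

test_that("the ratio obeys the sign rule and scale equivariance", {
  set.seed(51)
  for (i in 1:30) {
    b1 <- effect_estimate(runif(1, -1, 1), runif(1, 0.01, 0.2), "linear")
    if (abs(b1$beta) < 1e-3) next
    b2 <- effect_estimate(runif(1, -1, 1), runif(1, 0.01, 0.5), "log_hazard")
    w <- wald_ratio(b1, b2)
    expect_equal(sign(w$beta3), sign(b1$beta) * sign(b2$beta))
    b1d <- effect_estimate(2 * b1$beta, b1$se, "linear")
    w2 <- wald_ratio(b1d, b2)
    expect_equal(w2$beta3, w$beta3 / 2, tolerance = 1e-12)
    expect_equal(w2$se3, w$se3 / 2, tolerance = 1e-12)
    expect_equal(w$beta3 * b1$beta, b2$beta, tolerance = 1e-12)
  }
})

test_that("weak instruments and scale mismatches are rejected", {
  b2 <- effect_estimate(-0.1, 0.2, "log_hazard")
  expect_error(wald_ratio(effect_estimate(1e-9, 0.01, "linear"), b2), "weak")
  expect_error(wald_ratio(b2, b2), "scale mismatch")
  expect_error(wald_ratio(effect_estimate(0.2, 0.01, "linear"),
                          effect_estimate(0.1, 0.1, "log_odds")), "scale mismatch")
})

test_that("reported confidence intervals convert back to standard errors", {
  expect_equal(round(se_from_ci(0.62, 1.38, "log"), 5), 0.20411)
  expect_equal(round(se_from_ci(0.14, 0.31, "linear"), 5), 0.04337)
  expect_warning(s <- se_from_ci(1, 1, "log"), "degenerate")
  expect_equal(s, 0)
  expect_error(se_from_ci(-0.5, 1.2, "log"), "non-positive")
  expect_error(se_from_ci(2, 1, "log"), "out of order")
})

test_that("the delta SE matches Monte-Carlo when the instrument is treated as fixed", {
  b1 <- effect_estimate(0.23, 0, "linear")
  b2 <- b2_printed()
  d <- mr_delta_vs_montecarlo(b1, b2, reps = 20000, seed = 61)
  expect_equal(d$sd_mc, d$se_delta, tolerance = 0.03)
  expect_false(d$weak)
})

test_that("a weak instrument inflates the Monte-Carlo SD beyond the delta SE", {
  b1 <- effect_estimate(0.02, se_from_ci(0.14, 0.31, "linear"), "linear")
  b2 <- b2_printed()
  expect_warning(d <- mr_delta_vs_montecarlo(b1, b2, reps = 5000, seed = 62),
                 "weak")
  expect_gt(d$sd_mc, d$se_delta)
})
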