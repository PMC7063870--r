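# independent oracle: explicit Efron partial log-likelihood, evaluated
# directly from its definition (sums over risk sets), no shared code with
# the estimator
efron_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (t0 in unique(time[event == 1])) {
    D <- which(time == t0 & event == 1)
    R <- which(time >= t0)
    d <- length(D)
    s0d <- sum(exp(beta * x[D]))
    ll <- ll + sum(beta * x[D])
    for (l in seq_len(d)) {
      ll <- ll - log(sum(exp(beta * x[R])) - (l - 1) / d * s0d)
    }
  }
  ll
}

grid_max <- function(f, lo = -5, hi = 5) {
  for (pass in 1:6) {
    g <- seq(lo, hi, length.out = 201)
    v <- vapply(g, f, numeric(1))
    b <- g[which.max(v)]
    step <- g[2] - g[1]
    lo <- b - 2 * step; hi <- b + 2 * step
  }
  b
}

test_that("a swap-symmetric dataset forces the coefficient to zero", {
  time <- c(1, 1, 2, 2); event <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  f <- cox_fit(time, event, x)
  expect_lt(abs(f$coef[[1]]), 1e-8)
})

test_that("the estimator matches grid maximization of the partial likelihood", {
  # distinct event times
  time <- c(0.5, 1.2, 1.9, 2.3, 3.1, 3.8, 4.4, 5.0)
  event <- c(1, 1, 0, 1, 1, 0, 1, 1)
  x <- c(1, 0, 1, 1, 0, 0, 1, 0)
  f <- cox_fit(time, event, x)
  b_grid <- grid_max(function(b) efron_loglik(b, time, event, x))
  expect_lt(abs(f$coef[[1]] - b_grid), 1e-4)

  # tied event times exercise the Efron correction
  time2 <- c(1, 1, 1, 2, 2, 3, 3, 4, 5, 5)
  event2 <- c(1, 1, 0, 1, 1, 1, 0, 1, 1, 0)
  x2 <- c(1, 1, 0, 0, 1, 0, 1, 1, 0, 0)
  f2 <- cox_fit(time2, event2, x2)
  b_grid2 <- grid_max(function(b) efron_loglik(b, time2, event2, x2))
  expect_lt(abs(f2$coef[[1]] - b_grid2), 1e-4)
})

test_that("estimates agree with survival::coxph for both tie corrections", {
  skip_if_not_installed("survival")
  set.seed(31)
  n <- 250
  x <- rnorm(n); w <- rbinom(n, 1, 0.4)
  t <- rexp(n, exp(0.4 * x - 0.2 * w))
  cens <- runif(n, 0.2, 2.5)
  time <- round(pmin(t, cens), 1) + 0.05 # induce ties
  event <- as.integer(t <= cens)
  for (tie in c("efron", "breslow")) {
    f <- cox_fit(time, event, x, covariates = data.frame(w = w), ties = tie)
    s <- survival::coxph(survival::Surv(time, event) ~ x + w, ties = tie)
    expect_equal(unname(f$coef), unname(coef(s)), tolerance = 1e-7)
    expect_equal(unname(f$se), unname(sqrt(diag(vcov(s)))), tolerance = 1e-7)
  }
})

test_that("relabeling the covariate x -> 1 - x flips the coefficient sign", {
  set.seed(32)
  n <- 120
  x <- rbinom(n, 1, 0.5)
  t <- rexp(n, exp(0.6 * x))
  cens <- runif(n, 0.2, 2)
  time <- pmin(t, cens); event <- as.integer(t <= cens)
  f1 <- cox_fit(time, event, x)
  f2 <- cox_fit(time, event, 1 - x)
  expect_equal(f1$coef[[1]], -f2$coef[[1]], tolerance = 1e-8)
  expect_equal(f1$se[[1]], f2$se[[1]], tolerance = 1e-8)
})

test_that("the maximized partial likelihood never falls below its null value", {
  set.seed(33)
  for (i in 1:10) {
    n <- 60
    x <- rnorm(n)
    t <- rexp(n, exp(runif(1, -0.5, 0.5) * x))
    cens <- runif(n, 0.2, 2)
    time <- pmin(t, cens); event <- as.integer(t <= cens)
    if (sum(event) == 0) next
    f <- cox_fit(time, event, x)
    expect_gte(f$loglik[["final"]], f$loglik[["null"]])
  }
})

test_that("degenerate survival inputs are flagged or rejected", {
  expect_error(cox_fit(c(1, 2), c(0, 0), c(0, 1)), "no events")
  expect_error(cox_fit(c(-1, 2), c(1, 1), c(0, 1)), "positive")
  # monotone likelihood: the only events sit at the covariate extreme
  time <- c(1, 2, 3, 4, 5, 6)
  event <- c(1, 1, 0, 0, 0, 0)
  x <- c(1, 1, 0, 0, 0, 0)
  f <- cox_fit(time, event, x)
  expect_false(f$converged)
})

test_that("the log-hazard and its SE are recovered in simulation", {
  set.seed(34)
  reps <- 30
  beta <- matrix(NA_real_, reps, 2)
  for (i in seq_len(reps)) {
    n <- 2000
    x <- rnorm(n)
    t <- rexp(n, 0.1 * exp(0.5 * x))
    cens <- rexp(n, 0.045) # ~30% censoring
    time <- pmin(t, cens); event <- as.integer(t <= cens)
    f <- cox_fit(time, event, x)
    beta[i, ] <- c(f$coef[[1]], f$se[[1]])
  }
  expect_lt(abs(mean(beta[, 1]) - 0.5), 0.05)
  # model-based SE tracks the sampling SD
  expect_equal(mean(beta[, 2]), sd(beta[, 1]), tolerance = 0.25)
})
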