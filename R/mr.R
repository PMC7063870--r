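#' Single-instrument Wald-ratio causal estimate
#'
#' Combines the instrument-exposure coefficient `beta1` (per-allele shift in
#' the standardized exposure, SD units) and the instrument-outcome
#' log-hazard coefficient `beta2` into the Wald-ratio causal estimate
#' `beta3 = beta2 / beta1`, the causal log-hazard per SD of exposure. The
#' standard error is the first-order delta approximation
#' `se3 = se2 / |beta1|`, which treats the instrument-exposure coefficient as
#' fixed; the causal hazard ratio is `exp(beta3)` with 95% CI
#' `exp(beta3 +/- 1.96 * se3)`. [mr_delta_vs_montecarlo()] quantifies when
#' this approximation understates the sampling spread (weak instruments).
#'
#' @param beta1 [effect_estimate] on the `"linear"` scale: per-allele effect
#'   on the SD-standardized exposure.
#' @param beta2 [effect_estimate] on the `"log_hazard"` scale: per-allele
#'   log-hazard for the outcome.
#' @param outcome_name optional outcome label carried into the result.
#' @param weak_floor smallest admissible `|beta1|` (default `1e-6`).
#' @return an object of class `mr_result` with `beta3`, `se3`, `hr`,
#'   `ci_low`, `ci_high`, the two input estimates, the first-stage F
#'   statistic `instrument_F` (reported, never gating), and `outcome_name`.
#' @examples
#' b1 <- effect_estimate(0.23, se_from_ci(0.14, 0.31, "linear"), "linear")
#' b2 <- effect_estimate(log(0.92), se_from_ci(0.62, 1.38, "log"), "log_hazard")
#' wald_ratio(b1, b2) # causal HR 0.70
#' @export
wald_ratio <- function(beta1, beta2, outcome_name = NA_character_,
                       weak_floor = 1e-6) {
  stopifnot(inherits(beta1, "effect_estimate"), inherits(beta2, "effect_estimate"))
  if (beta1$scale != "linear") {
    stop("wald_ratio(): scale mismatch; 'beta1' must be on the linear (exposure-SD) scale")
  }
  if (beta2$scale != "log_hazard") {
    stop("wald_ratio(): scale mismatch; 'beta2' must be on the log-hazard scale")
  }
  if (!is.finite(beta1$beta) || abs(beta1$beta) < weak_floor) {
    stop("wald_ratio(): instrument-exposure coefficient below the weak-instrument floor")
  }
  beta3 <- beta2$beta / beta1$beta
  se3 <- beta2$se / abs(beta1$beta)
  Fstat <- if (!is.na(beta1$se) && beta1$se > 0) (beta1$beta / beta1$se)^2 else NA_real_
  structure(
    list(beta3 = beta3, se3 = se3, hr = exp(beta3),
         ci_low = exp(beta3 - 1.96 * se3), ci_high = exp(beta3 + 1.96 * se3),
         instrument_beta1 = beta1, outcome_beta2 = beta2,
         instrument_F = Fstat, outcome_name = outcome_name),
    class = "mr_result"
  )
}

#' @export
print.mr_result <- function(x, digits = 4, ...) {
  cat("Wald-ratio Mendelian randomization estimate")
  if (!is.na(x$outcome_name)) cat(sprintf(" [outcome: %s]", x$outcome_name))
  cat("\n")
  cat(sprintf("  causal log-HR per SD exposure: %s (SE %s)\n",
              format(x$beta3, digits = digits), format(x$se3, digits = digits)))
  cat(sprintf("  causal HR: %s, 95%% CI: %s to %s\n",
              format(x$hr, digits = digits),
              format(x$ci_low, digits = digits), format(x$ci_high, digits = digits)))
  if (!is.na(x$instrument_F)) {
    cat(sprintf("  first-stage F: %.1f\n", x$instrument_F))
  }
  invisible(x)
}

#' Standard error reconstructed from a reported 95% confidence interval
#'
#' Published ratio-scale intervals (hazard/odds ratios) are converted back to
#' the standard error of the log coefficient as
#' `(log(high) - log(low)) / (2 * 1.96)`; linear-scale intervals as
#' `(high - low) / (2 * 1.96)`.
#'
#' @param low,high reported 95% bounds.
#' @param scale `"log"` for ratio-scale bounds, `"linear"` otherwise.
#' @return the implied standard error.
#' @examples
#' se_from_ci(0.62, 1.38, "log")    # 0.20411
#' se_from_ci(0.14, 0.31, "linear") # 0.04337
#' @export
se_from_ci <- function(low, high, scale = c("log", "linear")) {
  scale <- match.arg(scale)
  if (low > high) stop("se_from_ci(): bounds out of order")
  if (scale == "log" && low <= 0) stop("se_from_ci(): non-positive bound on ratio scale")
  if (low == high) {
    warning("se_from_ci(): degenerate interval; returning se = 0")
    return(0)
  }
  if (scale == "log") (log(high) - log(low)) / 3.92 else (high - low) / 3.92
}

#' Monte-Carlo check of the delta-method standard error
#'
#' Draws `(beta2*, beta1*)` from independent normals centred at the point
#' estimates with their standard errors, recomputes the ratio
#' `beta2*/beta1*`, and compares the empirical SD of the simulated ratios to
#' the delta-method `se3 = se2/|beta1|`. With a strong instrument (or with
#' `beta1`'s SE forced to zero, where the delta assumption is exact) the two
#' agree; with a weak instrument the ratio distribution is heavy-tailed and
#' the delta SE understates the Monte-Carlo SD, which is flagged with a
#' warning.
#'
#' @param beta1,beta2 [effect_estimate]s as in [wald_ratio()].
#' @param reps number of Monte-Carlo draws (>= 100).
#' @param seed optional integer seed; RNG state is restored afterwards.
#' @return list with `se_delta`, `sd_mc`, `ratio` (`sd_mc / se_delta`),
#'   `reps`, and `weak` (logical).
#' @export
mr_delta_vs_montecarlo <- function(beta1, beta2, reps = 10000L, seed = NULL) {
  if (reps < 100L) stop("mr_delta_vs_montecarlo(): reps must be >= 100")
  wr <- wald_ratio(beta1, beta2)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  s1 <- if (is.na(beta1$se)) 0 else beta1$se
  b1 <- stats::rnorm(reps, beta1$beta, s1)
  b2 <- stats::rnorm(reps, beta2$beta, beta2$se)
  sd_mc <- stats::sd(b2 / b1)
  ratio <- sd_mc / wr$se3
  weak <- is.finite(ratio) && ratio > 1.5
  if (weak) {
    warning("mr_delta_vs_montecarlo(): delta-method SE understates the Monte-Carlo SD; ",
            "the instrument is likely weak")
  }
  list(se_delta = wr$se3, sd_mc = sd_mc, ratio = ratio, reps = reps, weak = weak)
}
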