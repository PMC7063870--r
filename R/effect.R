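#' Effect estimate container
#'
#' A light S3 container for a single regression coefficient with its standard
#' error, 95% confidence interval, and p-value. Linear-scale estimates carry a
#' CI on the coefficient scale; log-hazard and log-odds estimates carry a CI on
#' the exponentiated (ratio) scale, i.e. `exp(beta +/- 1.96 * se)`.
#'
#' @param beta coefficient on the model's linear scale (log-hazard for Cox,
#'   log-odds for logistic, exposure-SD units per allele for linear).
#' @param se standard error of `beta`; must be non-negative.
#' @param scale one of `"linear"`, `"log_hazard"`, `"log_odds"`.
#' @param term name of the coefficient (informational).
#' @param n number of subjects used in the fit.
#' @param events number of events (Cox fits only).
#' @param p_value two-sided p-value; computed as a Wald test if missing and
#'   `se > 0`.
#' @param converged logical; `FALSE` flags separation / monotone-likelihood
#'   fits whose Wald quantities are unreliable.
#' @return an object of class `effect_estimate`.
#' @export
effect_estimate <- function(beta, se, scale = c("linear", "log_hazard", "log_odds"),
                            term = "x", n = NA_integer_, events = NA_integer_,
                            p_value = NULL, converged = TRUE) {
  scale <- match.arg(scale)
  beta <- unname(beta); se <- unname(se)
  stopifnot(is.numeric(beta), length(beta) == 1L, is.numeric(se), length(se) == 1L)
  if (!is.na(se) && se < 0) stop("'se' must be non-negative")
  if (is.null(p_value)) {
    p_value <- if (!is.na(se) && se > 0) 2 * stats::pnorm(-abs(beta / se)) else NA_real_
  }
  ci <- ci_bounds(beta, se, scale)
  structure(
    list(term = term, beta = beta, se = se,
         ci_low = ci[1L], ci_high = ci[2L],
         p_value = p_value, scale = scale,
         n = n, events = events, converged = converged),
    class = "effect_estimate"
  )
}

# 95% bounds on the reported scale; z multiplier fixed at 1.96
ci_bounds <- function(beta, se, scale) {
  lo <- beta - 1.96 * se
  hi <- beta + 1.96 * se
  if (scale == "linear") c(lo, hi) else exp(c(lo, hi))
}

#' @export
print.effect_estimate <- function(x, digits = 4, ...) {
  lab <- switch(x$scale,
                linear = "beta", log_hazard = "log HR", log_odds = "log OR")
  cat(sprintf("Effect estimate for '%s' (%s scale)\n", x$term, x$scale))
  cat(sprintf("  %s = %s (SE %s), p = %s\n", lab,
              format(x$beta, digits = digits), format(x$se, digits = digits),
              format.pval(x$p_value, digits = digits)))
  if (x$scale == "linear") {
    cat(sprintf("  95%% CI: %s to %s\n",
                format(x$ci_low, digits = digits), format(x$ci_high, digits = digits)))
  } else {
    rat <- if (x$scale == "log_hazard") "HR" else "OR"
    cat(sprintf("  %s = %s, 95%% CI: %s to %s\n", rat,
                format(exp(x$beta), digits = digits),
                format(x$ci_low, digits = digits), format(x$ci_high, digits = digits)))
  }
  if (!is.na(x$n)) cat(sprintf("  n = %d%s\n", x$n,
                               if (!is.na(x$events)) sprintf(", events = %d", x$events) else ""))
  if (!isTRUE(x$converged)) cat("  WARNING: fit did not converge; estimate unreliable\n")
  invisible(x)
}

#' @export
as.data.frame.effect_estimate <- function(x, ...) {
  data.frame(term = x$term, beta = x$beta, se = x$se,
             ci_low = x$ci_low, ci_high = x$ci_high, p = x$p_value,
             scale = x$scale, n = x$n, events = x$events,
             stringsAsFactors = FALSE)
}
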