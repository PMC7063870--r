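#' Linear association of an exposure with genotype dose
#'
#' Ordinary least squares of the (standardized) exposure on the additive
#' genotype dose, optionally adjusting for covariates. The reported
#' coefficient is the per-allele shift in the exposure, in the exposure's
#' units (SD units when the exposure was z-standardized). The 95% CI is
#' `beta +/- 1.96 * se`.
#'
#' @param y numeric response (exposure values).
#' @param x numeric primary regressor (genotype dose 0/1/2).
#' @param covariates optional data frame or matrix of adjustment covariates.
#' @return an [effect_estimate] on the `"linear"` scale.
#' @export
linear_fit <- function(y, x, covariates = NULL) {
  if (stats::var(x) == 0) stop("linear_fit(): 'x' is constant")
  X <- design_matrix(x, covariates)
  if (length(y) <= ncol(X) + 1L) stop("linear_fit(): too few observations")
  fit <- stats::lm(y ~ X)
  cf <- stats::coef(fit)
  if (anyNA(cf)) {
    stop("linear_fit(): rank-deficient design; collinear column(s): ",
         paste(sub("^X", "", names(cf)[is.na(cf)]), collapse = ", "))
  }
  sm <- summary(fit)$coefficients
  effect_estimate(beta = sm[2L, 1L], se = sm[2L, 2L], scale = "linear",
                  term = "dose", n = length(y),
                  p_value = sm[2L, 4L])
}

#' Logistic association of a binary trait with genotype dose
#'
#' Maximum-likelihood logistic regression of a binary covariate on the
#' additive genotype dose; the coefficient is the per-allele log-odds with a
#' Wald standard error. Complete or quasi-complete separation is detected and
#' flagged (`converged = FALSE`) rather than reported as a finite estimate.
#'
#' @param y binary response (0/1).
#' @param x numeric genotype dose.
#' @return an [effect_estimate] on the `"log_odds"` scale.
#' @export
logistic_fit <- function(y, x) {
  if (length(unique(y[!is.na(y)])) < 2L) {
    stop("logistic_fit(): both outcome classes must be present")
  }
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  sm <- summary(fit)$coefficients
  beta <- sm["x", 1L]; se <- sm["x", 2L]
  converged <- fit$converged && !sep && abs(beta) < 10 && se < 100
  effect_estimate(beta = beta, se = se, scale = "log_odds", term = "dose",
                  n = length(y), p_value = sm["x", 4L], converged = converged)
}

# column-bind primary regressor and covariates into a named numeric matrix
design_matrix <- function(x, covariates = NULL, xname = "x") {
  X <- matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, xname))
  if (!is.null(covariates)) {
    cv <- as.matrix(as.data.frame(covariates))
    storage.mode(cv) <- "double"
    if (is.null(colnames(cv))) colnames(cv) <- paste0("z", seq_len(ncol(cv)))
    X <- cbind(X, cv)
  }
  X
}
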