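#' Pearson chi-square test of Hardy-Weinberg equilibrium
#'
#' Given genotype counts (n0, n1, n2) for 0/1/2 copies of the effect allele,
#' estimates the allele frequency `p = (2*n2 + n1) / (2*n)` and compares the
#' observed counts to the Hardy-Weinberg expectation
#' `n * ((1-p)^2, 2*p*(1-p), p^2)` with a Pearson chi-square statistic on one
#' degree of freedom. No continuity correction is applied.
#'
#' @param n0,n1,n2 non-negative genotype counts.
#' @return an object of class `hwe_test` with elements `observed`, `p_hat`,
#'   `expected`, `statistic`, `df` and `p_value`.
#' @examples
#' hwe_test(30, 40, 30) # chi2 = 4, p ~ 0.0455
#' @export
hwe_test <- function(n0, n1, n2) {
  obs <- c(n0, n1, n2)
  if (anyNA(obs) || any(obs < 0)) stop("hwe_test(): counts must be non-negative")
  n <- sum(obs)
  if (n < 1) stop("hwe_test(): no observations")
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) stop("hwe_test(): monomorphic genotypes; test undefined")
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  chi2 <- sum((obs - expected)^2 / expected)
  structure(
    list(observed = obs, p_hat = p, expected = expected,
         statistic = chi2, df = 1L,
         p_value = stats::pchisq(chi2, df = 1L, lower.tail = FALSE)),
    class = "hwe_test"
  )
}

#' @export
print.hwe_test <- function(x, digits = 4, ...) {
  cat("Hardy-Weinberg equilibrium (Pearson chi-square, 1 df)\n")
  cat(sprintf("  observed: %s   effect-allele freq: %.4f\n",
              paste(x$observed, collapse = "/"), x$p_hat))
  cat(sprintf("  expected: %s\n",
              paste(format(x$expected, digits = digits), collapse = "/")))
  cat(sprintf("  chi2 = %s, p = %s\n", format(x$statistic, digits = digits),
              format.pval(x$p_value, digits = digits)))
  invisible(x)
}
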