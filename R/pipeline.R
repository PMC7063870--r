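#' Run the full observational + Mendelian randomization analysis
#'
#' For each requested outcome the pipeline builds the incident cohort
#' ([build_cohort()]), standardizes baseline uric acid by 5-year age bands,
#' and fits:
#'
#' 1. `beta1`: linear per-allele effect of genotype dose on the standardized
#'    exposure ([linear_fit()], unadjusted);
#' 2. `beta2`: Cox per-allele log-hazard of the outcome for genotype dose
#'    ([cox_fit()]);
#' 3. observational exposure-outcome Cox fits, unadjusted and adjusted for
#'    age, baseline indicators of the components other than the target
#'    outcome, and the three drug flags (smoking/drinking are not adjusted
#'    for; constant covariates are dropped);
#' 4. the Wald-ratio causal estimate ([wald_ratio()]).
#'
#' Genotype Hardy-Weinberg equilibrium is tested once on the full sample.
#' Subjects missing genotype or a covariate are dropped per fit
#' (complete-case), with counts in the per-outcome log. A failure in one
#' outcome is recorded and the remaining outcomes still run.
#'
#' @param records longitudinal check-up data frame, or a path to a CSV in
#'   the [cohort_schema] layout.
#' @param outcomes outcomes to analyse (default: all five).
#' @param seed optional integer recorded in the provenance (the analysis
#'   itself is deterministic).
#' @return an object of class `analysis_report`.
#' @export
run_analysis <- function(records, outcomes = OUTCOMES, seed = NULL) {
  if (is.character(records)) records <- read_cohort_csv(records)
  outcomes <- match.arg(outcomes, OUTCOMES, several.ok = TRUE)

  first <- !duplicated(records$subject_id)
  doses <- records$geno_dose[first]
  doses <- doses[!is.na(doses)]
  hwe <- tryCatch(hwe_test(sum(doses == 0), sum(doses == 1), sum(doses == 2)),
                  error = function(e) e)

  blocks <- lapply(outcomes, function(oc) {
    tryCatch(analyse_outcome(records, oc), error = function(e) {
      list(outcome = oc, error = conditionMessage(e))
    })
  })
  names(blocks) <- outcomes

  structure(
    list(outcomes = blocks, hwe = hwe,
         provenance = list(
           n_records = nrow(records),
           n_subjects = sum(first),
           seed = seed,
           package_version = as.character(utils::packageVersion("uramr")),
           timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE))),
    class = "analysis_report"
  )
}

# adjustment set: age + baseline component indicators other than the target
# + the three drug-use flags (constant columns dropped)
adjustment_covariates <- function(cohort, outcome) {
  comp <- setdiff(setdiff(OUTCOMES, "mets"), outcome)
  cols <- c("age", comp, "drug_glucose", "drug_bp", "drug_lipid")
  cv <- as.data.frame(cohort)[, cols, drop = FALSE]
  keep <- vapply(cv, function(v) stats::var(v) > 0, logical(1L))
  cv[, keep, drop = FALSE]
}

analyse_outcome <- function(records, oc) {
  cohort <- build_cohort(records, outcome = oc)
  ok <- !is.na(cohort$geno_dose)
  n_dropped <- sum(!ok)
  ch <- cohort[ok, , drop = FALSE]
  events <- sum(ch$event)
  py <- sum(ch$time)

  beta1 <- linear_fit(ch$ua_z, ch$geno_dose)
  beta2_fit <- cox_fit(ch$time, ch$event, ch$geno_dose)
  obs_fit <- cox_fit(ch$time, ch$event, ch$ua_z)
  adj_fit <- cox_fit(ch$time, ch$event, ch$ua_z,
                     covariates = adjustment_covariates(ch, oc))
  mr <- wald_ratio(beta1, beta2_fit$estimate, outcome_name = oc)

  list(outcome = oc,
       n = nrow(ch), events = events, censored = nrow(ch) - events,
       person_years = py,
       incidence_density = incidence_density(events, py),
       exclusions = c(attr(cohort, "exclusions"), missing_genotype = n_dropped),
       beta1 = beta1,
       beta2 = beta2_fit$estimate,
       observational = obs_fit$estimate,
       observational_adjusted = adj_fit$estimate,
       mr = mr)
}

#' Replace the ingredients of a report's IV estimate and recompute it
#'
#' Recompute hook: substitutes externally supplied `beta1` and/or `beta2`
#' effect estimates (for example, coefficients transcribed from a published
#' table) into one outcome block and recomputes the Wald ratio.
#'
#' @param report an `analysis_report`.
#' @param outcome outcome block to update.
#' @param beta1,beta2 optional [effect_estimate] replacements.
#' @return the updated report.
#' @export
recompute_iv <- function(report, outcome, beta1 = NULL, beta2 = NULL) {
  stopifnot(inherits(report, "analysis_report"), outcome %in% names(report$outcomes))
  blk <- report$outcomes[[outcome]]
  if (!is.null(blk$error)) stop("recompute_iv(): outcome block carries an error")
  if (!is.null(beta1)) blk$beta1 <- beta1
  if (!is.null(beta2)) blk$beta2 <- beta2
  blk$mr <- wald_ratio(blk$beta1, blk$beta2, outcome_name = outcome)
  report$outcomes[[outcome]] <- blk
  report
}

#' Forest-plot export of a report
#'
#' Flattens a report into the machine-readable twin of a forest plot: one
#' row per outcome and model, in fixed order (outcomes as analysed; models
#' `observational`, `observational_adjusted`, `iv`), with the hazard ratio
#' and its 95% bounds. At export time the IV rows are recomputed from the
#' report's own `beta1`/`beta2` entries and compared with the stored result
#' as an internal consistency check.
#'
#' @param report an `analysis_report`.
#' @param path optional TSV output path.
#' @return data frame with columns `outcome`, `model`, `hr`, `ci_low`,
#'   `ci_high`.
#' @export
export_forest <- function(report, path = NULL) {
  stopifnot(inherits(report, "analysis_report"))
  rows <- list()
  for (blk in report$outcomes) {
    if (!is.null(blk$error)) {
      warning(sprintf("export_forest(): outcome '%s' incomplete (%s); skipped",
                      blk$outcome, blk$error))
      next
    }
    check <- wald_ratio(blk$beta1, blk$beta2, outcome_name = blk$outcome)
    if (abs(check$beta3 - blk$mr$beta3) > 1e-12) {
      stop("export_forest(): IV estimate inconsistent with the report's own beta1/beta2")
    }
    est <- function(e) c(exp(e$beta), e$ci_low, e$ci_high)
    rows[[length(rows) + 1L]] <- data.frame(
      outcome = blk$outcome,
      model = c("observational", "observational_adjusted", "iv"),
      rbind(est(blk$observational), est(blk$observational_adjusted),
            c(blk$mr$hr, blk$mr$ci_low, blk$mr$ci_high)),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  names(out) <- c("outcome", "model", "hr", "ci_low", "ci_high")
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  out
}

#' Serialize a report to JSON
#'
#' Flat JSON rendering of every estimate in a report (term, beta, se, CI, p,
#' scale, n, events), the per-outcome cohort summaries, the HWE test and the
#' provenance block.
#'
#' @param report an `analysis_report`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_results <- function(report, path) {
  stopifnot(inherits(report, "analysis_report"))
  ser_est <- function(e) e[c("term", "beta", "se", "ci_low", "ci_high",
                             "p_value", "scale", "n", "events", "converged")]
  blocks <- lapply(report$outcomes, function(blk) {
    if (!is.null(blk$error)) return(list(outcome = blk$outcome, error = blk$error))
    list(outcome = blk$outcome, n = blk$n, events = blk$events,
         person_years = blk$person_years,
         incidence_density = blk$incidence_density,
         exclusions = as.list(blk$exclusions),
         beta1 = ser_est(blk$beta1), beta2 = ser_est(blk$beta2),
         observational = ser_est(blk$observational),
         observational_adjusted = ser_est(blk$observational_adjusted),
         mr = list(beta3 = blk$mr$beta3, se3 = blk$mr$se3, hr = blk$mr$hr,
                   ci_low = blk$mr$ci_low, ci_high = blk$mr$ci_high,
                   instrument_F = blk$mr$instrument_F))
  })
  hwe <- if (inherits(report$hwe, "hwe_test")) {
    list(observed = report$hwe$observed, p_hat = report$hwe$p_hat,
         chi2 = report$hwe$statistic, p_value = report$hwe$p_value)
  } else list(error = conditionMessage(report$hwe))
  jsonlite::write_json(list(outcomes = blocks, hwe = hwe,
                            provenance = report$provenance),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @export
print.analysis_report <- function(x, digits = 3, ...) {
  cat("Mendelian randomization analysis report\n")
  cat(sprintf("  %d subjects, %d records\n",
              x$provenance$n_subjects, x$provenance$n_records))
  if (inherits(x$hwe, "hwe_test")) {
    cat(sprintf("  HWE: chi2 = %.3f, p = %.3f\n", x$hwe$statistic, x$hwe$p_value))
  }
  for (blk in x$outcomes) {
    if (!is.null(blk$error)) {
      cat(sprintf("  [%s] ERROR: %s\n", blk$outcome, blk$error))
      next
    }
    cat(sprintf("  [%s] n = %d, events = %d, %.1f PY, incidence %.2f/1000 PY\n",
                blk$outcome, blk$n, blk$events, blk$person_years,
                blk$incidence_density))
    cat(sprintf("      beta1 = %.3f (SE %.3f); SNP->outcome HR = %.3f\n",
                blk$beta1$beta, blk$beta1$se, exp(blk$beta2$beta)))
    cat(sprintf("      obs HR = %.3f (%.3f-%.3f), adj HR = %.3f (%.3f-%.3f)\n",
                exp(blk$observational$beta), blk$observational$ci_low,
                blk$observational$ci_high,
                exp(blk$observational_adjusted$beta),
                blk$observational_adjusted$ci_low,
                blk$observational_adjusted$ci_high))
    cat(sprintf("      IV (causal) HR = %.3f (%.3f-%.3f)\n",
                blk$mr$hr, blk$mr$ci_low, blk$mr$ci_high))
  }
  invisible(x)
}

#' @export
summary.analysis_report <- function(object, ...) export_forest(object)
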