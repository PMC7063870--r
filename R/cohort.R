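#' Build an analysis-ready incident cohort for one outcome
#'
#' Turns longitudinal check-up records into a one-row-per-subject survival
#' cohort for a target outcome. The first record of each subject is the
#' baseline. Subjects are excluded (and counted in the exclusions log) when
#' they have fewer than two records, are aged 20 or less at baseline, have
#' metabolic syndrome or (when a `cvd` column is present) self-reported
#' cardio-/cerebrovascular disease at baseline, or already have the target
#' outcome at baseline. The event time is the time from baseline to the first
#' check-up at which [phenotype()] flags the target outcome (right-endpoint
#' imputation of the interval-censored onset); subjects without an event are
#' censored at their last check-up.
#'
#' Baseline serum uric acid is standardized within the retained cohort by
#' 5-year age bands via [standardize_exposure()] and returned as `ua_z`.
#'
#' @param records longitudinal data frame in the check-up schema (see
#'   [read_cohort_csv()]); must contain `subject_id`, `visit_time` (years,
#'   strictly increasing within subject), `age`, the phenotyping fields, and
#'   `uric_acid`; `geno_dose` and `cvd` are carried through when present.
#' @param outcome one of `r paste0('"', OUTCOMES, '"', collapse = ", ")`.
#' @param standardize logical; compute `ua_z` (default `TRUE`).
#' @return a data frame of class `analysis_cohort` with baseline fields,
#'   baseline phenotype flags, `time` (years), `event` (0/1) and `ua_z`;
#'   attributes `outcome`, `exclusions` (named counts) and `person_years`.
#' @export
build_cohort <- function(records, outcome = OUTCOMES, standardize = TRUE) {
  outcome <- match.arg(outcome)
  need <- c("subject_id", "visit_time", "age")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("build_cohort(): missing column(s): ", paste(miss, collapse = ", "))

  ord <- order(records$subject_id, records$visit_time)
  records <- records[ord, , drop = FALSE]
  sid <- records$subject_id
  if (any(tapply(records$visit_time, sid, function(t) any(diff(t) <= 0)))) {
    stop("build_cohort(): visit times not strictly increasing within subject")
  }

  flags <- phenotype(records)
  n_rec <- tapply(sid, sid, length)
  first <- !duplicated(sid)
  base <- records[first, , drop = FALSE]
  base_flags <- flags[first, , drop = FALSE]
  rownames(base) <- rownames(base_flags) <- NULL
  key <- base$subject_id

  excl <- c(lt2_records = 0L, age_le_20 = 0L, baseline_mets_or_cvd = 0L,
            baseline_outcome = 0L)
  keep <- rep(TRUE, nrow(base))

  few <- n_rec[match(key, names(n_rec))] < 2L
  excl["lt2_records"] <- sum(few)
  keep <- keep & !few

  young <- base$age <= 20
  excl["age_le_20"] <- sum(keep & young)
  keep <- keep & !young

  cvd <- if ("cvd" %in% names(base)) base$cvd == 1 else rep(FALSE, nrow(base))
  prev_parent <- base_flags$mets == 1L | cvd
  excl["baseline_mets_or_cvd"] <- sum(keep & prev_parent)
  keep <- keep & !prev_parent

  if (outcome != "mets") {
    prev_target <- base_flags[[outcome]] == 1L
    excl["baseline_outcome"] <- sum(keep & prev_target)
    keep <- keep & !prev_target
  }

  base <- base[keep, , drop = FALSE]
  base_flags <- base_flags[keep, , drop = FALSE]
  kept <- base$subject_id

  # first post-baseline visit flagging the target, else censor at last visit
  rec_keep <- records[sid %in% kept, , drop = FALSE]
  flag_keep <- flags[sid %in% kept, , drop = FALSE]
  sid_k <- rec_keep$subject_id
  t_rel <- rec_keep$visit_time - ave(rec_keep$visit_time, sid_k, FUN = function(x) x[1L])
  hit <- flag_keep[[outcome]] == 1L & t_rel > 0
  ev_time <- tapply(ifelse(hit, t_rel, NA_real_), sid_k, function(x) {
    if (all(is.na(x))) NA_real_ else min(x, na.rm = TRUE)
  })
  last_time <- tapply(t_rel, sid_k, max)
  m <- match(kept, names(ev_time))
  event <- as.integer(!is.na(ev_time[m]))
  time <- ifelse(event == 1L, ev_time[m], last_time[match(kept, names(last_time))])
  names(time) <- NULL

  out <- cbind(base, base_flags, time = time, event = event)
  if (standardize && nrow(out) >= 2L && "uric_acid" %in% names(out)) {
    out$ua_z <- as.numeric(standardize_exposure(out$uric_acid, out$age))
  }
  rownames(out) <- NULL
  structure(out,
            outcome = outcome,
            exclusions = excl,
            person_years = sum(time),
            class = c("analysis_cohort", "data.frame"))
}

#' @export
print.analysis_cohort <- function(x, ...) {
  ex <- attr(x, "exclusions")
  cat(sprintf("Analysis cohort for outcome '%s': %d subjects, %d events, %.1f person-years\n",
              attr(x, "outcome"), nrow(x), sum(x$event), attr(x, "person_years")))
  cat(sprintf("Incidence density: %.2f / 1000 person-years\n",
              incidence_density(sum(x$event), attr(x, "person_years"))))
  cat("Exclusions:", paste(sprintf("%s=%d", names(ex), ex), collapse = ", "), "\n")
  cat("First rows:\n")
  print.data.frame(utils::head(as.data.frame(x)))
  invisible(x)
}
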