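#' Metabolic-syndrome phenotyping (Chinese Diabetes Society 2004 criteria)
#'
#' Classifies check-up records into the four metabolic-syndrome component
#' phenotypes and the syndrome itself. A subject has metabolic syndrome when
#' three or more of the following hold:
#'
#' * overweight/obesity: BMI >= 25.0 kg/m^2;
#' * hyperglycemia: fasting glucose >= 6.1 mmol/L, or 2-hour postload glucose
#'   >= 7.8 mmol/L (when measured), or current glucose-lowering treatment;
#' * hypertension: SBP >= 140 mmHg or DBP >= 90 mmHg, or current
#'   antihypertensive treatment;
#' * dyslipidemia: TG >= 1.7 mmol/L, or HDL-c < 1.0 mmol/L (women) /
#'   < 0.9 mmol/L (men).
#'
#' A missing 2-hour postload glucose is treated as non-contributory (routine
#' check-ups rarely measure it); the fasting and treatment clauses suffice.
#' Lipid-lowering treatment does not enter the dyslipidemia definition.
#'
#' @param records data frame of check-up records with columns `bmi`, `fpg`,
#'   `sbp`, `dbp`, `tg`, `hdl`, `sex` (`"female"`/`"male"`), `drug_glucose`,
#'   `drug_bp` (0/1), and optionally `pg2h` (may be `NA`).
#' @return data frame with logical-as-integer columns `overweight_obesity`,
#'   `hyperglycemia`, `hypertension`, `dyslipidemia`, the component count
#'   `n_components` (0-4) and `mets` (1 when `n_components >= 3`).
#' @examples
#' phenotype(data.frame(bmi = 26, fpg = 6.5, sbp = 145, dbp = 95, tg = 1.0,
#'                      hdl = 1.2, sex = "female",
#'                      drug_glucose = 0, drug_bp = 0))
#' @export
phenotype <- function(records) {
  required <- c("bmi", "fpg", "sbp", "dbp", "tg", "hdl", "sex",
                "drug_glucose", "drug_bp")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols)) {
    stop("phenotype(): missing required field(s): ",
         paste(missing_cols, collapse = ", "))
  }
  for (f in setdiff(required, "sex")) {
    bad <- which(is.na(records[[f]]))
    if (length(bad)) {
      stop(sprintf("phenotype(): field '%s' is missing (NA) in record(s) %s",
                   f, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  pg2h <- if ("pg2h" %in% names(records)) records$pg2h else rep(NA_real_, nrow(records))
  hdl_cut <- ifelse(records$sex == "male", 0.9, 1.0)

  ow <- records$bmi >= 25.0
  hg <- records$fpg >= 6.1 | (!is.na(pg2h) & pg2h >= 7.8) | records$drug_glucose == 1
  ht <- records$sbp >= 140 | records$dbp >= 90 | records$drug_bp == 1
  dl <- records$tg >= 1.7 | records$hdl < hdl_cut

  n_comp <- as.integer(ow) + as.integer(hg) + as.integer(ht) + as.integer(dl)
  data.frame(
    overweight_obesity = as.integer(ow),
    hyperglycemia = as.integer(hg),
    hypertension = as.integer(ht),
    dyslipidemia = as.integer(dl),
    n_components = n_comp,
    mets = as.integer(n_comp >= 3L)
  )
}

#' Outcome names recognised by the pipeline
#' @export
OUTCOMES <- c("mets", "overweight_obesity", "hyperglycemia",
              "hypertension", "dyslipidemia")
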