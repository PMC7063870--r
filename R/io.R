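#' Check-up cohort CSV schema
#'
#' Column names of the longitudinal check-up CSV consumed by the pipeline.
#' Mandatory columns: `subject_id`, `visit_time` (decimal years from an
#' arbitrary epoch, or an ISO date), `age` (years), `sex`
#' (`"female"`/`"male"`), `bmi` (kg/m^2), `fpg` (mmol/L), `sbp`, `dbp`
#' (mmHg), `tg`, `hdl` (mmol/L), `uric_acid` (umol/L), `smoker`, `drinker`,
#' `drug_glucose`, `drug_bp`, `drug_lipid` (0/1), `geno_dose` (0/1/2 copies
#' of the effect allele, NA allowed). Optional: `pg2h` (mmol/L), `ldl`
#' (mmol/L), `cvd` (0/1 self-reported cardio-/cerebrovascular disease at
#' baseline).
#'
#' @format list with `mandatory` and `optional` character vectors.
#' @export
cohort_schema <- list(
  mandatory = c("subject_id", "visit_time", "age", "sex", "bmi", "fpg",
                "sbp", "dbp", "tg", "hdl", "uric_acid", "smoker", "drinker",
                "drug_glucose", "drug_bp", "drug_lipid", "geno_dose"),
  optional = c("pg2h", "ldl", "cvd")
)

#' Read a longitudinal check-up cohort CSV
#'
#' Reads a UTF-8, comma-separated, headered CSV in the schema of
#' [cohort_schema]. Empty strings and `"NA"` parse as missing. Missing
#' mandatory columns raise an error naming them; unknown columns produce a
#' warning and are carried through untouched. A `visit_time` column holding
#' ISO dates (`YYYY-MM-DD`) is converted to decimal years at 365.25 days per
#' year.
#'
#' @param path file path.
#' @return data frame of check-up records.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, na.strings = c("", "NA"), stringsAsFactors = FALSE,
                        check.names = FALSE, fileEncoding = "UTF-8")
  miss <- setdiff(cohort_schema$mandatory, names(df))
  if (length(miss)) {
    stop("read_cohort_csv(): missing mandatory column(s): ",
         paste(miss, collapse = ", "))
  }
  unknown <- setdiff(names(df), c(cohort_schema$mandatory, cohort_schema$optional))
  if (length(unknown)) {
    warning("read_cohort_csv(): unknown column(s) carried through: ",
            paste(unknown, collapse = ", "))
  }
  if (is.character(df$visit_time)) {
    d <- as.Date(df$visit_time)
    if (anyNA(d)) stop("read_cohort_csv(): 'visit_time' is neither numeric nor ISO dates")
    df$visit_time <- as.numeric(d - min(d)) / 365.25
  }
  df$subject_id <- as.character(df$subject_id)
  num <- intersect(c("visit_time", "age", "bmi", "fpg", "pg2h", "sbp", "dbp",
                     "tg", "hdl", "ldl", "uric_acid"), names(df))
  for (f in num) df[[f]] <- as.numeric(df[[f]])
  int <- intersect(c("smoker", "drinker", "drug_glucose", "drug_bp",
                     "drug_lipid", "geno_dose", "cvd"), names(df))
  for (f in int) df[[f]] <- as.integer(df[[f]])
  bad_dose <- !is.na(df$geno_dose) & !df$geno_dose %in% 0:2
  if (any(bad_dose)) stop("read_cohort_csv(): 'geno_dose' outside {0,1,2}")
  df
}

#' Write a check-up cohort CSV
#'
#' @param records data frame of check-up records.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = FALSE)
  invisible(path)
}
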