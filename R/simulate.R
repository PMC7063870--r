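#' Draw additive genotype doses under Hardy-Weinberg proportions
#'
#' @param n number of subjects.
#' @param p effect-allele frequency in (0,1).
#' @param seed optional integer seed.
#' @return integer vector of doses in \{0,1,2\} with HWE probabilities
#'   `((1-p)^2, 2p(1-p), p^2)`.
#' @export
simulate_genotypes <- function(n, p, seed = NULL) {
  if (p <= 0 || p >= 1) stop("simulate_genotypes(): p must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  sample(0:2, n, replace = TRUE, prob = c((1 - p)^2, 2 * p * (1 - p), p^2))
}

#' Simulate serum uric acid from genotype, age and a latent confounder
#'
#' The latent standardized exposure is
#' `z = b_g * (dose - 2p) + b_u * U + eps`, with `U` a standard-normal
#' confounder correlated with standardized age (`cor = age_confounder_cor`)
#' and `eps` scaled so that `Var(z | age) = 1` (using the theoretical dose
#' variance `2p(1-p)`). The conditional scaling matters: the analysis
#' standardizes uric acid within age bands, so per-allele effects are stated
#' per *age-conditional* SD, and `b_g` is defined on that same scale. With
#' `b_u = 0` (or `age_confounder_cor = 0`) the marginal variance is exactly
#' 1. Raw uric acid is `ua_mean + ua_sd * z` (umol/L).
#'
#' @param doses integer genotype doses.
#' @param ages ages in years (used only to correlate the confounder).
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return numeric uric acid (umol/L) with attributes `"z"` (the latent
#'   standardized exposure) and `"confounder"` (`U`).
#' @export
simulate_exposure <- function(doses, ages, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"), length(doses) == length(ages))
  if (!is.null(seed)) set.seed(seed)
  n <- length(doses)
  p <- config$effect_allele_freq
  rho <- config$age_confounder_cor
  age_z <- if (stats::sd(ages) > 0) (ages - mean(ages)) / stats::sd(ages) else rep(0, n)
  U <- rho * age_z + sqrt(1 - rho^2) * stats::rnorm(n)
  # unit variance *conditional on age*: the analysis age-band z-scores then
  # measure the exposure on the same SD scale that b_g is stated on
  s_eps <- sqrt(1 - config$b_g^2 * 2 * p * (1 - p) - config$b_u^2 * (1 - rho^2))
  z <- config$b_g * (doses - 2 * p) + config$b_u * U + s_eps * stats::rnorm(n)
  ua <- config$ua_mean + config$ua_sd * z
  attr(ua, "z") <- z
  attr(ua, "confounder") <- U
  ua
}

# truncated-normal draws by inverse-CDF; vectorized over means
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Simulate longitudinal check-up records with incident outcomes
#'
#' Generates the post-genotype part of the cohort: per-outcome event times
#' under a proportional-hazards model with linear predictor
#' `gamma_x * z + gamma_u * U` and Weibull (default exponential) baseline,
#' baseline component prevalence from a logistic model on the same linear
#' predictor, an annual visit schedule with a follow-up length drawn from
#' `followup_years`, and laboratory values at every visit back-filled to be
#' consistent with [phenotype()]: a visit at which a component is active
#' carries a lab value beyond its diagnostic threshold, and conversely.
#'
#' The metabolic-syndrome event time is drawn directly from its own hazard;
#' component activation is then reconciled so that the third component
#' activates exactly at that time (at most two components are active
#' earlier). This keeps the syndrome flag, the component flags and the lab
#' values mutually consistent at every visit.
#'
#' @param z latent standardized exposure (from [simulate_exposure()]).
#' @param U latent confounder (from [simulate_exposure()]).
#' @param ages baseline ages.
#' @param doses genotype doses.
#' @param uric_acid baseline uric acid (umol/L).
#' @param config a [sim_config].
#' @param seed optional integer seed.
#' @return longitudinal data frame in the [cohort_schema] layout.
#' @export
simulate_outcomes <- function(z, U, ages, doses, uric_acid, config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  n <- length(z)
  comps <- setdiff(OUTCOMES, "mets")
  lp <- config$gamma_x * z + config$gamma_u * U
  shape <- config$weibull_shape

  # baseline component prevalence shares the hazard's linear predictor
  B <- sapply(comps, function(k) {
    pr <- stats::plogis(stats::qlogis(config$baseline_prev[[k]]) + lp)
    stats::rbinom(n, 1L, pr)
  })

  draw_time <- function(h0) (stats::rexp(n) / (h0 * exp(lp)))^(1 / shape)
  A <- sapply(comps, function(k) {
    ifelse(B[, k] == 1L, 0, draw_time(config$baseline_hazard[[k]]))
  })
  t_mets <- draw_time(config$baseline_hazard[["mets"]])

  # reconcile: among subjects free of baseline MetS, exactly the third
  # component activates at the drawn MetS time
  free <- rowSums(B) <= 2L
  for (i in which(free)) {
    o <- order(A[i, ])
    A[i, o[1:2]] <- pmin(A[i, o[1:2]], t_mets[i])
    A[i, o[3L]] <- t_mets[i]
    A[i, o[4L]] <- max(A[i, o[4L]], t_mets[i])
  }

  t_total <- sample(config$followup_years, n, replace = TRUE,
                    prob = config$followup_probs)
  nv <- t_total + 1L
  subj <- rep.int(seq_len(n), nv)
  visit_no <- sequence(nv) - 1L
  vt <- visit_no + ifelse(visit_no == 0L | visit_no == rep.int(t_total, nv), 0,
                          stats::rnorm(length(subj), 0, config$visit_jitter))

  N <- length(subj)
  act <- sapply(comps, function(k) A[subj, k] <= vt)

  drug <- sapply(comps, function(k) {
    B[, k] * stats::rbinom(n, 1L, config$p_drug_given_active)
  })

  bmi <- ifelse(act[, "overweight_obesity"],
                25 + stats::rgamma(N, shape = 1.5, scale = 1.5),
                rtnorm(N, 22.3, 2.2, 15, 24.9))
  fpg <- ifelse(act[, "hyperglycemia"],
                6.1 + stats::rexp(N, rate = 2),
                rtnorm(N, 5.0, 0.45, 3.5, 6.05))
  sbp <- ifelse(act[, "hypertension"],
                140 + stats::rexp(N, rate = 0.1),
                rtnorm(N, 118, 10, 85, 139.5))
  dbp <- ifelse(act[, "hypertension"],
                rtnorm(N, 88, 8, 60, 120),
                rtnorm(N, 72, 8, 45, 89.5))
  tg <- ifelse(act[, "dyslipidemia"],
               1.7 + stats::rexp(N, rate = 2),
               rtnorm(N, 0.95, 0.35, 0.2, 1.69))
  hdl <- ifelse(act[, "dyslipidemia"],
                rtnorm(N, 1.45, 0.25, 1.02, 3),
                rtnorm(N, 1.60, 0.28, 1.02, 3))

  ua_visit <- uric_acid[subj] + ifelse(visit_no == 0L, 0, stats::rnorm(N, 0, 12))
  ua_visit <- pmax(ua_visit, 50)

  data.frame(
    subject_id = sprintf("S%05d", subj),
    visit_time = vt,
    age = ages[subj] + vt,
    sex = "female",
    bmi = bmi, fpg = fpg, pg2h = NA_real_,
    sbp = sbp, dbp = dbp, tg = tg, hdl = hdl,
    ldl = rtnorm(N, 2.65, 0.68, 0.5, 6),
    uric_acid = ua_visit,
    smoker = rep.int(stats::rbinom(n, 1L, config$p_smoker), nv),
    drinker = rep.int(stats::rbinom(n, 1L, config$p_drinker), nv),
    drug_glucose = drug[subj, "hyperglycemia"],
    drug_bp = drug[subj, "hypertension"],
    drug_lipid = drug[subj, "dyslipidemia"],
    geno_dose = doses[subj],
    cvd = rep.int(stats::rbinom(n, 1L, config$p_cvd), nv),
    stringsAsFactors = FALSE
  )
}

#' Simulate a complete longitudinal check-up study
#'
#' Composes [simulate_genotypes()], [simulate_exposure()] and
#' [simulate_outcomes()] into a full synthetic study: a longitudinal cohort
#' CSV in the [cohort_schema] layout plus a truth record of all latent
#' parameters for recovery tests.
#'
#' @param config a [sim_config]; its `seed` (when set) makes the output
#'   fully reproducible.
#' @param out_dir optional directory; when given, writes `cohort.csv` and
#'   `truth.json` there.
#' @return list with `records` (longitudinal data frame) and `truth` (list:
#'   the configuration and the implied true quantities).
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_subjects
  ages <- rtnorm(n, config$age_mean, config$age_sd,
                 config$age_range[1], config$age_range[2])
  doses <- simulate_genotypes(n, config$effect_allele_freq)
  ua <- simulate_exposure(doses, ages, config)
  records <- simulate_outcomes(attr(ua, "z"), attr(ua, "confounder"),
                               ages, doses, as.numeric(ua), config)
  truth <- list(
    config = unclass(config),
    true_beta1_per_allele_sd = config$b_g,
    true_causal_log_hr_per_sd = config$gamma_x,
    approx_confounded_log_hr_per_sd = config$gamma_u * config$b_u
  )
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_cohort_csv(records, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(records = records, truth = truth)
}

#' Fast one-row-per-subject survival cohort for replicate experiments
#'
#' Bypasses the longitudinal visit machinery: draws genotype, exposure and a
#' single outcome's event time directly under the same latent model as
#' [simulate_study()], with administrative censoring at the scheduled end of
#' follow-up. Used for parameter-recovery and coverage experiments where
#' thousands of replicate cohorts are fitted.
#'
#' @param config a [sim_config].
#' @param outcome which outcome's hazard to use (default `"mets"`).
#' @param seed optional integer seed.
#' @return data frame with `dose`, `age`, `uric_acid`, `ua_z` (age-band
#'   standardized), `z` (latent truth), `confounder`, `time`, `event`.
#' @export
simulate_survival_cohort <- function(config = sim_config(), outcome = "mets",
                                     seed = NULL) {
  stopifnot(inherits(config, "sim_config"), outcome %in% OUTCOMES)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_subjects
  ages <- rtnorm(n, config$age_mean, config$age_sd,
                 config$age_range[1], config$age_range[2])
  doses <- simulate_genotypes(n, config$effect_allele_freq)
  ua <- simulate_exposure(doses, ages, config)
  z <- attr(ua, "z"); U <- attr(ua, "confounder")
  lp <- config$gamma_x * z + config$gamma_u * U
  h0 <- config$baseline_hazard[[outcome]]
  t_event <- (stats::rexp(n) / (h0 * exp(lp)))^(1 / config$weibull_shape)
  t_admin <- sample(config$followup_years, n, replace = TRUE,
                    prob = config$followup_probs)
  event <- as.integer(t_event <= t_admin)
  time <- pmin(t_event, t_admin)
  df <- data.frame(dose = doses, age = ages, uric_acid = as.numeric(ua),
                   ua_z = as.numeric(standardize_exposure(as.numeric(ua), ages)),
                   z = z, confounder = U, time = time, event = event)
  attr(df, "outcome") <- outcome
  df
}
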