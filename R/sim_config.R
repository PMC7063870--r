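#' Synthetic-cohort generator configuration
#'
#' Full parameterization of the synthetic health check-up cohort. Defaults
#' describe the study conditions the pipeline targets: a female check-up
#' cohort of 1381 subjects aged 21-81 (ages approximately normal, mean 39.5,
#' SD 12, truncated), serum uric acid with mean 257.33 and SD 52.80 umol/L,
#' an instrument SNP with effect-allele frequency 0.40 shifting the
#' standardized exposure by 0.23 SD per allele, no causal exposure effect on
#' any outcome (`gamma_x = 0`), and an unmeasured standard-normal confounder
#' (correlated with age) that drives both the exposure (`b_u = 0.6` SD) and
#' the outcome hazards (`gamma_u = 0.7` per unit), inducing a non-causal
#' observational exposure-outcome hazard ratio of roughly 1.5. Baseline
#' hazards are calibrated so that the metabolic-syndrome incidence density
#' falls near 20 per 1000 person-years; annual visits with a follow-up length
#' distribution whose median is 2 years.
#'
#' @param n_subjects cohort size before baseline exclusions.
#' @param seed integer seed for reproducibility (optional).
#' @param effect_allele_freq effect-allele frequency `p`, in (0,1).
#' @param b_g per-allele effect on the standardized exposure (SD units).
#' @param b_u confounder effect on the standardized exposure (SD units).
#' @param gamma_x causal effect of the standardized exposure on each
#'   outcome's log-hazard (per SD).
#' @param gamma_u confounder effect on each outcome's log-hazard.
#' @param age_mean,age_sd,age_range age distribution: normal, truncated to
#'   `age_range`.
#' @param age_confounder_cor correlation between the confounder and
#'   standardized age.
#' @param ua_mean,ua_sd raw uric-acid moments (umol/L) used to back-convert
#'   the latent standardized exposure.
#' @param baseline_hazard named per-year baseline hazards for the five
#'   outcomes.
#' @param baseline_prev named baseline prevalences of the four components
#'   (logistic intercepts are derived from these).
#' @param followup_years,followup_probs distribution of total scheduled
#'   follow-up (years; annual visits).
#' @param visit_jitter SD of the jitter (years) on interior visit times.
#' @param weibull_shape shape of the event-time distribution (1 =
#'   exponential, i.e. constant baseline hazard).
#' @param p_cvd baseline prevalence of self-reported cardio-/cerebrovascular
#'   disease (excluded at cohort construction).
#' @param p_smoker,p_drinker prevalences of the lifestyle covariates.
#' @param p_drug_given_active probability of a treatment flag for a
#'   component active at baseline.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 1381L,
                       seed = NULL,
                       effect_allele_freq = 0.40,
                       b_g = 0.23,
                       b_u = 0.6,
                       gamma_x = 0,
                       gamma_u = 0.7,
                       age_mean = 39.5, age_sd = 12, age_range = c(21, 81),
                       age_confounder_cor = 0.5,
                       ua_mean = 257.33, ua_sd = 52.80,
                       baseline_hazard = c(mets = 0.016,
                                           overweight_obesity = 0.040,
                                           hyperglycemia = 0.015,
                                           hypertension = 0.045,
                                           dyslipidemia = 0.055),
                       baseline_prev = c(overweight_obesity = 0.15,
                                         hyperglycemia = 0.03,
                                         hypertension = 0.08,
                                         dyslipidemia = 0.08),
                       followup_years = 1:5,
                       followup_probs = c(0.25, 0.35, 0.20, 0.12, 0.08),
                       visit_jitter = 0.05,
                       weibull_shape = 1,
                       p_cvd = 0.01,
                       p_smoker = 0.0036, p_drinker = 0.0646,
                       p_drug_given_active = 0.3) {
  cfg <- list(n_subjects = as.integer(n_subjects), seed = seed,
              effect_allele_freq = effect_allele_freq,
              b_g = b_g, b_u = b_u, gamma_x = gamma_x, gamma_u = gamma_u,
              age_mean = age_mean, age_sd = age_sd, age_range = age_range,
              age_confounder_cor = age_confounder_cor,
              ua_mean = ua_mean, ua_sd = ua_sd,
              baseline_hazard = baseline_hazard,
              baseline_prev = baseline_prev,
              followup_years = followup_years,
              followup_probs = followup_probs,
              visit_jitter = visit_jitter,
              weibull_shape = weibull_shape,
              p_cvd = p_cvd, p_smoker = p_smoker, p_drinker = p_drinker,
              p_drug_given_active = p_drug_given_active)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_subjects < 2L) stop("sim_config: n_subjects must be >= 2")
    if (effect_allele_freq <= 0 || effect_allele_freq >= 1) {
      stop("sim_config: effect_allele_freq must lie strictly in (0, 1)")
    }
    if (any(baseline_hazard <= 0)) stop("sim_config: baseline hazards must be > 0")
    if (!setequal(names(baseline_hazard), OUTCOMES)) {
      stop("sim_config: baseline_hazard must be named for all five outcomes")
    }
    if (!setequal(names(baseline_prev), setdiff(OUTCOMES, "mets"))) {
      stop("sim_config: baseline_prev must be named for the four components")
    }
    vz <- b_g^2 * 2 * effect_allele_freq * (1 - effect_allele_freq) +
      b_u^2 * (1 - age_confounder_cor^2)
    if (vz >= 1) stop("sim_config: b_g/b_u leave no residual exposure variance")
    if (length(followup_probs) != length(followup_years) ||
        abs(sum(followup_probs) - 1) > 1e-8) {
      stop("sim_config: followup_probs must sum to 1")
    }
    if (weibull_shape <= 0) stop("sim_config: weibull_shape must be > 0")
    invisible(TRUE)
  })
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  n = %d, effect-allele freq = %.2f, b_g = %.2f SD/allele\n",
              x$n_subjects, x$effect_allele_freq, x$b_g))
  cat(sprintf("  confounding: b_u = %.2f, gamma_u = %.2f; causal gamma_x = %.2f\n",
              x$b_u, x$gamma_u, x$gamma_x))
  cat(sprintf("  uric acid %.2f (%.2f) umol/L; ages ~ N(%.1f, %.1f) on [%g, %g]\n",
              x$ua_mean, x$ua_sd, x$age_mean, x$age_sd,
              x$age_range[1], x$age_range[2]))
  cat("  baseline hazards/yr:",
      paste(sprintf("%s=%.3f", names(x$baseline_hazard), x$baseline_hazard),
            collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a generator configuration as YAML
#'
#' @param path YAML file path.
#' @return [sim_config] for the reader; `path` invisibly for the writer.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  for (f in c("baseline_hazard", "baseline_prev")) {
    if (!is.null(raw[[f]])) raw[[f]] <- unlist(raw[[f]])
  }
  do.call(sim_config, raw)
}

#' @rdname read_sim_config
#' @param config a [sim_config].
#' @export
write_sim_config <- function(config, path) {
  out <- unclass(config)
  # yaml drops names on atomic vectors; named maps need lists
  for (f in c("baseline_hazard", "baseline_prev")) out[[f]] <- as.list(out[[f]])
  yaml::write_yaml(out, path)
  invisible(path)
}
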