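#' Define a simulation scenario
#'
#' A scenario bundles every knob of the synthetic-cohort generator: cohort and
#' instrument size, how much exposure variance the genetic risk score (GRS)
#' explains, the confounding structure, the true causal effect on the hazard,
#' direct (pleiotropic) variant effects on the outcome, the censoring scheme,
#' and the master seed. Passing the same scenario twice yields bit-identical
#' cohorts.
#'
#' @param n Number of participants.
#' @param m Number of instrument variants.
#' @param eaf_range Length-2 interval inside (0.01, 0.99) from which
#'   effect-allele frequencies are drawn uniformly.
#' @param beta_mean,beta_sd Mean and SD of the normal distribution of
#'   per-allele effects on the exposure.
#' @param variance_explained Fraction of exposure variance attributable to the
#'   GRS (liability variance for binary exposures); must lie in `[0, 1)`.
#' @param exposure_kind `"continuous"` or `"binary-liability"`.
#' @param prevalence Target exposure prevalence for binary exposures,
#'   evaluated at covariate means.
#' @param exposure_mean,exposure_sd Location and scale of a continuous
#'   exposure.
#' @param confounder_effect_on_exposure Effect of the standard-normal latent
#'   confounder U on the exposure (same scale as the exposure for continuous;
#'   log-odds for binary).
#' @param confounder_effect_on_log_hazard Effect of U on the log hazard.
#' @param true_log_hr True causal log hazard ratio per exposure unit
#'   (continuous) or per unit of log-odds of the exposure (binary; multiply by
#'   `log(2)` to express per doubling of odds).
#' @param pleiotropy `"none"`, `"balanced"` (direct variant effects on the log
#'   hazard with mean 0), or `"directional"` (non-zero mean).
#' @param pleiotropy_mean,pleiotropy_sd Mean and SD of the per-variant direct
#'   effects when `pleiotropy != "none"`.
#' @param baseline_hazard_rate Baseline events per person-year.
#' @param weibull_shape Shape of the Weibull event-time law; `1` (default)
#'   gives a constant (exponential) baseline hazard.
#' @param admin_censor_time Administrative censoring horizon in years.
#' @param ltfu_prob Probability a participant is lost to follow-up before the
#'   horizon; dropout times are uniform on `(0, admin_censor_time)`.
#' @param prevalent_fraction Fraction of participants flagged as prevalent
#'   cases (disease before enrolment), drawn independently of everything else.
#' @param seed Master seed; every generator stage derives its own sub-seed
#'   from it.
#'
#' @return An object of class `sim_scenario` (a validated list).
#' @examples
#' sc <- sim_scenario(n = 1000, m = 10, seed = 1)
#' sc$variance_explained
#' @export
sim_scenario <- function(n = 20000,
                         m = 50,
                         eaf_range = c(0.1, 0.9),
                         beta_mean = 0.08,
                         beta_sd = 0.03,
                         variance_explained = 0.006,
                         exposure_kind = c("continuous", "binary-liability"),
                         prevalence = 0.3,
                         exposure_mean = 0,
                         exposure_sd = 1,
                         confounder_effect_on_exposure = 0.3,
                         confounder_effect_on_log_hazard = 0.2,
                         true_log_hr = log(1.25),
                         pleiotropy = c("none", "balanced", "directional"),
                         pleiotropy_mean = 0,
                         pleiotropy_sd = 0,
                         baseline_hazard_rate = 0.002,
                         weibull_shape = 1,
                         admin_censor_time = 12,
                         ltfu_prob = 0,
                         prevalent_fraction = 0,
                         seed = 1L) {
  exposure_kind <- match.arg(exposure_kind)
  pleiotropy <- match.arg(pleiotropy)

  check_scalar_number(n, "n", lower = 1)
  check_scalar_number(m, "m", lower = 1)
  if (length(eaf_range) != 2L || eaf_range[1] > eaf_range[2]) {
    abort("`eaf_range` must be an ordered length-2 interval.")
  }
  check_scalar_number(eaf_range[1], "eaf_range[1]", lower = 0.01, upper = 0.99,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(eaf_range[2], "eaf_range[2]", lower = 0.01, upper = 0.99,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(variance_explained, "variance_explained",
                      lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_number(prevalence, "prevalence", lower = 0, upper = 1,
                      strict_lower = TRUE, strict_upper = TRUE)
  check_scalar_number(baseline_hazard_rate, "baseline_hazard_rate",
                      lower = 0, strict_lower = TRUE)
  check_scalar_number(weibull_shape, "weibull_shape", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(admin_censor_time, "admin_censor_time", lower = 0,
                      strict_lower = TRUE)
  check_scalar_number(ltfu_prob, "ltfu_prob", lower = 0, upper = 1)
  check_scalar_number(prevalent_fraction, "prevalent_fraction",
                      lower = 0, upper = 1, strict_upper = TRUE)
  check_scalar_number(seed, "seed")

  structure(
    list(
      n = as.integer(n), m = as.integer(m), eaf_range = as.numeric(eaf_range),
      beta_mean = beta_mean, beta_sd = beta_sd,
      variance_explained = variance_explained,
      exposure_kind = exposure_kind, prevalence = prevalence,
      exposure_mean = exposure_mean, exposure_sd = exposure_sd,
      confounder_effect_on_exposure = confounder_effect_on_exposure,
      confounder_effect_on_log_hazard = confounder_effect_on_log_hazard,
      true_log_hr = true_log_hr,
      pleiotropy = pleiotropy,
      pleiotropy_mean = pleiotropy_mean, pleiotropy_sd = pleiotropy_sd,
      baseline_hazard_rate = baseline_hazard_rate,
      weibull_shape = weibull_shape,
      admin_censor_time = admin_censor_time,
      ltfu_prob = ltfu_prob,
      prevalent_fraction = prevalent_fraction,
      seed = as.integer(seed)
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario>\n")
  cat(sprintf("  n = %d participants, m = %d variants (eaf in [%g, %g])\n",
              x$n, x$m, x$eaf_range[1], x$eaf_range[2]))
  cat(sprintf("  exposure: %s, GRS variance explained = %g\n",
              x$exposure_kind, x$variance_explained))
  cat(sprintf("  true log-HR = %g, confounding (exposure, log-hazard) = (%g, %g)\n",
              x$true_log_hr, x$confounder_effect_on_exposure,
              x$confounder_effect_on_log_hazard))
  cat(sprintf("  pleiotropy: %s (mean %g, sd %g)\n",
              x$pleiotropy, x$pleiotropy_mean, x$pleiotropy_sd))
  cat(sprintf("  hazard: rate %g/yr, Weibull shape %g, censored at %g yr\n",
              x$baseline_hazard_rate, x$weibull_shape, x$admin_censor_time))
  cat(sprintf("  seed = %d\n", x$seed))
  invisible(x)
}
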