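#' Simulate a table of instrument variants
#'
#' Draws `m` biallelic variants with effect-allele frequencies uniform on
#' `eaf_range` and per-allele exposure effects from a normal distribution,
#' mimicking the weight files distributed with genome-wide association study
#' (GWAS) summary statistics.
#'
#' @param m Number of variants (>= 1).
#' @param eaf_range Interval inside (0.01, 0.99) for effect-allele
#'   frequencies.
#' @param beta_mean,beta_sd Normal distribution of per-allele effects.
#' @param seed Integer seed.
#'
#' @return A tibble with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `eaf`, `pval`.
#' @examples
#' simulate_variants(3, eaf_range = c(0.2, 0.8), seed = 1)
#' @export
simulate_variants <- function(m, eaf_range = c(0.1, 0.9), beta_mean = 0.08,
                              beta_sd = 0.03, seed = 1L) {
  check_scalar_number(m, "m", lower = 1)
  if (length(eaf_range) != 2L || eaf_range[1] > eaf_range[2] ||
      eaf_range[1] <= 0.01 || eaf_range[2] >= 0.99) {
    abort("`eaf_range` must be an ordered interval inside (0.01, 0.99).")
  }
  m <- as.integer(m)
  withr::with_seed(as.integer(seed), {
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, m, replace = TRUE)
    oa <- vapply(ea, function(a) sample(setdiff(bases, a), 1L), character(1))
    tibble(
      variant_id = sprintf("rs%06d", seq_len(m)),
      effect_allele = ea,
      other_allele = unname(oa),
      beta = rnorm(m, beta_mean, beta_sd),
      eaf = runif(m, eaf_range[1], eaf_range[2]),
      pval = 10^runif(m, -30, log10(5e-8))
    )
  })
}

#' Simulate genotype dosages
#'
#' Each variant is drawn independently (linkage equilibrium) as
#' `Binomial(2, eaf)` effect-allele counts, i.e. Hardy-Weinberg proportions.
#'
#' @param n Number of participants.
#' @param variants Variant table as produced by [simulate_variants()] (needs
#'   `variant_id` and `eaf`).
#' @param seed Integer seed.
#'
#' @return An `n` x `m` numeric matrix of dosages in `[0, 2]`; rownames are
#'   sample IDs, colnames variant IDs.
#' @examples
#' v <- simulate_variants(2, seed = 1)
#' simulate_genotypes(4, v, seed = 1)
#' @export
simulate_genotypes <- function(n, variants, seed = 1L) {
  check_scalar_number(n, "n", lower = 1)
  check_columns(variants, c("variant_id", "eaf"), "variants")
  if (anyDuplicated(variants$variant_id)) {
    abort("`variants$variant_id` must be unique.")
  }
  n <- as.integer(n)
  m <- nrow(variants)
  withr::with_seed(as.integer(seed), {
    g <- vapply(variants$eaf, function(p) rbinom(n, 2L, p), numeric(n))
  })
  g <- matrix(g, nrow = n, ncol = m,
              dimnames = list(sprintf("id%06d", seq_len(n)),
                              variants$variant_id))
  g
}

#' Simulate an exposure from genotypes and a latent confounder
#'
#' The true (generating) genetic risk score is the beta-weighted dosage sum,
#' standardized. A continuous exposure is
#' `X = a * Z + b * U + e`, with `a` chosen so the score explains
#' `variance_explained` of the exposure variance and `U` a standard-normal
#' latent confounder. A binary exposure is generated from a logistic
#' liability: `logit P(X = 1) = c0 + a * Z + b * U`, with `a` set so the
#' score accounts for `variance_explained` of the liability variance and the
#' intercept `c0 = qlogis(prevalence)` fixing the prevalence at covariate
#' means.
#'
#' @param genotypes Dosage matrix from [simulate_genotypes()].
#' @param variants Variant table (provides the generating weights `beta`).
#' @param scenario A [sim_scenario()].
#'
#' @return A tibble with columns `sample_id`, `exposure`, `grs_true`
#'   (standardized generating score) and `U` (latent confounder, retained for
#'   oracle checks).
#' @export
simulate_exposure <- function(genotypes, variants, scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  check_columns(variants, c("variant_id", "beta"), "variants")
  if (!all(colnames(genotypes) == variants$variant_id)) {
    abort("`genotypes` columns must match `variants$variant_id` in order.")
  }
  n <- nrow(genotypes)
  raw <- drop(genotypes %*% variants$beta)
  s <- sd(raw)
  z <- if (is.na(s) || s == 0) rep(0, n) else (raw - mean(raw)) / s

  v <- scenario$variance_explained
  b <- scenario$confounder_effect_on_exposure

  withr::with_seed(derive_seeds(scenario$seed, 1L, salt = 11L), {
    u <- rnorm(n)
    if (scenario$exposure_kind == "continuous") {
      # Unit-variance construction: a^2 + b^2 + resid = 1, then rescaled.
      a <- sqrt(v)
      resid_var <- 1 - v - b^2
      if (resid_var < 0) {
        abort("`variance_explained` + confounder effect^2 exceeds 1; no residual variance left.")
      }
      x <- a * z + b * u + rnorm(n, sd = sqrt(resid_var))
      x <- scenario$exposure_mean + scenario$exposure_sd * x
    } else {
      if (scenario$prevalence <= 0 || scenario$prevalence >= 1) {
        abort("Target prevalence must lie strictly between 0 and 1.")
      }
      # Liability variance = a^2 + b^2 + pi^2/3 (logistic noise); choose a so
      # the score explains `v` of it.
      noise_var <- b^2 + pi^2 / 3
      a <- sqrt(v * noise_var / (1 - v))
      eta <- qlogis(scenario$prevalence) + a * z + b * u
      x <- rbinom(n, 1L, plogis(eta))
    }
    tibble(sample_id = rownames(genotypes), exposure = x, grs_true = z, U = u)
  })
}

#' Simulate censored survival outcomes under proportional hazards
#'
#' Event times follow a Weibull law (exponential when `weibull_shape = 1`)
#' with log hazard
#' `log(rate) = log(lambda0) + true_log_hr * X + bU * U + sum(alpha_j g_j)`,
#' where the `alpha_j` are per-variant direct (pleiotropic) effects drawn
#' according to the scenario. Follow-up is censored administratively at
#' `admin_censor_time`, optionally earlier by uniform loss to follow-up, and
#' a `prevalent_fraction` of participants is flagged as prevalent
#' independently of all covariates.
#'
#' @param exposure Numeric exposure vector.
#' @param U Latent confounder vector (same length).
#' @param scenario A [sim_scenario()].
#' @param genotypes Optional dosage matrix, required when
#'   `scenario$pleiotropy != "none"`.
#'
#' @return A tibble with columns `time` (years, > 0), `event` (0/1),
#'   `prevalent` (0/1) and, as an attribute `"alpha"`, the vector of direct
#'   variant effects used.
#' @export
simulate_survival <- function(exposure, U, scenario, genotypes = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  n <- length(exposure)
  if (length(U) != n) abort("`exposure` and `U` must have the same length.")

  withr::with_seed(derive_seeds(scenario$seed, 1L, salt = 23L), {
    alpha <- rep(0, scenario$m)
    direct <- rep(0, n)
    if (scenario$pleiotropy != "none") {
      if (is.null(genotypes)) {
        abort("`genotypes` are required when the scenario includes pleiotropy.")
      }
      mu <- if (scenario$pleiotropy == "balanced") 0 else scenario$pleiotropy_mean
      alpha <- rnorm(ncol(genotypes), mu, scenario$pleiotropy_sd)
      direct <- drop(genotypes %*% alpha)
    }
    lp <- scenario$true_log_hr * exposure +
      scenario$confounder_effect_on_log_hazard * U + direct
    rate <- scenario$baseline_hazard_rate * exp(lp)
    if (any(rate <= 0)) abort("Hazard rates must be positive.")
    # Inverse cumulative hazard of the Weibull: H(t) = lambda * t^shape.
    e <- rexp(n)
    t_event <- (e / rate)^(1 / scenario$weibull_shape)
    cens <- rep(scenario$admin_censor_time, n)
    if (scenario$ltfu_prob > 0) {
      lost <- runif(n) < scenario$ltfu_prob
      cens[lost] <- runif(sum(lost), 0, scenario$admin_censor_time)
    }
    event <- as.integer(t_event <= cens)
    time <- pmin(t_event, cens)
    # Guard against zero follow-up from numerically tiny event times.
    time <- pmax(time, .Machine$double.eps)
    prevalent <- as.integer(runif(n) < scenario$prevalent_fraction)
    out <- tibble(time = time, event = event, prevalent = prevalent)
    attr(out, "alpha") <- alpha
    out
  })
}

#' Simulate a complete analysis-ready cohort
#'
#' Chains [simulate_variants()], [simulate_genotypes()],
#' [simulate_exposure()] and [simulate_survival()] under a single scenario,
#' adding age and sex covariates that are independent of genotype (so they
#' are valid adjustment variables but not confounders of the genetic
#' instrument).
#'
#' @param scenario A [sim_scenario()].
#'
#' @return A list with elements `variants` (tibble), `genotypes` (matrix) and
#'   `cohort` (tibble with `sample_id`, `exposure`, `grs_true`, `U`, `age`,
#'   `sex`, `time`, `event`, `prevalent`).
#' @examples
#' sim <- simulate_cohort(sim_scenario(n = 200, m = 5, seed = 1))
#' head(sim$cohort)
#' @export
simulate_cohort <- function(scenario) {
  stopifnot(inherits(scenario, "sim_scenario"))
  seeds <- derive_seeds(scenario$seed, 3L)
  variants <- simulate_variants(scenario$m, scenario$eaf_range,
                                scenario$beta_mean, scenario$beta_sd,
                                seed = seeds[1])
  genotypes <- simulate_genotypes(scenario$n, variants, seed = seeds[2])
  exposure <- simulate_exposure(genotypes, variants, scenario)
  surv <- simulate_survival(exposure$exposure, exposure$U, scenario,
                            genotypes = genotypes)
  covar <- withr::with_seed(seeds[3], {
    tibble(
      age = round(runif(scenario$n, 40, 70)),
      sex = rbinom(scenario$n, 1L, 0.5)
    )
  })
  cohort <- dplyr::bind_cols(exposure, covar, surv)
  list(variants = variants, genotypes = genotypes, cohort = cohort,
       alpha = attr(surv, "alpha"))
}
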