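# Shared fixtures, built in code at test time.

# Small per-variant association table with known structure.
make_assoc <- function(m = 8, beta = 0.3, intercept = 0, noise = 0,
                       seed = 42) {
  withr::with_seed(seed, {
    gamma <- runif(m, 0.05, 0.2)
    tibble::tibble(
      variant_id = sprintf("rs%d", seq_len(m)),
      gamma = gamma,
      se_gamma = runif(m, 0.005, 0.02),
      Gamma = intercept + beta * gamma + rnorm(m, sd = noise),
      se_Gamma = runif(m, 0.01, 0.05)
    )
  })
}

# Analysis-ready simulated cohort with its score attached.
make_cohort <- function(n = 4000, m = 20, seed = 7, ...) {
  sc <- sim_scenario(n = n, m = m, variance_explained = 0.05,
                     baseline_hazard_rate = 0.01, seed = seed, ...)
  sim <- simulate_cohort(sc)
  grs <- compute_grs(sim$genotypes, sim$variants, "weighted")
  sim$cohort$grs <- grs$score
  sim
}

# Survival draw from an exponential law with per-subject rates, censored
# administratively; used as an outcome oracle independent of the package
# generator.
rexp_surv <- function(rate, horizon) {
  t <- rexp(length(rate), rate)
  tibble::tibble(time = pmin(t, horizon), event = as.integer(t <= horizon))
}
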