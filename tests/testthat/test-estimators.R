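test_that("per-variant associations recover constructed effects", {
  withr::with_seed(1, {
    n <- 6000
    v <- simulate_variants(6, seed = 2)
    g <- simulate_genotypes(n, v, seed = 3)
    x <- 0.2 * g[, 3] + rnorm(n)
    surv <- rexp_surv(rep(0.02, n), horizon = 12)
    cohort <- dplyr::bind_cols(surv, exposure = x)
    assoc <- per_snp_associations(cohort, g, "exposure")
    row <- assoc[assoc$variant_id == v$variant_id[3], ]
    expect_lt(abs(row$gamma - 0.2), 3 * row$se_gamma)
    # Outcome independent of dosage: Gammas consistent with zero.
    expect_true(all(abs(assoc$Gamma) < 4 * assoc$se_Gamma))

    # Orthogonal covariates barely move the exposure effects.
    cohort$noise <- rnorm(n)
    assoc2 <- per_snp_associations(cohort, g, "exposure",
                                   covariates = "noise")
    expect_true(all(abs(assoc$gamma - assoc2$gamma) < 2 * assoc$se_gamma))
  })
})

test_that("monomorphic variants are dropped with a warning", {
  withr::with_seed(2, {
    n <- 500
    g <- cbind(rs1 = rbinom(n, 2, 0.4), rs2 = rep(1, n))
    cohort <- dplyr::bind_cols(rexp_surv(rep(0.05, n), 10),
                               exposure = rnorm(n))
    expect_warning(assoc <- per_snp_associations(cohort, g, "exposure"),
                   "rs2")
    expect_equal(assoc$variant_id, "rs1")
  })
})

test_that("with one variant every estimator equals the ratio estimate", {
  a <- tibble::tibble(variant_id = "rs1", gamma = 0.12, se_gamma = 0.01,
                      Gamma = 0.03, se_Gamma = 0.02)
  ratio <- 0.03 / 0.12
  expect_equal(mr_ivw(a)$estimate, ratio, tolerance = 1e-12)
  a2 <- dplyr::bind_rows(a, a)  # median needs two rows; equal ratios
  expect_equal(mr_weighted_median(a2, n_boot = 100)$estimate, ratio)
  a3 <- dplyr::bind_rows(a, a, a)
  expect_equal(mr_weighted_mode(a3, n_boot = 100)$estimate, ratio,
               tolerance = 1e-8)
})

test_that("IVW and MR-Egger are exact on noise-free linear systems", {
  a <- make_assoc(m = 8, beta = 0.5, noise = 0)
  expect_equal(mr_ivw(a)$estimate, 0.5, tolerance = 1e-10)

  eg <- mr_egger(dplyr::mutate(a, Gamma = 0.5 * gamma + 0.01))
  expect_equal(eg$estimate[eg$method == "egger"], 0.5, tolerance = 1e-10)
  expect_equal(eg$estimate[eg$method == "egger_intercept"], 0.01,
               tolerance = 1e-10)

  # Constraining the Egger intercept to zero recovers IVW exactly.
  noisy <- make_assoc(m = 8, beta = 0.5, noise = 0.03, seed = 9)
  expect_equal(mr_egger(noisy, intercept = FALSE)$estimate,
               mr_ivw(noisy)$estimate, tolerance = 1e-10)

  expect_error(mr_egger(a[1:2, ]), "3")
  expect_error(mr_ivw(dplyr::mutate(a, gamma = 0)), "zero")
})

test_that("IVW matches an exact weighted-least-squares oracle", {
  a <- make_assoc(m = 10, beta = 0.3, noise = 0.05, seed = 3)
  w <- 1 / a$se_Gamma^2
  oracle <- solve(t(a$gamma * w) %*% a$gamma, t(a$gamma * w) %*% a$Gamma)
  expect_equal(mr_ivw(a)$estimate, drop(oracle), tolerance = 1e-10)
})

test_that("weighted median interpolates the cumulative weight function", {
  base <- tibble::tibble(se_gamma = 0.01, se_Gamma = 0.02)
  a3 <- tibble::tibble(gamma = 1, se_gamma = 0.01, Gamma = c(1, 2, 3),
                       se_Gamma = 0.02)
  expect_equal(mr_weighted_median(a3, "simple", n_boot = 100)$estimate, 2)
  a2 <- tibble::tibble(gamma = 1, se_gamma = 0.01, Gamma = c(1, 3),
                       se_Gamma = 0.02)
  expect_equal(mr_weighted_median(a2, "simple", n_boot = 100)$estimate, 2)

  # Brute-force cumulative-weight-inversion oracle on random weights.
  withr::with_seed(4, {
    for (rep in 1:5) {
      b <- sort(rnorm(7))
      w <- runif(7)
      a <- tibble::tibble(gamma = 1, se_gamma = 1e-6, Gamma = b,
                          se_Gamma = sqrt(1 / w))
      est <- mr_weighted_median(a, "weighted", n_boot = 100)$estimate
      wn <- w / sum(w)
      oracle <- approx(cumsum(wn) - wn / 2, b, xout = 0.5, rule = 2)$y
      expect_equal(est, oracle, tolerance = 1e-10)
    }
  })

  # All-equal weights reduce the weighted median to the simple median.
  a <- tibble::tibble(gamma = 1, se_gamma = 1e-6,
                      Gamma = c(0.1, 0.5, 0.7, 1.1, 2), se_Gamma = 1)
  expect_equal(mr_weighted_median(a, "weighted", n_boot = 100)$estimate,
               mr_weighted_median(a, "simple", n_boot = 100)$estimate)

  expect_warning(
    mr_weighted_median(tibble::tibble(gamma = c(0, 1, 2), se_gamma = 0.1,
                                      Gamma = 1, se_Gamma = 0.1),
                       n_boot = 100),
    "zero exposure effect")
})

test_that("weighted mode finds the plurality cluster", {
  # 6 of 9 ratios at 0.5, 3 outliers at 2.0.
  a <- tibble::tibble(gamma = 1, se_gamma = 0.01,
                      Gamma = c(rep(0.5, 6), rep(2, 3)) +
                        withr::with_seed(5, rnorm(9, sd = 0.01)),
                      se_Gamma = 0.05)
  est <- mr_weighted_mode(a, n_boot = 100)$estimate
  expect_lt(abs(est - 0.5), 0.05)

  # Dense-grid + golden-section oracle on the same density.
  b <- a$Gamma / a$gamma
  w <- (abs(a$gamma) / a$se_Gamma)^2
  w <- w / sum(w)
  h <- 0.9 * min(sd(b), mad(b)) * length(b)^(-1 / 5)
  dens <- function(x) sum(w * dnorm(x, b, h))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = 4096)
  i <- which.max(vapply(grid, dens, numeric(1)))
  oracle <- optimize(dens, grid[c(i - 1, i + 1)], maximum = TRUE,
                     tol = 1e-12)$maximum
  expect_equal(est, oracle, tolerance = 1e-8)

  # Halving the bandwidth keeps the argmax in the same cluster.
  est_half <- mr_weighted_mode(a, bandwidth_factor = 0.5,
                               n_boot = 100)$estimate
  expect_lt(abs(est_half - 0.5), 0.05)

  expect_error(mr_weighted_mode(a, bandwidth_factor = 0), "positive")
})

test_that("estimators are invariant to allele reorientation", {
  a <- make_assoc(m = 9, beta = 0.4, noise = 0.02, seed = 6)
  flip <- withr::with_seed(7, sample(c(-1, 1), 9, TRUE))
  af <- dplyr::mutate(a, gamma = gamma * flip, Gamma = Gamma * flip)
  expect_equal(mr_ivw(a)$estimate, mr_ivw(af)$estimate, tolerance = 1e-12)
  eg <- mr_egger(a)
  egf <- mr_egger(af)
  expect_equal(eg$estimate, egf$estimate, tolerance = 1e-12)
  expect_equal(mr_weighted_median(a, n_boot = 100, seed = 1)$estimate,
               mr_weighted_median(af, n_boot = 100, seed = 1)$estimate,
               tolerance = 1e-12)
  expect_equal(mr_weighted_mode(a, n_boot = 100, seed = 1)$estimate,
               mr_weighted_mode(af, n_boot = 100, seed = 1)$estimate,
               tolerance = 1e-8)
})

test_that("simulated valid instruments are recovered by IVW", {
  withr::with_seed(8, {
    a <- make_assoc(m = 30, beta = 0.25, noise = 0, seed = 10)
    a$Gamma <- a$Gamma + rnorm(30, sd = a$se_Gamma)
    est <- mr_ivw(a)
    expect_lt(abs(est$estimate - 0.25), 3 * est$std.error)
  })
})

test_that("the sensitivity panel returns one row per estimator", {
  a <- make_assoc(m = 10, beta = 0.3, noise = 0.02, seed = 11)
  panel <- mr_sensitivity(a, n_boot = 100, seed = 1)
  expect_setequal(panel$method,
                  c("ivw", "egger", "egger_intercept", "simple_median",
                    "weighted_median", "weighted_mode"))
  expect_true(all(is.finite(panel$estimate)))
  p <- plot_snp_associations(a, panel)
  expect_s3_class(p, "ggplot")
})
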