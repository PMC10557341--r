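test_that("2x2 group assignment follows the median-split rule", {
  g <- assign_2x2_groups(c(1, 2, 3, 4), c(4, 3, 2, 1))
  expect_equal(as.character(g), c("b_high", "b_high", "a_high", "a_high"))

  same <- assign_2x2_groups(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(sort(unique(as.character(same))), c("both_high", "both_low"))

  expect_error(assign_2x2_groups(1:4, 1:5), "length")
})

test_that("group assignment is invariant to monotone transforms", {
  withr::with_seed(1, {
    a <- rnorm(501)
    b <- rexp(501)
    g1 <- assign_2x2_groups(a, b)
    g2 <- assign_2x2_groups(exp(a), b^3)
    expect_identical(g1, g2)
  })
})

test_that("RERI arithmetic and guards follow the additive-interaction rules", {
  V <- diag(3) * 1e-4
  expect_equal(reri_from_hrs(1, 1, 1, V)$reri, 0)
  expect_equal(reri_from_hrs(1.03, 1.05, 1.10, V)$reri, 0.02)
  r <- reri_from_hrs(1.2, 1.3, 1.56, V)
  expect_equal(r$reri, 0.06)

  expect_warning(bad <- reri_from_hrs(0.9, 1.3, 1.56, V), "preventive")
  expect_false(bad$defined)
  expect_true(is.na(bad$reri))
  forced <- reri_from_hrs(0.9, 1.3, 1.56, V, force = TRUE)
  expect_equal(forced$reri, 1.56 - 0.9 - 1.3 + 1)
})

test_that("multiplicative joint effects give RERI = (HR10-1)(HR01-1)", {
  V <- diag(3) * 1e-6
  for (h10 in c(1, 1.1, 1.4, 2)) {
    for (h01 in c(1, 1.25, 1.8)) {
      r <- reri_from_hrs(h10, h01, h10 * h01, V)$reri
      expect_equal(r, (h10 - 1) * (h01 - 1), tolerance = 1e-12)
      expect_gte(r, 0)
    }
  }
})

test_that("the delta-method RERI CI agrees with a parametric-bootstrap oracle", {
  V <- matrix(c(4, 1, 1,
                1, 5, 1,
                1, 1, 6) * 1e-3, 3, 3)
  r <- reri_from_hrs(1.2, 1.3, 1.56, V, n_boot = 10000, seed = 42)
  # Oracle: multivariate-normal draws of the log HRs, empirical RERI sd.
  oracle_sd <- withr::with_seed(4242, {
    L <- chol(V)
    mu <- log(c(1.2, 1.3, 1.56))
    d <- sweep(matrix(rnorm(3 * 20000), 20000, 3) %*% L, 2, mu, "+")
    sd(exp(d[, 3]) - exp(d[, 1]) - exp(d[, 2]) + 1)
  })
  expect_lt(abs(r$se - oracle_sd) / oracle_sd, 0.1)
  # The bootstrap interval computed inside reri_from_hrs brackets the
  # delta interval closely.
  expect_lt(abs(r$ci_low_boot - r$ci_low), 0.05)
  expect_lt(abs(r$ci_high_boot - r$ci_high), 0.05)
})

test_that("factorial Cox recovers constructed group hazards", {
  withr::with_seed(7, {
    n <- 40000
    groups <- factor(rep(c("both_low", "a_high", "b_high", "both_high"),
                         each = n / 4),
                     levels = c("both_low", "a_high", "b_high", "both_high"))
    hr <- c(both_low = 1, a_high = 1.2, b_high = 1.3, both_high = 1.56)
    surv <- rexp_surv(0.01 * hr[as.character(groups)], horizon = 12)
    fit <- factorial_cox(surv, groups)
    est <- fit$estimates
    for (g in c("a_high", "b_high", "both_high")) {
      row <- est[est$group == g, ]
      expect_lt(abs(row$estimate - log(hr[[g]])), 3 * row$std.error)
    }
    expect_equal(sum(fit$group_sizes), n)
    # RERI on multiplicative hazards centres near (1.2-1)(1.3-1).
    fit <- add_reri(fit)
    expect_true(fit$reri$defined)
    expect_lt(abs(fit$reri$reri - 0.06), 3 * fit$reri$se)
  })
})

test_that("factorial Cox rejects empty or event-free groups", {
  withr::with_seed(8, {
    groups <- factor(rep(c("both_low", "a_high", "b_high", "both_high"),
                         each = 50),
                     levels = c("both_low", "a_high", "b_high", "both_high"))
    surv <- rexp_surv(rep(0.05, 200), horizon = 10)
    surv$event[groups == "both_high"] <- 0L
    expect_error(factorial_cox(surv, groups), "both_high")
  })
})

test_that("covariate adjustment leaves estimates unchanged for independent covariates", {
  withr::with_seed(9, {
    n <- 20000
    groups <- factor(sample(c("both_low", "a_high", "b_high", "both_high"),
                            n, TRUE),
                     levels = c("both_low", "a_high", "b_high", "both_high"))
    hr <- c(both_low = 1, a_high = 1.1, b_high = 1.15, both_high = 1.25)
    surv <- rexp_surv(0.01 * hr[as.character(groups)], horizon = 12)
    surv$noise_cov <- rnorm(n)
    f0 <- factorial_cox(surv, groups)
    f1 <- factorial_cox(surv, groups, covariates = "noise_cov")
    d <- abs(f0$estimates$estimate - f1$estimates$estimate)
    expect_true(all(d < 2 * f0$estimates$std.error))
  })
})

test_that("continuous factorial MR matches closed-form RERI and is scale invariant", {
  withr::with_seed(10, {
    n <- 30000
    a <- rnorm(n)
    b <- rnorm(n)
    b1 <- 0.03
    b2 <- 0.03
    surv <- rexp_surv(0.01 * exp(b1 * a + b2 * b), horizon = 12)
    # force = TRUE: at this small effect size a per-SD estimate can fall
    # below 1 by sampling noise, which would trip the preventive-HR guard.
    fit <- continuous_factorial_cox(surv, a, b, force = TRUE)
    est <- fit$estimates
    # Product term should be null.
    prod_row <- est[est$term == "product", ]
    expect_lt(abs(prod_row$estimate), 3 * prod_row$std.error)
    # RERI CI covers its closed-form plug-in value.
    target <- exp(b1 + b2) - exp(b1) - exp(b2) + 1
    expect_true(fit$reri$ci_low <= target && target <= fit$reri$ci_high)

    # Rescaling the raw scores changes nothing after standardization.
    fit2 <- continuous_factorial_cox(surv, 10 * a, b / 4, force = TRUE)
    expect_equal(fit$estimates$estimate, fit2$estimates$estimate,
                 tolerance = 1e-10)
    expect_equal(fit$reri$reri, fit2$reri$reri, tolerance = 1e-10)

    expect_error(continuous_factorial_cox(surv, rep(1, n), b), "non-constant")
  })
})

test_that("factorial_mr composes assignment, Cox fit and RERI", {
  sim <- make_cohort(n = 4000, m = 20, seed = 11)
  other <- withr::with_seed(12, rnorm(4000))
  fit <- factorial_mr(sim$cohort, sim$cohort$grs, other,
                      covariates = c("age", "sex"), force = TRUE)
  expect_s3_class(fit, "mr_factorial")
  expect_equal(sum(fit$group_sizes), 4000L)
  td <- tidy(fit)
  expect_true(all(c("group", "hr") %in% names(td)))
  gl <- glance(fit)
  expect_equal(gl$n, 4000L)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
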