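# Summary-statistic MR estimators computed from per-variant association
# estimates in the same cohort: IVW, MR-Egger, simple/weighted median,
# weighted mode.

#' Per-variant exposure and outcome associations
#'
#' For each variant, estimates the variant-exposure effect `gamma` (linear
#' regression for a continuous exposure, logistic for binary, restricted to
#' participants without the event — the same restriction as the TSPS first
#' stage) and the variant-outcome log hazard ratio `Gamma` from a Cox
#' regression, both adjusted for the supplied covariates. Monomorphic
#' variants are dropped with a warning.
#'
#' @param cohort Tibble with `time`, `event`, the exposure and covariates;
#'   prevalent cases excluded.
#' @param genotypes Dosage matrix aligned with `cohort` rows.
#' @param exposure Name of the exposure column.
#' @param covariates Character vector of covariate columns.
#' @param exposure_kind `"continuous"` or `"binary"`.
#'
#' @return A tibble with one row per variant: `variant_id`, `gamma`,
#'   `se_gamma`, `Gamma`, `se_Gamma`.
#' @export
per_snp_associations <- function(cohort, genotypes, exposure,
                                 covariates = character(),
                                 exposure_kind = c("continuous", "binary")) {
  exposure_kind <- match.arg(exposure_kind)
  check_columns(cohort, c("time", "event", exposure, covariates), "cohort")
  if (nrow(genotypes) != nrow(cohort)) {
    abort("`genotypes` and `cohort` must describe the same samples.")
  }
  if ("prevalent" %in% names(cohort) && any(cohort$prevalent != 0)) {
    abort("Prevalent cases must be excluded first.")
  }
  mono <- apply(genotypes, 2, sd) == 0
  if (any(mono)) {
    warn(sprintf("Dropping %d monomorphic variant(s): %s", sum(mono),
                 paste(colnames(genotypes)[mono], collapse = ", ")))
    genotypes <- genotypes[, !mono, drop = FALSE]
  }
  covars <- covariate_matrix(cohort, covariates)
  noncase <- cohort$event == 0L
  x <- cohort[[exposure]]
  surv <- survival::Surv(cohort$time, cohort$event)

  one <- function(j) {
    g <- genotypes[, j]
    Zg <- cbind(`(Intercept)` = 1, dosage = g, covars)
    if (exposure_kind == "binary") {
      f1 <- suppressWarnings(glm.fit(Zg[noncase, , drop = FALSE], x[noncase],
                                     family = binomial()))
      # Dispersion-1 covariance of the logistic MLE.
      W <- f1$weights
      XtWX <- crossprod(Zg[noncase, , drop = FALSE] * sqrt(W))
      se <- sqrt(diag(solve(XtWX)))[2]
      gam <- f1$coefficients[2]
    } else {
      f1 <- stats::lm.fit(Zg[noncase, , drop = FALSE], x[noncase])
      rss <- sum(f1$residuals^2)
      sigma2 <- rss / f1$df.residual
      R <- qr.R(f1$qr)
      cov_unscaled <- chol2inv(R)
      se <- sqrt(sigma2 * diag(cov_unscaled))[2]
      gam <- f1$coefficients[2]
    }
    f2 <- survival::coxph.fit(
      x = cbind(dosage = g, covars), y = surv, strata = NULL, offset = NULL,
      init = NULL, control = survival::coxph.control(), weights = NULL,
      method = "efron", rownames = NULL
    )
    tibble(variant_id = colnames(genotypes)[j],
           gamma = unname(gam), se_gamma = unname(se),
           Gamma = unname(f2$coefficients[1]),
           se_Gamma = sqrt(f2$var[1, 1]))
  }
  purrr::map_dfr(seq_len(ncol(genotypes)), one)
}

check_assoc <- function(assoc, min_variants = 1L) {
  check_columns(assoc, c("gamma", "se_gamma", "Gamma", "se_Gamma"),
                "association table")
  if (any(assoc$se_gamma <= 0) || any(assoc$se_Gamma <= 0)) {
    abort("Standard errors must be positive.")
  }
  if (nrow(assoc) < min_variants) {
    abort(sprintf("At least %d variant(s) required.", min_variants))
  }
  invisible(assoc)
}

mr_result <- function(method, beta, se) {
  tibble(method = method, estimate = beta, std.error = se,
         hr = exp(beta),
         conf.low = exp(beta - 1.96 * se), conf.high = exp(beta + 1.96 * se))
}

#' Inverse-variance-weighted estimator
#'
#' Weighted least-squares regression of the variant-outcome effects on the
#' variant-exposure effects through the origin, with weights
#' `1 / se_Gamma^2`. The standard error does not allow the residual
#' dispersion to drop below 1 (multiplicative random-effects convention).
#'
#' @param assoc Association table from [per_snp_associations()] (or with
#'   the same columns).
#' @return A one-row tibble: `method`, `estimate` (log-HR scale),
#'   `std.error`, `hr`, `conf.low`, `conf.high`.
#' @export
mr_ivw <- function(assoc) {
  check_assoc(assoc, 1L)
  if (all(assoc$gamma == 0)) abort("All variant-exposure effects are zero.")
  w <- 1 / assoc$se_Gamma^2
  beta <- sum(w * assoc$gamma * assoc$Gamma) / sum(w * assoc$gamma^2)
  if (nrow(assoc) > 1L) {
    resid <- assoc$Gamma - beta * assoc$gamma
    sigma2 <- sum(w * resid^2) / (nrow(assoc) - 1L)
    se <- sqrt(max(sigma2, 1) / sum(w * assoc$gamma^2))
  } else {
    se <- sqrt(1 / sum(w * assoc$gamma^2))
  }
  mr_result("ivw", beta, se)
}

#' MR-Egger regression
#'
#' Weighted least squares of the variant-outcome effects on the
#' variant-exposure effects with an intercept, weights `1 / se_Gamma^2`.
#' Exposure effects are first oriented non-negative (flipping the outcome
#' effect sign accordingly), making the fit invariant to the coded allele.
#' The intercept estimates the average directional pleiotropic effect; the
#' slope is the causal estimate under the InSIDE assumption. With
#' `intercept = FALSE` the fit collapses to [mr_ivw()].
#'
#' @param assoc Association table (>= 3 variants).
#' @param intercept Fit the pleiotropy intercept (default `TRUE`).
#' @return A tibble with rows `slope` and `intercept` (the latter on the
#'   log-hazard scale, with its `hr` column `NA`).
#' @export
mr_egger <- function(assoc, intercept = TRUE) {
  if (!intercept) {
    out <- mr_ivw(assoc)
    out$method <- "egger_no_intercept"
    return(out)
  }
  check_assoc(assoc, 3L)
  flip <- sign(assoc$gamma)
  flip[flip == 0] <- 1
  g <- assoc$gamma * flip
  G <- assoc$Gamma * flip
  w <- 1 / assoc$se_Gamma^2
  fit <- lm(G ~ g, weights = w)
  sm <- summary(fit)
  co <- sm$coefficients
  # Dispersion floored at 1, as for IVW.
  infl <- 1 / min(1, sm$sigma)
  slope <- mr_result("egger", co["g", 1], co["g", 2] * infl)
  interc <- tibble(method = "egger_intercept", estimate = co[1, 1],
                   std.error = co[1, 2] * infl, hr = NA_real_,
                   conf.low = co[1, 1] - 1.96 * co[1, 2] * infl,
                   conf.high = co[1, 1] + 1.96 * co[1, 2] * infl)
  dplyr::bind_rows(slope, interc)
}

# Weighted median of per-variant ratio estimates by inversion of the
# midpoint cumulative weight function.
weighted_median_point <- function(b, w) {
  o <- order(b)
  b <- b[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(b[1])
  if (cum[length(cum)] <= 0.5) return(b[length(b)])
  j <- max(which(cum <= 0.5))
  b[j] + (b[j + 1] - b[j]) * (0.5 - cum[j]) / (cum[j + 1] - cum[j])
}

#' Simple and weighted median estimators
#'
#' Per-variant ratio estimates `Gamma / gamma` are combined by a weighted
#' median: ratios are sorted and the estimate is the linear interpolation
#' of the ratio at cumulative weight one half, using midpoint cumulative
#' sums. Weights are equal (`mode = "simple"`) or
#' `gamma^2 / se_Gamma^2` (`mode = "weighted"`). The standard error comes
#' from a parametric bootstrap that redraws each `gamma` and `Gamma` from
#' normal distributions with their estimated standard errors. Valid when at
#' least half the weight comes from valid instruments. Variants with
#' `gamma = 0` are dropped with a warning.
#'
#' @param assoc Association table (>= 2 variants).
#' @param mode `"weighted"` (default) or `"simple"`.
#' @param n_boot Parametric bootstrap draws for the SE.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble as for [mr_ivw()].
#' @export
mr_weighted_median <- function(assoc, mode = c("weighted", "simple"),
                               n_boot = 1000, seed = 1L) {
  mode <- match.arg(mode)
  check_assoc(assoc, 2L)
  zero <- assoc$gamma == 0
  if (any(zero)) {
    warn(sprintf("Dropping %d variant(s) with zero exposure effect.",
                 sum(zero)))
    assoc <- assoc[!zero, , drop = FALSE]
    check_assoc(assoc, 2L)
  }
  wts <- function(a) {
    if (mode == "simple") rep(1, nrow(a)) else a$gamma^2 / a$se_Gamma^2
  }
  beta <- weighted_median_point(assoc$Gamma / assoc$gamma, wts(assoc))
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      a <- assoc
      a$gamma <- rnorm(nrow(a), assoc$gamma, assoc$se_gamma)
      a$Gamma <- rnorm(nrow(a), assoc$Gamma, assoc$se_Gamma)
      ok <- a$gamma != 0
      weighted_median_point(a$Gamma[ok] / a$gamma[ok], wts(a)[ok])
    }, numeric(1))
  })
  mr_result(paste0(mode, "_median"), beta, sd(reps))
}

# Weighted kernel density argmax: coarse grid to bracket the global
# maximum, then golden-section refinement inside the bracket.
mode_point <- function(b, w, h, grid_n = 512L) {
  if (h <= 0) abort("Kernel bandwidth must be positive.")
  dens <- function(x) sum(w * dnorm(x, b, h))
  grid <- seq(min(b) - 3 * h, max(b) + 3 * h, length.out = grid_n)
  i <- which.max(vapply(grid, dens, numeric(1)))
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(grid_n, i + 1L)]
  stats::optimize(dens, c(lo, hi), maximum = TRUE, tol = 1e-12)$maximum
}

#' Weighted mode estimator
#'
#' Clusters the per-variant ratio estimates with a weighted Gaussian kernel
#' density and takes the density argmax: consistent when a plurality of the
#' weight comes from valid instruments. Ratio estimates are inverse-variance
#' weighted (`1 / se_ratio^2` with `se_ratio = se_Gamma / |gamma|`). The
#' bandwidth is `bandwidth_factor * 0.9 * min(sd, mad) * m^(-1/5)`, the
#' classic normal-reference rule on the ratio spread; when every ratio is
#' identical the common value is returned directly. SE by the same
#' parametric bootstrap as [mr_weighted_median()].
#'
#' @param assoc Association table (>= 3 variants).
#' @param bandwidth_factor Multiplier on the reference bandwidth (> 0).
#' @param n_boot Parametric bootstrap draws for the SE.
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble as for [mr_ivw()].
#' @export
mr_weighted_mode <- function(assoc, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L) {
  check_assoc(assoc, 3L)
  if (bandwidth_factor <= 0) abort("`bandwidth_factor` must be positive.")
  zero <- assoc$gamma == 0
  if (any(zero)) {
    warn(sprintf("Dropping %d variant(s) with zero exposure effect.",
                 sum(zero)))
    assoc <- assoc[!zero, , drop = FALSE]
    check_assoc(assoc, 3L)
  }
  point <- function(a) {
    b <- a$Gamma / a$gamma
    w <- (abs(a$gamma) / a$se_Gamma)^2
    w <- w / sum(w)
    spread <- min(sd(b), mad(b))
    if (spread == 0) {
      if (length(unique(b)) == 1L) return(b[1])
      abort("Kernel bandwidth is zero: ratio spread degenerate.")
    }
    h <- bandwidth_factor * 0.9 * spread * length(b)^(-1 / 5)
    mode_point(b, w, h)
  }
  beta <- point(assoc)
  reps <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_boot), function(i) {
      a <- assoc
      a$gamma <- rnorm(nrow(a), assoc$gamma, assoc$se_gamma)
      a$Gamma <- rnorm(nrow(a), assoc$Gamma, assoc$se_Gamma)
      a <- a[a$gamma != 0, , drop = FALSE]
      tryCatch(point(a), error = function(e) NA_real_)
    }, numeric(1))
  })
  mr_result("weighted_mode", beta, sd(reps, na.rm = TRUE))
}

#' Run the full panel of summary-statistic estimators
#'
#' @param assoc Association table from [per_snp_associations()].
#' @param n_boot Bootstrap draws for the median/mode standard errors.
#' @param seed Seed.
#' @return A tibble with one row per estimator (IVW, MR-Egger slope and
#'   intercept, simple and weighted median, weighted mode).
#' @export
mr_sensitivity <- function(assoc, n_boot = 1000, seed = 1L) {
  seeds <- derive_seeds(seed, 3L)
  dplyr::bind_rows(
    mr_ivw(assoc),
    mr_egger(assoc),
    mr_weighted_median(assoc, "simple", n_boot = n_boot, seed = seeds[1]),
    mr_weighted_median(assoc, "weighted", n_boot = n_boot, seed = seeds[2]),
    mr_weighted_mode(assoc, n_boot = n_boot, seed = seeds[3])
  )
}

#' Scatter plot of variant associations with estimator fits
#'
#' @param assoc Association table.
#' @param estimates Optional tibble of estimator results (as from
#'   [mr_sensitivity()]); slopes are drawn through the origin.
#' @return A ggplot object.
#' @export
plot_snp_associations <- function(assoc, estimates = NULL) {
  flip <- sign(assoc$gamma)
  flip[flip == 0] <- 1
  d <- tibble(gamma = assoc$gamma * flip, Gamma = assoc$Gamma * flip,
              se_Gamma = assoc$se_Gamma)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$Gamma)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$Gamma - 1.96 * .data$se_Gamma,
                                        ymax = .data$Gamma + 1.96 * .data$se_Gamma),
                           width = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Variant-exposure effect",
                  y = "Variant-outcome log HR") +
    ggplot2::theme_minimal()
  if (!is.null(estimates)) {
    sl <- estimates[!estimates$method %in% "egger_intercept", , drop = FALSE]
    p <- p + ggplot2::geom_abline(
      data = sl,
      ggplot2::aes(slope = .data$estimate, intercept = 0,
                   colour = .data$method)
    )
  }
  p
}
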