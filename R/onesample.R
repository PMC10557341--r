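# One-sample Mendelian randomization: two-stage predictor substitution
# (TSPS) with a Cox proportional-hazards second stage and bootstrap
# standard errors.

#' Scale a log hazard ratio to "per doubling of odds" of a binary exposure
#'
#' For a binary exposure instrumented on the log-odds scale, multiplying the
#' estimate and its standard error by `ln 2 = 0.693` re-expresses the effect
#' per doubling of the odds of the exposure.
#'
#' @param beta Log hazard ratio(s).
#' @param se Standard error(s).
#' @return A tibble with scaled `beta` and `se`.
#' @examples
#' scale_per_doubling(1.0, 0.5)  # 0.693, 0.347
#' @export
scale_per_doubling <- function(beta, se) {
  if (any(!is.finite(beta)) || any(!is.finite(se))) {
    abort("`beta` and `se` must be finite.")
  }
  tibble(beta = beta * log(2), se = se * log(2))
}

#' Bootstrap standard error of a statistic
#'
#' Resamples rows of `data` with replacement `n_boot` times, recomputes
#' `statistic` on each resample, and reports the standard deviation of the
#' replicates together with a normal-approximation confidence interval
#' around the full-sample estimate and a percentile interval. Replicate
#' seeds derive from the master seed through a counter, so changing
#' `n_boot` never reorders the streams.
#'
#' @param data A data frame (resampled by row) or vector.
#' @param statistic Function of one resampled `data` returning a single
#'   number; may signal an error on a degenerate resample (tallied; more
#'   than 5% failures aborts).
#' @param n_boot Number of bootstrap iterations (>= 100).
#' @param seed Master seed.
#' @param level Confidence level (default 0.95).
#'
#' @return A one-row tibble with `estimate`, `se`, `ci_low`, `ci_high`
#'   (normal), `ci_low_pct`, `ci_high_pct` (percentile) and `n_failed`;
#'   the replicate values are attached as attribute `"replicates"`.
#' @examples
#' x <- rnorm(400)
#' bootstrap_se(x, mean, n_boot = 200, seed = 1)
#' @export
bootstrap_se <- function(data, statistic, n_boot = 2000, seed = 1L,
                         level = 0.95) {
  check_scalar_number(n_boot, "n_boot", lower = 100)
  n <- if (is.data.frame(data) || is.matrix(data)) nrow(data) else length(data)
  take <- function(d, idx) {
    if (is.data.frame(d) || is.matrix(d)) d[idx, , drop = FALSE] else d[idx]
  }
  est <- statistic(data)
  seeds <- derive_seeds(seed, n_boot)
  reps <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    reps[i] <- withr::with_seed(seeds[i], {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(statistic(take(data, idx)), error = function(e) NA_real_)
    })
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * n_boot) {
    abort(sprintf("%d of %d bootstrap replicates failed to fit.",
                  n_failed, n_boot))
  }
  z <- qnorm(1 - (1 - level) / 2)
  se <- sd(reps, na.rm = TRUE)
  pct <- quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                  na.rm = TRUE, names = FALSE)
  out <- tibble(estimate = est, se = se,
                ci_low = est - z * se, ci_high = est + z * se,
                ci_low_pct = pct[1], ci_high_pct = pct[2],
                n_failed = n_failed)
  attr(out, "replicates") <- reps
  out
}

# One TSPS fit on a row subset. Stage 1 is fit on non-cases only; its
# coefficients are then applied to every selected row, and the Cox second
# stage runs on the fitted values plus covariates.
tsps_fit_once <- function(idx, time, event, exposure, Z, covars, binary,
                          stage1_scale) {
  ev <- event[idx]
  noncase <- idx[ev == 0L]
  if (length(noncase) < ncol(Z) + 1L) abort("Too few non-cases for stage 1.")
  if (binary) {
    fit1 <- suppressWarnings(
      glm.fit(Z[noncase, , drop = FALSE], exposure[noncase],
              family = binomial())
    )
    if (!fit1$converged ||
        any(fit1$fitted.values < 1e-10 | fit1$fitted.values > 1 - 1e-10)) {
      abort("Stage-1 logistic regression did not converge (possible separation).")
    }
    co <- fit1$coefficients
  } else {
    fit1 <- .lm.fit(Z[noncase, , drop = FALSE], exposure[noncase])
    co <- fit1$coefficients
    if (any(is.na(co))) abort("Stage-1 design is singular.")
  }
  xhat <- drop(Z[idx, , drop = FALSE] %*% co)
  if (binary && stage1_scale == "probability") xhat <- plogis(xhat)
  x2 <- cbind(xhat = xhat, covars[idx, , drop = FALSE])
  fast_coxph(x2, time[idx], ev)[1]
}

#' Two-stage predictor substitution MR with a Cox second stage
#'
#' Estimates the average causal hazard ratio of an exposure on a censored
#' time-to-event outcome, using a genetic risk score as the instrument.
#' Stage 1 regresses the exposure on the score and covariates — linear
#' regression for a continuous exposure, logistic for a binary one — with
#' the fit restricted to participants who did not experience the event;
#' stage-1 fitted values are then computed for *all* participants from
#' those coefficients. Stage 2 is a Cox regression (Efron ties) of the
#' outcome on the fitted values plus the same covariates; the reported
#' coefficient is the stage-2 log hazard ratio on the fitted value. For a
#' binary exposure instrumented on the log-odds scale the estimate can be
#' rescaled per doubling of the odds (multiplying by `ln 2`, see
#' [scale_per_doubling()]). Standard errors come from a participant
#' bootstrap that reruns the full two-stage procedure on each resample.
#'
#' @param cohort Tibble with the outcome columns `time` and `event`, the
#'   exposure, the score and any covariates. Prevalent cases must already be
#'   excluded; a `prevalent` column with nonzero entries is an error.
#' @param exposure Name of the exposure column.
#' @param grs Name of the genetic risk score column.
#' @param covariates Character vector of covariate column names (both
#'   stages).
#' @param exposure_kind `"continuous"` or `"binary"`.
#' @param scale_doubling Rescale per doubling of odds (binary exposures
#'   only; default `TRUE` for binary).
#' @param stage1_scale For binary exposures, carry stage-1 fitted values on
#'   the `"linear_predictor"` (log-odds, default; makes the doubling
#'   rescaling exact) or `"probability"` scale.
#' @param n_boot Bootstrap iterations (>= 100).
#' @param seed Master seed for the bootstrap.
#'
#' @return An object of class `mr_tsps`; see [tidy.mr_tsps()] and
#'   [glance.mr_tsps()].
#' @examples
#' sim <- simulate_cohort(sim_scenario(n = 3000, m = 20,
#'                                     variance_explained = 0.05,
#'                                     baseline_hazard_rate = 0.01, seed = 7))
#' grs <- compute_grs(sim$genotypes, sim$variants, "weighted")
#' cohort <- dplyr::mutate(sim$cohort, grs = grs$score)
#' fit <- tsps_cox(cohort, "exposure", "grs", covariates = c("age", "sex"),
#'                 n_boot = 100, seed = 1)
#' tidy(fit)
#' @export
tsps_cox <- function(cohort, exposure, grs, covariates = character(),
                     exposure_kind = c("continuous", "binary"),
                     scale_doubling = NULL,
                     stage1_scale = c("linear_predictor", "probability"),
                     n_boot = 2000, seed = 1L) {
  exposure_kind <- match.arg(exposure_kind)
  stage1_scale <- match.arg(stage1_scale)
  binary <- exposure_kind == "binary"
  scale_doubling <- scale_doubling %||% binary
  if (scale_doubling && !binary) {
    abort("`scale_doubling` applies to binary exposures only.")
  }
  check_columns(cohort, c("time", "event", exposure, grs), "cohort")
  if ("prevalent" %in% names(cohort) && any(cohort$prevalent != 0)) {
    abort("Prevalent cases must be excluded before TSPS estimation.")
  }
  keep <- complete.cases(cohort[, c("time", "event", exposure, grs,
                                    covariates)])
  cohort <- cohort[keep, , drop = FALSE]
  n <- nrow(cohort)
  time <- cohort$time
  event <- cohort$event
  x <- cohort[[exposure]]
  if (sum(event) == 0L) abort("No events in the cohort.")
  if (sd(cohort[[grs]]) == 0) abort("`grs` is constant.")
  if (binary && !all(x %in% c(0, 1))) {
    abort("A binary exposure must be coded 0/1.")
  }

  covars <- covariate_matrix(cohort, covariates)
  Z <- cbind(`(Intercept)` = 1, grs = cohort[[grs]], covars)

  mult <- if (scale_doubling) log(2) else 1
  all_idx <- seq_len(n)
  beta <- mult * tsps_fit_once(all_idx, time, event, x, Z, covars, binary,
                               stage1_scale)

  check_scalar_number(n_boot, "n_boot", lower = 100)
  seeds <- derive_seeds(seed, n_boot)
  reps <- rep(NA_real_, n_boot)
  for (i in seq_len(n_boot)) {
    reps[i] <- withr::with_seed(seeds[i], {
      idx <- sample.int(n, n, replace = TRUE)
      tryCatch(
        mult * tsps_fit_once(idx, time, event, x, Z, covars, binary,
                             stage1_scale),
        error = function(e) NA_real_
      )
    })
  }
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.05 * n_boot) {
    abort(sprintf("%d of %d bootstrap replicates failed to fit.",
                  n_failed, n_boot))
  }
  se <- sd(reps, na.rm = TRUE)
  pct <- quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)

  structure(
    list(
      beta = beta, se = se, hr = exp(beta),
      ci_low = beta - 1.96 * se, ci_high = beta + 1.96 * se,
      ci_low_pct = pct[1], ci_high_pct = pct[2],
      scaled_doubling = scale_doubling, exposure_kind = exposure_kind,
      exposure = exposure, grs = grs, covariates = covariates,
      n_boot = as.integer(n_boot), seed = as.integer(seed),
      n_used = n, n_events = sum(event), n_failed = n_failed,
      boot_betas = reps
    ),
    class = "mr_tsps"
  )
}

# Linear-outcome TSPS used as a small-instance oracle: with a single
# instrument and no covariates it reduces to the instrumental-variable
# ratio cov(Y, G) / cov(X, G).
tsps_linear <- function(y, x, g) {
  Z <- cbind(1, g)
  co <- .lm.fit(Z, x)$coefficients
  xhat <- drop(Z %*% co)
  .lm.fit(cbind(1, xhat), y)$coefficients[2]
}

#' @export
print.mr_tsps <- function(x, ...) {
  cat("<mr_tsps> two-stage predictor substitution Cox estimate\n")
  unit <- if (x$scaled_doubling) "per doubling of odds" else
    if (x$exposure_kind == "binary") "per unit log-odds" else "per exposure unit"
  cat(sprintf("  HR %.3f (95%% CI %.3f, %.3f) %s\n",
              x$hr, exp(x$ci_low), exp(x$ci_high), unit))
  cat(sprintf("  n = %d, events = %d, bootstrap n = %d (seed %d, %d failed)\n",
              x$n_used, x$n_events, x$n_boot, x$seed, x$n_failed))
  invisible(x)
}

#' Tidy a TSPS-Cox fit
#'
#' @param x An `mr_tsps` object.
#' @param ... Unused.
#' @return A one-row tibble with the log hazard ratio (`estimate`),
#'   bootstrap `std.error`, Wald `statistic` and `p.value`, the hazard
#'   ratio and both normal and percentile confidence limits.
#' @method tidy mr_tsps
#' @export
tidy.mr_tsps <- function(x, ...) {
  tibble(
    term = x$exposure,
    estimate = x$beta, std.error = x$se,
    statistic = x$beta / x$se,
    p.value = 2 * pnorm(-abs(x$beta / x$se)),
    hr = x$hr,
    conf.low = exp(x$ci_low), conf.high = exp(x$ci_high),
    conf.low.pct = exp(x$ci_low_pct), conf.high.pct = exp(x$ci_high_pct),
    scaled_doubling = x$scaled_doubling
  )
}

#' @rdname tidy.mr_tsps
#' @method glance mr_tsps
#' @export
glance.mr_tsps <- function(x, ...) {
  tibble(n = x$n_used, events = x$n_events, n_boot = x$n_boot,
         n_boot_failed = x$n_failed, seed = x$seed,
         exposure_kind = x$exposure_kind)
}
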