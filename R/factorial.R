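# 2x2 and continuous factorial Mendelian randomization with RERI additive
# interaction.

#' Assign 2x2 factorial groups from two genetic risk scores
#'
#' Each score is split at its sample median (ties to low, see
#' [dichotomize_at_median()]); the cross of the two splits defines four
#' genetic-predisposition groups with "both low" as the reference. The
#' assignment depends on the scores only through their ranks, so any
#' strictly monotone transform of either score leaves it unchanged.
#'
#' @param grsA,grsB Numeric score vectors on the same samples.
#' @return A factor with levels `both_low` (reference), `a_high`, `b_high`,
#'   `both_high`.
#' @examples
#' assign_2x2_groups(c(1, 2, 3, 4), c(4, 3, 2, 1))
#' @export
assign_2x2_groups <- function(grsA, grsB) {
  if (length(grsA) != length(grsB)) {
    abort("`grsA` and `grsB` must have the same length.")
  }
  a <- dichotomize_at_median(grsA)
  b <- dichotomize_at_median(grsB)
  lab <- dplyr::case_when(
    a == "low" & b == "low" ~ "both_low",
    a == "high" & b == "low" ~ "a_high",
    a == "low" & b == "high" ~ "b_high",
    TRUE ~ "both_high"
  )
  factor(lab, levels = c("both_low", "a_high", "b_high", "both_high"))
}

#' Cox regression across 2x2 factorial groups
#'
#' Fits a Cox model (Efron ties) of the outcome on the three non-reference
#' group indicators plus covariates, returning hazard ratios versus the
#' "both low" reference and the variance-covariance matrix of the three log
#' hazard ratios, which [reri_from_hrs()] consumes. By default a robust
#' (sandwich) covariance is retained.
#'
#' @param cohort Tibble with `time`, `event` and covariate columns;
#'   prevalent cases must already be excluded.
#' @param groups Factor from [assign_2x2_groups()] (same rows as `cohort`).
#' @param covariates Character vector of covariate column names.
#' @param robust Use a robust variance estimate (default `TRUE`).
#'
#' @return An object of class `mr_factorial` with elements `estimates`
#'   (tibble of the three group HRs with CIs), `group_sizes`, `events`,
#'   `vcov` (3x3, log-HR scale) and `reri` (`NULL` until
#'   [add_reri()]/[reri_from_hrs()] is applied).
#' @export
factorial_cox <- function(cohort, groups, covariates = character(),
                          robust = TRUE) {
  check_columns(cohort, c("time", "event", covariates), "cohort")
  if (length(groups) != nrow(cohort)) {
    abort("`groups` must have one label per cohort row.")
  }
  if ("prevalent" %in% names(cohort) && any(cohort$prevalent != 0)) {
    abort("Prevalent cases must be excluded before factorial estimation.")
  }
  sizes <- table(groups)
  events <- tapply(cohort$event, groups, sum)
  events[is.na(events)] <- 0
  if (any(sizes == 0L) || any(events == 0)) {
    bad <- names(sizes)[sizes == 0L | events == 0]
    abort(sprintf("Group(s) without participants or events: %s",
                  paste(bad, collapse = ", ")))
  }
  dat <- dplyr::mutate(cohort, .group = groups)
  f <- stats::reformulate(c(".group", covariates),
                          response = "survival::Surv(time, event)")
  fit <- survival::coxph(f, data = dat, ties = "efron", robust = robust)
  co <- coef(fit)[1:3]
  V <- vcov(fit)[1:3, 1:3]
  term <- sub("^\\.group", "", names(co))
  est <- tibble(
    group = term,
    n = as.integer(sizes[term]),
    events = as.integer(events[term]),
    estimate = unname(co),
    std.error = sqrt(diag(V)),
    hr = exp(unname(co)),
    conf.low = exp(unname(co) - 1.96 * sqrt(diag(V))),
    conf.high = exp(unname(co) + 1.96 * sqrt(diag(V)))
  )
  structure(
    list(estimates = est,
         group_sizes = setNames(as.integer(sizes), names(sizes)),
         events = setNames(as.integer(events), names(events)),
         vcov = V, covariates = covariates, robust = robust, reri = NULL),
    class = "mr_factorial"
  )
}

#' Relative excess risk due to interaction from three hazard ratios
#'
#' `RERI = HR11 - HR10 - HR01 + 1`; 0 means exact additivity of excess
#' risks, positive values synergy, negative antagonism. Following standard
#' practice, RERI is only defined when none of the three hazard ratios is
#' preventive (all >= 1); otherwise no number is emitted unless
#' `force = TRUE`. The confidence interval uses the delta method on the
#' jointly normal log hazard ratios, with gradient
#' `(-HR10, -HR01, HR11)`; a parametric-bootstrap interval from
#' multivariate-normal draws of the log HRs is available as a cross-check.
#'
#' @param hr_10,hr_01,hr_11 Hazard ratios versus the double-low reference
#'   for "A high only", "B high only" and "both high".
#' @param log_hr_covariance 3x3 covariance of the log hazard ratios, in the
#'   order (10, 01, 11).
#' @param level Confidence level.
#' @param force Compute RERI even when some HR < 1 (methodological use).
#' @param n_boot If > 0, also compute a parametric-bootstrap CI from this
#'   many multivariate-normal draws.
#' @param seed Seed for the bootstrap draws.
#'
#' @return A one-row tibble with `reri`, `se`, `ci_low`, `ci_high`,
#'   `defined`, and (when requested) `ci_low_boot`, `ci_high_boot`.
#' @examples
#' V <- diag(3) * 1e-4
#' reri_from_hrs(1.03, 1.05, 1.10, V)  # RERI 0.02
#' @export
reri_from_hrs <- function(hr_10, hr_01, hr_11, log_hr_covariance,
                          level = 0.95, force = FALSE, n_boot = 0,
                          seed = 1L) {
  V <- as.matrix(log_hr_covariance)
  stopifnot(all(dim(V) == c(3L, 3L)))
  if (!force && (hr_10 < 1 || hr_01 < 1 || hr_11 < 1)) {
    warn("RERI undefined: at least one hazard ratio is preventive (< 1).")
    return(tibble(reri = NA_real_, se = NA_real_, ci_low = NA_real_,
                  ci_high = NA_real_, defined = FALSE))
  }
  reri <- hr_11 - hr_10 - hr_01 + 1
  grad <- c(-hr_10, -hr_01, hr_11)
  se <- sqrt(drop(t(grad) %*% V %*% grad))
  z <- qnorm(1 - (1 - level) / 2)
  out <- tibble(reri = reri, se = se,
                ci_low = reri - z * se, ci_high = reri + z * se,
                defined = TRUE)
  if (n_boot > 0) {
    mu <- log(c(hr_10, hr_01, hr_11))
    draws <- withr::with_seed(as.integer(seed), {
      L <- chol(V)
      e <- matrix(rnorm(3 * n_boot), n_boot, 3) %*% L
      sweep(e, 2, mu, "+")
    })
    r <- exp(draws[, 3]) - exp(draws[, 1]) - exp(draws[, 2]) + 1
    q <- quantile(r, c((1 - level) / 2, 1 - (1 - level) / 2), names = FALSE)
    out$ci_low_boot <- q[1]
    out$ci_high_boot <- q[2]
  }
  out
}

#' Add a RERI estimate to a factorial fit
#'
#' @param fit An `mr_factorial` object.
#' @param ... Passed to [reri_from_hrs()].
#' @return The fit with its `reri` element filled in.
#' @export
add_reri <- function(fit, ...) {
  stopifnot(inherits(fit, "mr_factorial"))
  hr <- setNames(fit$estimates$hr, fit$estimates$group)
  fit$reri <- reri_from_hrs(hr[["a_high"]], hr[["b_high"]],
                            hr[["both_high"]], fit$vcov, ...)
  fit
}

#' 2x2 factorial MR in one call
#'
#' Convenience wrapper: assigns median-split groups from two scores, fits
#' the factorial Cox model and computes RERI.
#'
#' @inheritParams factorial_cox
#' @param grsA,grsB Numeric score vectors aligned with `cohort`.
#' @param ... Passed to [reri_from_hrs()].
#' @return An `mr_factorial` object with `reri` filled in.
#' @export
factorial_mr <- function(cohort, grsA, grsB, covariates = character(),
                         robust = TRUE, ...) {
  groups <- assign_2x2_groups(grsA, grsB)
  add_reri(factorial_cox(cohort, groups, covariates, robust = robust), ...)
}

#' Continuous factorial MR with a product term
#'
#' Both scores are standardized to unit variance; a Cox model is fit on
#' `zA + zB + zA:zB` plus covariates, reporting per-SD hazard ratios and
#' the product-term HR. RERI is evaluated at +1 SD in both scores:
#' `exp(b1 + b2 + b3) - exp(b1) - exp(b2) + 1`, with a delta-method CI and
#' the same "no preventive HR" guard as the 2x2 analysis (applied to
#' `exp(b1)`, `exp(b2)` and `exp(b1 + b2 + b3)`).
#'
#' @inheritParams factorial_cox
#' @param grsA,grsB Numeric score vectors aligned with `cohort`.
#' @param force Compute RERI even when an HR is preventive.
#' @return An object of class `mr_contfact` with `estimates` (per-SD and
#'   product-term HRs), `vcov` and `reri`.
#' @export
continuous_factorial_cox <- function(cohort, grsA, grsB,
                                     covariates = character(),
                                     robust = TRUE, force = FALSE) {
  check_columns(cohort, c("time", "event", covariates), "cohort")
  if (sd(grsA) == 0 || sd(grsB) == 0) {
    abort("Scores must be non-constant for the continuous factorial model.")
  }
  dat <- dplyr::mutate(cohort,
                       .zA = as.numeric(scale(grsA)),
                       .zB = as.numeric(scale(grsB)))
  f <- stats::reformulate(c(".zA", ".zB", ".zA:.zB", covariates),
                          response = "survival::Surv(time, event)")
  fit <- survival::coxph(f, data = dat, ties = "efron", robust = robust)
  idx <- match(c(".zA", ".zB", ".zA:.zB"), names(coef(fit)))
  b <- coef(fit)[idx]
  V <- vcov(fit)[idx, idx]
  est <- tibble(
    term = c("grsA_per_sd", "grsB_per_sd", "product"),
    estimate = unname(b), std.error = sqrt(diag(V)),
    hr = exp(unname(b)),
    conf.low = exp(unname(b) - 1.96 * sqrt(diag(V))),
    conf.high = exp(unname(b) + 1.96 * sqrt(diag(V)))
  )
  s <- sum(b)
  hrs <- c(exp(b[1]), exp(b[2]), exp(s))
  if (!force && any(hrs < 1)) {
    warn("RERI undefined: at least one hazard ratio is preventive (< 1).")
    reri <- tibble(reri = NA_real_, se = NA_real_, ci_low = NA_real_,
                   ci_high = NA_real_, defined = FALSE)
  } else {
    r <- exp(s) - exp(b[1]) - exp(b[2]) + 1
    grad <- c(exp(s) - exp(b[1]), exp(s) - exp(b[2]), exp(s))
    se <- sqrt(drop(t(grad) %*% V %*% grad))
    reri <- tibble(reri = unname(r), se = se, ci_low = unname(r) - 1.96 * se,
                   ci_high = unname(r) + 1.96 * se, defined = TRUE)
  }
  structure(
    list(estimates = est, vcov = V, reri = reri, covariates = covariates,
         robust = robust),
    class = "mr_contfact"
  )
}

#' @export
print.mr_factorial <- function(x, ...) {
  cat("<mr_factorial> 2x2 factorial MR Cox fit\n")
  print(x$estimates)
  if (!is.null(x$reri)) {
    if (isTRUE(x$reri$defined)) {
      cat(sprintf("RERI %.3f (95%% CI %.3f, %.3f)\n",
                  x$reri$reri, x$reri$ci_low, x$reri$ci_high))
    } else {
      cat("RERI undefined (a hazard ratio is preventive).\n")
    }
  }
  invisible(x)
}

#' @export
print.mr_contfact <- function(x, ...) {
  cat("<mr_contfact> continuous factorial MR Cox fit (per SD)\n")
  print(x$estimates)
  if (isTRUE(x$reri$defined)) {
    cat(sprintf("RERI at +1 SD in both: %.3f (95%% CI %.3f, %.3f)\n",
                x$reri$reri, x$reri$ci_low, x$reri$ci_high))
  } else {
    cat("RERI undefined (a hazard ratio is preventive).\n")
  }
  invisible(x)
}

#' Tidy a factorial MR fit
#'
#' @param x An `mr_factorial` or `mr_contfact` object.
#' @param ... Unused.
#' @return A tibble of group (or per-SD term) hazard ratios, with the RERI
#'   row appended when defined.
#' @method tidy mr_factorial
#' @export
tidy.mr_factorial <- function(x, ...) {
  out <- x$estimates
  if (!is.null(x$reri) && isTRUE(x$reri$defined)) {
    out <- dplyr::bind_rows(
      out,
      tibble(group = "RERI", n = NA_integer_, events = NA_integer_,
             estimate = x$reri$reri, std.error = x$reri$se,
             hr = NA_real_, conf.low = x$reri$ci_low,
             conf.high = x$reri$ci_high)
    )
  }
  out
}

#' @rdname tidy.mr_factorial
#' @method tidy mr_contfact
#' @export
tidy.mr_contfact <- function(x, ...) {
  out <- x$estimates
  if (isTRUE(x$reri$defined)) {
    out <- dplyr::bind_rows(
      out,
      tibble(term = "RERI", estimate = x$reri$reri, std.error = x$reri$se,
             hr = NA_real_, conf.low = x$reri$ci_low,
             conf.high = x$reri$ci_high)
    )
  }
  out
}

#' @rdname tidy.mr_factorial
#' @method glance mr_factorial
#' @export
glance.mr_factorial <- function(x, ...) {
  tibble(n = sum(x$group_sizes), events = sum(x$events),
         robust = x$robust,
         reri_defined = !is.null(x$reri) && isTRUE(x$reri$defined))
}

#' Forest plot of a 2x2 factorial MR fit
#'
#' @param object An `mr_factorial` object.
#' @param ... Unused.
#' @return A ggplot object: group hazard ratios with 95% CIs versus the
#'   double-low reference.
#' @method autoplot mr_factorial
#' @export
autoplot.mr_factorial <- function(object, ...) {
  d <- object$estimates
  d$group <- factor(d$group, levels = rev(d$group))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$hr, y = .data$group)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$conf.low,
                                          xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "Hazard ratio (vs both GRS ≤ median)", y = NULL) +
    ggplot2::theme_minimal()
}
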