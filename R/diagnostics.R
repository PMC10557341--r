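# Model diagnostics: proportional-hazards check via Schoenfeld residuals
# and GRS-confounder association scans.

#' Test proportional hazards via Schoenfeld residuals
#'
#' Computes, for every term of a fitted Cox model, the Pearson correlation
#' between its Schoenfeld residuals and the event times, with a two-sided
#' p-value. Under proportional hazards the residuals are uncorrelated with
#' time; a systematic correlation indicates a time-varying effect.
#'
#' @param fit A fitted [survival::coxph] model with at least 2 events.
#' @return A tibble with `term`, `correlation` and `p.value`.
#' @examples
#' library(survival)
#' fit <- coxph(Surv(time, status) ~ age + sex, data = lung)
#' ph_schoenfeld_test(fit)
#' @export
ph_schoenfeld_test <- function(fit) {
  if (!inherits(fit, "coxph")) abort("`fit` must be a coxph model.")
  if (fit$nevent < 2L) abort("Need at least 2 events to test residuals.")
  res <- stats::residuals(fit, type = "schoenfeld")
  if (is.null(dim(res))) {
    res <- matrix(res, ncol = 1,
                  dimnames = list(names(res), names(coef(fit))))
  }
  times <- as.numeric(rownames(res))
  purrr::map_dfr(colnames(res), function(tm) {
    ct <- cor.test(res[, tm], times, method = "pearson")
    tibble(term = tm, correlation = unname(ct$estimate),
           p.value = ct$p.value)
  })
}

#' Scan genetic risk scores for confounder associations
#'
#' Regresses every candidate confounder on every standardized score —
#' linear regression for numeric covariates, logistic for binary ones
#' (0/1, logical, or two-level factors) — and flags associations beyond
#' the Bonferroni threshold `alpha / (n_scores * n_covariates)`. A valid
#' instrument should show no such associations; flagged covariates are
#' candidates for additional adjustment. Constant covariates are skipped
#' with a warning.
#'
#' @param grs_table Tibble (or data frame) of score columns, one per trait.
#' @param covariate_table Tibble of candidate confounders on the same
#'   samples.
#' @param alpha Family-wise error rate (default 0.05).
#' @return A tibble with `grs`, `covariate`, `estimate` (per SD of the
#'   score), `p.value`, `threshold` and `flagged`.
#' @export
confounder_scan <- function(grs_table, covariate_table, alpha = 0.05) {
  grs_table <- as_tibble(grs_table)
  covariate_table <- as_tibble(covariate_table)
  if (ncol(grs_table) < 1L || ncol(covariate_table) < 1L) {
    abort("Need at least one score and one covariate.")
  }
  usable <- names(covariate_table)[vapply(covariate_table, function(x) {
    x <- x[!is.na(x)]
    length(unique(x)) > 1L
  }, logical(1))]
  skipped <- setdiff(names(covariate_table), usable)
  if (length(skipped) > 0L) {
    warn(sprintf("Skipping constant covariate(s): %s",
                 paste(skipped, collapse = ", ")))
  }
  threshold <- alpha / (ncol(grs_table) * length(usable))
  purrr::map_dfr(names(grs_table), function(gn) {
    z <- as.numeric(scale(grs_table[[gn]]))
    purrr::map_dfr(usable, function(cn) {
      y <- covariate_table[[cn]]
      if (is.logical(y)) y <- as.integer(y)
      if (is.factor(y) || is.character(y)) {
        lv <- unique(y[!is.na(y)])
        if (length(lv) != 2L) {
          warn(sprintf("Skipping non-binary categorical covariate `%s`.", cn))
          return(NULL)
        }
        y <- as.integer(y == lv[2])
      }
      binary <- all(y[!is.na(y)] %in% c(0, 1))
      if (binary) {
        m <- glm(y ~ z, family = binomial())
      } else {
        m <- lm(y ~ z)
      }
      co <- summary(m)$coefficients
      tibble(grs = gn, covariate = cn, estimate = co["z", 1],
             p.value = co["z", 4], threshold = threshold,
             flagged = co["z", 4] < threshold)
    })
  })
}
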