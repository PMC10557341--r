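# Internal helpers shared across modules.

# Derive a stream of child seeds from one master seed. Keeps every derived
# seed inside the 32-bit integer range R requires.
derive_seeds <- function(seed, n, salt = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  (as.integer(seed) + salt + 104729L * seq_len(n)) %% .Machine$integer.max
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  lo_ok <- if (strict_lower) x > lower else x >= lower
  hi_ok <- if (strict_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok) {
    abort(sprintf(
      "`%s` must be in %s%s, %s%s (got %g).", name,
      if (strict_lower) "(" else "[", format(lower),
      format(upper), if (strict_upper) ")" else "]", x
    ))
  }
  invisible(x)
}

check_columns <- function(data, cols, what = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing) > 0L) {
    abort(sprintf(
      "Column%s %s missing from %s.",
      if (length(missing) > 1L) "s" else "",
      paste0("`", missing, "`", collapse = ", "), what
    ))
  }
  invisible(data)
}

# Covariate design matrix (no intercept column); factors expanded to
# treatment contrasts. Returns a zero-column matrix for empty `covariates`.
covariate_matrix <- function(data, covariates) {
  if (length(covariates) == 0L) {
    return(matrix(numeric(0), nrow = nrow(data), ncol = 0L))
  }
  check_columns(data, covariates, "cohort")
  f <- as.formula(paste("~", paste(covariates, collapse = " + ")))
  mm <- stats::model.matrix(f, data = data)
  mm[, -1L, drop = FALSE]
}

# Fast Cox fit on a prepared design matrix (Efron ties). Returns the
# coefficient vector; used on bootstrap resamples where formula dispatch
# would dominate the run time.
fast_coxph <- function(x, time, event) {
  fit <- survival::coxph.fit(
    x = x, y = survival::Surv(time, event),
    strata = NULL, offset = NULL, init = NULL,
    control = survival::coxph.control(), weights = NULL,
    method = "efron", rownames = NULL
  )
  fit$coefficients
}
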