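# Configuration-driven orchestration of the full analysis:
# simulate -> GRS -> one-sample MR -> factorial MR -> sensitivity.

# Small stable hash (FNV-1a over the deparsed config) used to stamp output
# tables so a result file can be traced back to its configuration.
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  bytes <- utf8ToInt(s)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a pipeline configuration
#'
#' Configurations are nested key-value YAML. Required: a `seed` and either a
#' `scenario` block (arguments to [sim_scenario()]) or input `paths`
#' (`cohort`, `genotypes`, `weights`). Optional: `covariates` (character),
#' `n_boot` (default 200), `exposure_kind`, `filters` (e.g.
#' `exclude_medication: true` with `medication_column`), `out_dir`.
#'
#' @param path YAML file path.
#' @return A validated config list of class `mr_config`.
#' @export
read_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

validate_config <- function(config) {
  if (is.null(config$seed)) abort("The configuration must set `seed`.")
  if (is.null(config$scenario) && is.null(config$paths)) {
    abort("The configuration needs a `scenario` block or input `paths`.")
  }
  config$n_boot <- config$n_boot %||% 200
  config$covariates <- as.character(config$covariates %||% c("age", "sex"))
  config$exposure_kind <- config$exposure_kind %||% "continuous"
  structure(config, class = "mr_config")
}

pipeline_inputs <- function(config) {
  if (!is.null(config$scenario)) {
    sc <- do.call(sim_scenario, c(config$scenario,
                                  list(seed = as.integer(config$seed))))
    sim <- simulate_cohort(sc)
    list(cohort = sim$cohort, genotypes = sim$genotypes,
         weights = sim$variants)
  } else {
    p <- config$paths
    list(
      cohort = readr::read_csv(p$cohort, show_col_types = FALSE),
      genotypes = read_genotypes_tsv(p$genotypes),
      weights = read_weights(p$weights)
    )
  }
}

#' Run the full MR pipeline from a configuration
#'
#' Stages: (1) obtain inputs — simulate a cohort from the `scenario` block
#' or read cohort/genotype/weight files; (2) apply filters (prevalent-case
#' exclusion always; optional medication-user exclusion); (3) build
#' weighted and unweighted genetic risk scores; (4) one-sample TSPS-Cox MR
#' with bootstrap CIs; (5) 2x2 and continuous factorial MR (the variant set
#' is split into two halves to form the score pair when only one trait is
#' present); (6) sensitivity analyses: per-variant associations, the
#' summary-statistic estimator panel, a proportional-hazards check and a
#' confounder scan. Every output table carries the seed and a hash of the
#' configuration; given the same configuration the run is deterministic.
#'
#' @param config An `mr_config` list (see [read_config()]) or a path to a
#'   YAML file.
#' @param out_dir Optional output directory; when set, every table is
#'   written as CSV together with a run log.
#' @return A named list of tibbles: `grs`, `onesample`, `factorial`,
#'   `continuous_factorial`, `sensitivity`, `diagnostics`, `log`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_config(config)
  config <- validate_config(unclass(config))
  hash <- config_hash(unclass(config))
  logs <- character(0)
  note <- function(...) logs <<- c(logs, sprintf(...))

  inputs <- pipeline_inputs(config)
  cohort <- inputs$cohort
  note("inputs: n = %d participants, %d variants", nrow(cohort),
       ncol(inputs$genotypes))

  keep <- rep(TRUE, nrow(cohort))
  if ("prevalent" %in% names(cohort)) {
    keep <- keep & cohort$prevalent == 0
    note("excluded %d prevalent case(s)", sum(cohort$prevalent != 0))
  }
  med_col <- config$filters$medication_column %||% "sleep_medication"
  if (isTRUE(config$filters$exclude_medication)) {
    if (!med_col %in% names(cohort)) {
      abort(sprintf("Medication filter requested but column `%s` is absent.",
                    med_col))
    }
    keep <- keep & cohort[[med_col]] == 0
    note("excluded %d sleep-medication user(s)", sum(cohort[[med_col]] != 0))
  }
  genotypes <- inputs$genotypes[keep, , drop = FALSE]
  cohort <- cohort[keep, , drop = FALSE]
  cohort$prevalent <- NULL
  note("analysis set: n = %d, events = %d", nrow(cohort), sum(cohort$event))

  covars <- intersect(config$covariates, names(cohort))
  exposure_kind <- config$exposure_kind

  # Stage: genetic risk scores (both flavours plus the median split).
  wgrs <- compute_grs(genotypes, inputs$weights, "weighted")
  ugrs <- compute_grs(genotypes, inputs$weights, "unweighted")
  strength <- instrument_strength(cohort$exposure, wgrs$score)
  grs_group <- dichotomize_at_median(wgrs$score)
  grs_tbl <- tibble(
    sample_id = wgrs$sample_id, wgrs = wgrs$score, uwgrs = ugrs$score,
    group = grs_group
  )
  note("instrument strength: R2 = %.4g, F = %.4g", strength$r2,
       strength$f_stat)

  # Stage: one-sample MR.
  cohort$`.wgrs` <- wgrs$score
  fit <- tsps_cox(cohort, "exposure", ".wgrs", covariates = covars,
                  exposure_kind = if (exposure_kind == "binary") "binary"
                                  else "continuous",
                  n_boot = config$n_boot, seed = as.integer(config$seed))
  onesample <- dplyr::mutate(tidy(fit), n = fit$n_used,
                             events = fit$n_events, n_boot = fit$n_boot)

  # Stage: factorial MR on a pair of scores; with a single simulated trait
  # the variant set is halved to emulate two instruments.
  m <- nrow(inputs$weights)
  half <- seq_len(m %/% 2)
  grsA <- compute_grs(genotypes, inputs$weights[half, ], "weighted")$score
  grsB <- compute_grs(genotypes, inputs$weights[-half, ], "weighted")$score
  fact <- factorial_mr(cohort, grsA, grsB, covariates = covars,
                       force = TRUE)
  contfact <- continuous_factorial_cox(cohort, grsA, grsB,
                                       covariates = covars, force = TRUE)

  # Stage: sensitivity.
  assoc <- per_snp_associations(cohort, genotypes, "exposure",
                                covariates = covars,
                                exposure_kind = if (exposure_kind == "binary")
                                  "binary" else "continuous")
  panel <- mr_sensitivity(assoc, n_boot = max(200, config$n_boot),
                          seed = as.integer(config$seed))
  ph_fit <- survival::coxph(
    survival::Surv(time, event) ~ .wgrs,
    data = dplyr::mutate(cohort, .wgrs = wgrs$score)
  )
  ph <- ph_schoenfeld_test(ph_fit)
  scan <- confounder_scan(tibble(wgrs = wgrs$score),
                          cohort[, covars, drop = FALSE])
  diagnostics <- dplyr::bind_rows(
    dplyr::mutate(ph, check = "schoenfeld", .before = 1),
    tibble(check = "confounder_scan", term = paste(scan$grs, scan$covariate),
           correlation = NA_real_, p.value = scan$p.value)
  )

  stamp <- function(tbl) {
    dplyr::mutate(tbl, seed = as.integer(config$seed), config = hash)
  }
  out <- list(
    grs = stamp(grs_tbl),
    instrument_strength = stamp(strength),
    onesample = stamp(onesample),
    factorial = stamp(tidy(fact)),
    continuous_factorial = stamp(tidy(contfact)),
    sensitivity = stamp(panel),
    diagnostics = stamp(diagnostics),
    log = tibble(message = logs, seed = as.integer(config$seed),
                 config = hash)
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(out)) {
      readr::write_csv(out[[nm]], file.path(out_dir, paste0(nm, ".csv")))
    }
  }
  out
}
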