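# Genetic risk score construction: allele harmonization, weighted and
# unweighted scores, instrument strength, median dichotomization.

#' Harmonize external variant weights to genotype data
#'
#' Aligns a GWAS weight table to the allele actually counted in the dosage
#' data. When the file's effect allele equals the counted allele the weight
#' is kept as is; when it equals the other allele the weight's sign is
#' negated and its frequency reflected (`eaf -> 1 - eaf`) — the dosage
#' column is left untouched, so a negative harmonized beta means the counted
#' allele is trait-decreasing. Variants absent from the genotype data, or
#' with an allele pair that is neither a match nor a swap, are dropped with
#' a warning. Palindromic variants (A/T or C/G) are flagged; with
#' `strict = TRUE` those with effect-allele frequency in `[0.42, 0.58]`
#' (where strand cannot be resolved from frequency) are dropped.
#'
#' @param weights Weight tibble (`variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `eaf`, ...).
#' @param genotype_meta Tibble describing the dosage data: `variant_id`,
#'   `counted_allele`, `other_allele`.
#' @param strict Drop unresolvable palindromic variants (default `FALSE`;
#'   they are kept but flagged).
#'
#' @return A list with `weights` (aligned tibble with added `palindromic`
#'   flag and `action` column: `"kept"` or `"flipped"`) and `report` (tibble
#'   of dropped variants with reasons).
#' @examples
#' w <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
#'                     other_allele = "G", beta = 0.1, eaf = 0.3, pval = 1e-9)
#' meta <- tibble::tibble(variant_id = "rs1", counted_allele = "G",
#'                        other_allele = "A")
#' harmonize_weights(w, meta)$weights
#' @export
harmonize_weights <- function(weights, genotype_meta, strict = FALSE) {
  check_columns(weights, c("variant_id", "effect_allele", "other_allele",
                           "beta", "eaf"), "weights")
  check_columns(genotype_meta, c("variant_id", "counted_allele",
                                 "other_allele"), "genotype_meta")
  if (anyDuplicated(weights$variant_id) ||
      anyDuplicated(genotype_meta$variant_id)) {
    abort("Variant IDs must be unique in both inputs.")
  }

  meta <- dplyr::rename(genotype_meta, g_counted = "counted_allele",
                        g_other = "other_allele")
  joined <- dplyr::left_join(weights, meta, by = "variant_id")

  complement <- c(A = "T", T = "A", C = "G", G = "C")
  palindromic <- weights$effect_allele ==
    unname(complement[weights$other_allele])

  match <- !is.na(joined$g_counted) &
    joined$effect_allele == joined$g_counted &
    joined$other_allele == joined$g_other
  swap <- !is.na(joined$g_counted) &
    joined$effect_allele == joined$g_other &
    joined$other_allele == joined$g_counted
  absent <- is.na(joined$g_counted)
  mismatch <- !absent & !match & !swap

  reason <- rep(NA_character_, nrow(joined))
  reason[absent] <- "not in genotype data"
  reason[mismatch] <- "allele pair mismatch"

  out <- joined
  out$beta[swap] <- -out$beta[swap]
  out$eaf[swap] <- 1 - out$eaf[swap]
  out$palindromic <- palindromic
  out$action <- ifelse(swap, "flipped", "kept")

  if (strict) {
    unresolvable <- palindromic & out$eaf >= 0.42 & out$eaf <= 0.58 &
      is.na(reason)
    reason[unresolvable] <- "palindromic with ambiguous frequency"
  }

  keep <- is.na(reason)
  report <- tibble(variant_id = joined$variant_id[!keep],
                   reason = reason[!keep])
  if (nrow(report) > 0L) {
    warn(sprintf("Dropped %d variant(s) during harmonization: %s",
                 nrow(report),
                 paste0(report$variant_id, " (", report$reason, ")",
                        collapse = ", ")))
  }
  aligned <- out[keep, , drop = FALSE]
  aligned$g_counted <- NULL
  aligned$g_other <- NULL
  list(weights = aligned, report = report)
}

#' Compute a genetic risk score
#'
#' The weighted score (wGRS) is the beta-weighted dosage sum,
#' `sum_j beta_j * dosage_j`. The unweighted score (uwGRS) counts
#' trait-increasing alleles: a variant with negative harmonized beta has its
#' dosage reflected (`2 - dosage`) so every counted allele increases the
#' trait and both score flavours point the same way. Unweighted scores
#' therefore lie in `[0, 2m]`.
#'
#' @param genotypes Dosage matrix (samples x variants) with variant IDs as
#'   colnames.
#' @param weights Harmonized weight tibble; only variants present in the
#'   genotype data are used.
#' @param mode `"weighted"` or `"unweighted"`.
#' @param trait Optional trait label carried in the result.
#'
#' @return A tibble with `sample_id` and `score`, carrying attributes
#'   `weighted` (flag), `n_variants_used` and `trait`.
#' @examples
#' g <- matrix(c(0, 1, 2), 1, dimnames = list("s1", c("a", "b", "c")))
#' w <- tibble::tibble(variant_id = c("a", "b", "c"), beta = c(0.1, 0.2, 0.3))
#' compute_grs(g, w, "weighted")$score  # 0.8
#' @export
compute_grs <- function(genotypes, weights,
                        mode = c("weighted", "unweighted"), trait = NA_character_) {
  mode <- match.arg(mode)
  check_columns(weights, c("variant_id", "beta"), "weights")
  use <- intersect(weights$variant_id, colnames(genotypes))
  if (length(use) == 0L) abort("No weight variants present in the genotype data.")
  w <- weights[match(use, weights$variant_id), ]
  g <- genotypes[, use, drop = FALSE]
  score <- if (mode == "weighted") {
    drop(g %*% w$beta)
  } else {
    neg <- w$beta < 0
    if (any(neg)) g[, neg] <- 2 - g[, neg, drop = FALSE]
    rowSums(g)
  }
  out <- tibble(sample_id = rownames(genotypes) %||%
                  as.character(seq_len(nrow(genotypes))),
                score = unname(score))
  attr(out, "weighted") <- mode == "weighted"
  attr(out, "n_variants_used") <- length(use)
  attr(out, "trait") <- trait
  out
}

#' Instrument strength of a genetic risk score
#'
#' Regresses the exposure on the score and reports the coefficient of
#' determination and the F-statistic. For a single regressor these satisfy
#' `F = R^2 (n - 2) / (1 - R^2)`. Binary exposures use a linear-probability
#' regression of the 0/1 trait by default (the canonical observed-scale
#' `R^2`); `binary_r2 = "mcfadden"` reports McFadden's pseudo-R^2 from a
#' logistic fit instead (its F is still taken from the linear fit).
#'
#' @param exposure Numeric (or 0/1) exposure vector.
#' @param grs Numeric score vector.
#' @param binary_r2 `"linear"` (default) or `"mcfadden"`.
#' @return A one-row tibble with `r2`, `f_stat` and `n`.
#' @examples
#' set.seed(1)
#' g <- rnorm(100); x <- g + rnorm(100)
#' instrument_strength(x, g)
#' @export
instrument_strength <- function(exposure, grs,
                                binary_r2 = c("linear", "mcfadden")) {
  binary_r2 <- match.arg(binary_r2)
  ok <- complete.cases(exposure, grs)
  exposure <- exposure[ok]
  grs <- grs[ok]
  n <- length(exposure)
  if (n <= 2L) abort("Need more than 2 complete observations.")
  if (sd(exposure) == 0 || sd(grs) == 0) {
    abort("`exposure` and `grs` must be non-constant.")
  }
  r2 <- cor(exposure, grs)^2
  is_binary <- all(exposure %in% c(0, 1))
  if (is_binary && binary_r2 == "mcfadden") {
    fit <- glm(exposure ~ grs, family = binomial())
    r2 <- 1 - fit$deviance / fit$null.deviance
  }
  f_from_linear <- cor(exposure, grs)^2
  tibble(r2 = r2,
         f_stat = f_from_linear * (n - 2) / (1 - f_from_linear),
         n = n)
}

#' Split scores at the sample median
#'
#' Scores at or below the median are labelled `"low"` genetic risk, scores
#' above it `"high"` (ties go low). With all-equal scores everything is
#' `"low"` and a warning flags the degenerate split.
#'
#' @param grs Numeric score vector (length >= 2).
#' @return A factor with levels `low`, `high`.
#' @examples
#' dichotomize_at_median(c(1, 2, 2, 3))
#' @export
dichotomize_at_median <- function(grs) {
  if (length(grs) < 2L) abort("Need at least 2 scores to split.")
  med <- median(grs, na.rm = TRUE)
  out <- factor(ifelse(grs <= med, "low", "high"), levels = c("low", "high"))
  if (all(out == "low", na.rm = TRUE)) {
    warn("All scores fall at or below the median; the split is degenerate.")
  }
  out
}
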