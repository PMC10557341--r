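#' Read and write variant weight files
#'
#' Weight files are tab-separated with the header
#' `variant_id, effect_allele, other_allele, beta, eaf, pval`, the usual
#' shape of GWAS-derived instrument lists.
#'
#' @param path File path.
#' @return `read_weights()` returns a validated tibble.
#' @export
read_weights <- function(path) {
  w <- readr::read_tsv(path, show_col_types = FALSE)
  check_columns(w, c("variant_id", "effect_allele", "other_allele",
                     "beta", "eaf", "pval"), "weights file")
  if (any(w$effect_allele == w$other_allele)) {
    abort("Effect and other allele must differ for every variant.")
  }
  if (any(w$eaf <= 0 | w$eaf >= 1)) {
    abort("Effect-allele frequencies must lie strictly in (0, 1).")
  }
  w
}

#' @param weights Variant weight tibble.
#' @rdname read_weights
#' @export
write_weights <- function(weights, path) {
  check_columns(weights, c("variant_id", "effect_allele", "other_allele",
                           "beta", "eaf", "pval"), "weights")
  readr::write_tsv(weights, path)
  invisible(path)
}

#' Write genotype dosages as delimited text or VCF
#'
#' `write_genotypes_tsv()` writes a sample-by-variant dosage table.
#' `write_genotypes_vcf()` writes a minimal VCF 4.2 file with per-sample `GT`
#' (hard genotype from rounded dosage) and `DS` (dosage) fields, one record
#' per variant on a placeholder chromosome.
#'
#' @param genotypes Dosage matrix (samples x variants).
#' @param variants Variant table supplying alleles; the VCF `REF` column is
#'   the other allele and `ALT` the effect (counted) allele, so `DS` equals
#'   the effect-allele dosage.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  tbl <- tibble::as_tibble(genotypes, rownames = "sample_id")
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
write_genotypes_vcf <- function(genotypes, variants, path) {
  check_columns(variants, c("variant_id", "effect_allele", "other_allele"),
                "variants")
  stopifnot(ncol(genotypes) == nrow(variants))
  samples <- rownames(genotypes)
  gt_of <- function(d) c("0/0", "0/1", "1/1")[pmin(pmax(round(d), 0), 2) + 1L]
  header <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Effect-allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(variants)), function(j) {
    d <- genotypes[, j]
    cells <- paste0(gt_of(d), ":", format(d, trim = TRUE))
    paste(c("1", j, variants$variant_id[j], variants$other_allele[j],
            variants$effect_allele[j], ".", "PASS", ".", "GT:DS", cells),
          collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotype dosage table written by [write_genotypes_tsv()]
#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE)
  m <- as.matrix(tbl[, -1, drop = FALSE])
  rownames(m) <- tbl$sample_id
  m
}
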