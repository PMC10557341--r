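test_that("harmonization keeps, flips, drops and flags variants correctly", {
  w <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3", "rs4", "rs5"),
    effect_allele = c("A", "G", "C", "A", "A"),
    other_allele = c("G", "A", "T", "T", "C"),
    beta = c(0.1, 0.2, 0.3, 0.4, 0.5),
    eaf = c(0.3, 0.6, 0.5, 0.45, 0.2),
    pval = rep(1e-9, 5)
  )
  meta <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs4", "rs5"),
    counted_allele = c("A", "A", "A", "C"),
    other_allele = c("G", "G", "T", "T")
  )
  expect_warning(h <- harmonize_weights(w, meta), "rs3")
  al <- h$weights
  # rs1: identity; rs2: swap -> beta negated, eaf reflected.
  expect_equal(al$beta[al$variant_id == "rs1"], 0.1)
  expect_equal(al$action[al$variant_id == "rs1"], "kept")
  expect_equal(al$beta[al$variant_id == "rs2"], -0.2)
  expect_equal(al$eaf[al$variant_id == "rs2"], 0.4)
  # rs4 is palindromic (A/T) and flagged.
  expect_true(al$palindromic[al$variant_id == "rs4"])
  # rs5: allele pair mismatch -> dropped with reason.
  expect_true(all(c("rs3", "rs5") %in% h$report$variant_id))
  expect_equal(nrow(h$report), 2L)

  # Strict mode drops the ambiguous palindromic rs4 (eaf 0.45).
  expect_warning(hs <- harmonize_weights(w, meta, strict = TRUE))
  expect_false("rs4" %in% hs$weights$variant_id)

  # Idempotence: harmonizing already-aligned weights changes nothing.
  meta2 <- tibble::tibble(variant_id = al$variant_id,
                          counted_allele = al$effect_allele,
                          other_allele = al$other_allele)
  h2 <- harmonize_weights(al, meta2)
  expect_equal(h2$weights$beta, al$beta)
  expect_equal(h2$weights$eaf, al$eaf)
  expect_equal(nrow(h2$report), 0L)
})

test_that("the flip convention zeroes the reflected contribution", {
  # Weight effect allele is the non-counted allele; a sample carrying two
  # counted alleles has zero copies of the effect allele, so after
  # harmonization its weighted contribution must be beta * 0.
  w <- tibble::tibble(variant_id = "rs1", effect_allele = "A",
                      other_allele = "G", beta = 0.1, eaf = 0.3, pval = 1e-9)
  meta <- tibble::tibble(variant_id = "rs1", counted_allele = "G",
                         other_allele = "A")
  h <- harmonize_weights(w, meta)$weights
  g <- matrix(2, 1, 1, dimnames = list("s1", "rs1"))
  score <- compute_grs(g, h, "weighted")$score
  expect_equal(score, h$beta * 2)
  # Negated-beta convention + intercept shift 2*beta equals the reflected
  # dosage contribution beta * (2 - dosage) = 0 here.
  expect_equal(score + 2 * 0.1, 0)
})

test_that("weighted and unweighted scores follow their definitions", {
  g <- matrix(c(0, 1, 2), 1, dimnames = list("s1", c("a", "b", "c")))
  w <- tibble::tibble(variant_id = c("a", "b", "c"),
                      beta = c(0.1, 0.2, 0.3))
  expect_equal(compute_grs(g, w, "weighted")$score, 0.8)
  expect_equal(compute_grs(g, w, "unweighted")$score, 3)

  # Negative beta reflects the dosage so the counted allele is increasing.
  w2 <- tibble::tibble(variant_id = "a", beta = -0.2)
  g2 <- matrix(0, 1, 1, dimnames = list("s1", "a"))
  expect_equal(compute_grs(g2, w2, "unweighted")$score, 2)

  # Partial overlap: only matching variants used.
  w3 <- tibble::tibble(variant_id = c("a", "b", "zz", "qq", "c"),
                       beta = rep(0.1, 5))
  res <- compute_grs(g, w3, "weighted")
  expect_equal(attr(res, "n_variants_used"), 3L)
  expect_error(compute_grs(g, tibble::tibble(variant_id = "nope", beta = 1),
                           "weighted"), "No weight variants")
})

test_that("weighted scores are linear in the weights", {
  withr::with_seed(1, {
    v <- simulate_variants(10, seed = 2)
    g <- simulate_genotypes(50, v, seed = 3)
    s1 <- compute_grs(g, v, "weighted")$score
    v2 <- dplyr::mutate(v, beta = 2 * beta)
    s2 <- compute_grs(g, v2, "weighted")$score
    expect_equal(s2, 2 * s1)
  })
})

test_that("unweighted scores stay within [0, 2m]", {
  v <- simulate_variants(12, seed = 4)
  v$beta <- v$beta * sample(c(-1, 1), 12, TRUE)
  g <- simulate_genotypes(200, v, seed = 5)
  s <- compute_grs(g, v, "unweighted")$score
  expect_true(all(s >= 0 & s <= 24))
})

test_that("instrument strength satisfies the single-regressor F identity", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(instrument_strength(x, x)$r2, 1)

  withr::with_seed(6, {
    g <- rnorm(102)
    # Build an exposure with R2 exactly 0.5 via orthogonalized noise.
    e <- rnorm(102)
    e <- residuals(lm(e ~ g))
    x <- g / sd(g) + e / sd(e)
    st <- instrument_strength(x, g)
    expect_equal(st$r2, 0.5, tolerance = 1e-10)
    expect_equal(st$f_stat, 0.5 * (102 - 2) / 0.5, tolerance = 1e-8)
  })

  # Null distribution: R2 stays tiny for independent data.
  withr::with_seed(7, {
    r2s <- replicate(20, instrument_strength(rnorm(10000), rnorm(10000))$r2)
    expect_gte(mean(r2s < 0.001), 0.95)
  })

  expect_error(instrument_strength(rep(1, 10), rnorm(10)), "non-constant")
})

test_that("median dichotomization sends ties low", {
  expect_equal(as.character(dichotomize_at_median(c(1, 2, 2, 3))),
               c("low", "low", "low", "high"))
  expect_equal(as.character(dichotomize_at_median(c(1, 2, 3, 4))),
               c("low", "low", "high", "high"))
  expect_warning(out <- dichotomize_at_median(rep(5, 4)), "degenerate")
  expect_true(all(out == "low"))

  withr::with_seed(8, {
    s <- rnorm(100000)
    frac_high <- mean(dichotomize_at_median(s) == "high")
    expect_lt(abs(frac_high - 0.5), 0.01)
  })
})

test_that("independent median splits give four near-equal cells", {
  withr::with_seed(9, {
    a <- rnorm(100000)
    b <- rnorm(100000)
    tab <- table(assign_2x2_groups(a, b)) / 100000
    expect_true(all(abs(tab - 0.25) < 0.015))
  })
})
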