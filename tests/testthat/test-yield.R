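test_that("diagnostic yield counts unique diagnosed individuals", {
  v <- tibble::tibble(
    individual_id = c("a", "a", "b", "c", "d"),
    gene = c("COL4A5", "COL4A3", "UMOD", "HNF1B", "NPHP1"),
    variant_type = c("SNV", "SNV", "SNV", "CNV", "SNV"),
    chromosome_class = c("gonosome", "autosome", "autosome", "autosome", "autosome"),
    acmg_class = c(5L, 4L, 4L, 5L, 3L)
  )
  y <- diagnostic_yield(v, n_cohort = 10)
  expect_equal(y$n_diagnosed, 3) # dual diagnosis counted once; VUS excluded
  expect_equal(y$yield, 0.3)
  ysmall <- diagnostic_yield(v, 10,
    include_types = c("SNV", "indel"),
    chromosome_classes = c("autosome", "gonosome")
  )
  expect_equal(ysmall$n_diagnosed, 2)
  # invariant to row order and duplicated rows
  y2 <- diagnostic_yield(v[c(5, 3, 1, 2, 4, 1), ], n_cohort = 10)
  expect_equal(y2$n_diagnosed, y$n_diagnosed)
  empty <- diagnostic_yield(v[0, ], n_cohort = 10)
  expect_equal(empty$n_diagnosed, 0)
  expect_equal(empty$yield, 0)
})

test_that("exact binomial p equals a direct mass-summation oracle", {
  # minimum-likelihood two-sided oracle built from dbinom directly
  oracle <- function(k, n, p0) {
    probs <- stats::dbinom(0:n, n, p0)
    sum(probs[probs <= probs[k + 1] * (1 + 1e-7)])
  }
  cases <- list(
    c(10, 17), c(4, 9), c(0, 23), c(8, 94), c(5, 71), c(1, 15), c(17, 17)
  )
  for (cs in cases) {
    expect_equal(
      binomial_enrichment(cs[1], cs[2], 39 / 292),
      oracle(cs[1], cs[2], 39 / 292),
      tolerance = 1e-12
    )
  }
  # for these parameters the two-sided value coincides with the upper tail
  expect_equal(
    binomial_enrichment(10, 17, 39 / 292),
    sum(stats::dbinom(10:17, 17, 39 / 292)),
    tolerance = 1e-12
  )
  expect_error(binomial_enrichment(2, 5, 0), "between 0 and 1")
  expect_error(binomial_enrichment(6, 5, 0.5), "k <= n")
})

test_that("Bonferroni threshold is alpha over m", {
  expect_equal(bonferroni_threshold(0.05, 9), 0.05 / 9)
  expect_equal(round(bonferroni_threshold(0.05, 9), 4), 0.0056)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  ms <- 1:20
  expect_true(all(diff(bonferroni_threshold(0.05, ms)) < 0))
})

test_that("per-category enrichment sums to the diagnosed combination count", {
  v <- gckd_diagnostic_variants()
  e <- category_enrichment(v)
  expect_equal(sum(e$k), 39)
  expect_equal(sum(e$n), 292)
  expect_equal(attr(e, "baseline"), 39 / 292)
  # the hereditary-disorders category is the only Bonferroni survivor
  expect_equal(e$category[e$significant], "hereditary disorders")
})

test_that("gene-by-category matrix counts triples once", {
  v <- tibble::tibble(
    individual_id = c("a", "a", "a", "b"),
    gene = c("COL4A5", "COL4A5", "HNF1B", "UMOD"),
    categories = c("gout", "gout", "gout", "interstitial nephritis")
  )
  m <- gene_category_matrix(v)
  expect_equal(sum(m$n), 3) # duplicate (a, COL4A5, gout) collapses
  m1 <- gene_category_matrix(gckd_diagnostic_variants())
  expect_equal(sum(m1$n), 41)
  # all three UMOD entries fall in interstitial nephritis
  expect_equal(m1$n[m1$gene == "UMOD" & m1$category == "interstitial nephritis"], 3L)
})

test_that("biopsy cross-tabulation pools per-individual flags", {
  ct <- biopsy_crosstab(gckd_diagnostic_variants())
  f <- ct$fractions
  expect_equal(f$biopsied_diagnosed, 18)
  expect_equal(f$biopsied_diagnosed_pct, 52.9)
  expect_equal(f$biopsied_col4a, 17)
  expect_equal(f$biopsied_col4a_pct, 63.0)
  expect_equal(f$biopsied_unsuspected, 12)
  # eight-cell overlap covers all diagnosed individuals
  expect_equal(sum(ct$cells$n[ct$cells$diagnosis]), 34)
  # with a cohort, non-diagnosed cells fill in
  cohort <- mk_cohort(id = c("z1", "z2"), biopsy = c(TRUE, FALSE))
  ct2 <- biopsy_crosstab(gckd_diagnostic_variants(), cohort)
  expect_equal(sum(ct2$cells$n), 36)
})

test_that("rank comparison handles degenerate and null inputs", {
  expect_equal(group_compare(c(1, 1, 1), c(1, 1))$p_value, 1)
  expect_error(group_compare(numeric(0), 1), "non-empty")
  # identical samples give p = 1 under tie handling
  x <- c(1, 2, 3, 4, 5)
  expect_equal(group_compare(x, x)$p_value, 1)
})

test_that("rank comparison holds its size under the null", {
  # p values from the rank-sum test at these group sizes are discrete, so
  # check calibration of the rejection rate at several levels rather than
  # a continuous-uniform fit
  set.seed(101)
  ps <- replicate(1000, {
    group_compare(stats::rlnorm(20, 5, 1.3), stats::rlnorm(25, 5, 1.3))$p_value
  })
  for (alpha in c(0.05, 0.10, 0.20)) {
    # 3 binomial SE around the nominal level
    expect_lt(abs(mean(ps < alpha) - alpha), 3 * sqrt(alpha * (1 - alpha) / 1000))
  }
})

test_that("fold enrichment and prevalence interpolation are plain rate arithmetic", {
  expect_equal(round(fold_enrichment(5, 271, 12, 3315), 1), 5.1)
  expect_equal(fold_enrichment(7, 271, 7, 271), 1)
  expect_equal(fold_enrichment(3, 100, 6, 200), 1)
  expect_warning(out <- fold_enrichment(1, 10, 0, 10), "undefined")
  expect_true(is.na(out))
  expect_equal(round(interpolate_prevalence(7, 5217), 2), 0.13)
  expect_equal(interpolate_prevalence(0, 100), 0)
  expect_equal(interpolate_prevalence(50, 50), 100)
})
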