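test_that("reference cohort matches its configured counts exactly", {
  ref <- simulate_reference_cohort(seed = 4)
  expect_equal(nrow(ref), 3315)
  expect_equal(sum(ref$diagnostic), round(3315 * 0.093))
  expect_equal(sum(ref$bucket == "COL4A"), 108)
  expect_equal(sum(ref$bucket == "ADTKD_small"), 12)
  # deterministic allocation, randomized order
  ref2 <- simulate_reference_cohort(seed = 4)
  expect_identical(ref, ref2)
  ref3 <- simulate_reference_cohort(seed = 5)
  expect_false(identical(ref$bucket, ref3$bucket))
  expect_equal(sort(ref$bucket), sort(ref3$bucket))
  # degenerate configs
  none <- simulate_reference_cohort(
    reference_cohort_config(n_total = 10, diagnostic_fraction = 0, gene_distribution = NULL),
    seed = 1
  )
  expect_equal(sum(none$diagnostic), 0)
  expect_error(
    reference_cohort_config(n_total = 100, diagnostic_fraction = 0.05,
      gene_distribution = c(COL4A = 10)),
    "configuration error"
  )
})

test_that("detectability predicate follows panel membership and variant type", {
  panel <- panel_definition()
  mk <- function(gene, vtype, chrom, diag = TRUE) {
    tibble::tibble(
      diagnostic = diag, gene = gene, variant_type = vtype,
      chromosome_class = chrom
    )
  }
  expect_true(is_panel_detectable(mk("COL4A5", "SNV", "gonosome"), panel))
  expect_false(is_panel_detectable(mk("PKD1", "SNV", "autosome"), panel))
  expect_false(is_panel_detectable(mk("UMOD", "CNV", "autosome"), panel))
  expect_false(is_panel_detectable(mk("MT-TF", "mito_SNV", "mitochondrial"), panel))
  expect_false(is_panel_detectable(mk("COL4A5", "SNV", "gonosome", diag = FALSE), panel))
  # full-scope panel mode recovers CNV and mitochondrial calls
  full <- panel_definition(
    detectable_types = c("SNV", "indel", "CNV", "mito_SNV"),
    chromosome_classes = c("autosome", "gonosome", "mitochondrial")
  )
  expect_true(is_panel_detectable(mk("UMOD", "CNV", "autosome"), full))
  expect_error(panel_definition(genes = c("COL4A3", "UMOD")), "ADTKD")
})

test_that("null yield matches closed-form hypergeometric moments", {
  ref <- simulate_reference_cohort(seed = 2)
  n_det <- sum(is_panel_detectable(ref))
  expect_equal(n_det, 120)
  reps <- 4000
  null <- simulate_null_yield(ref, n_draw = 271, reps = reps, seed = 9)
  counts <- null$statistics * 271
  N <- 3315
  mean_hyper <- 271 * n_det / N
  var_hyper <- 271 * (n_det / N) * (1 - n_det / N) * (N - 271) / (N - 1)
  se_mean <- sqrt(var_hyper / reps)
  expect_lt(abs(mean(counts) - mean_hyper), 3 * se_mean)
  se_var <- var_hyper * sqrt(2 / (reps - 1))
  expect_lt(abs(stats::var(counts) - var_hyper), 3 * se_var)
  # determinism
  null2 <- simulate_null_yield(ref, n_draw = 271, reps = 50, seed = 9)
  expect_identical(null2$statistics, null$statistics[1:50])
})

test_that("null is degenerate when nothing is detectable and errors on overdraw", {
  ref <- simulate_reference_cohort(
    reference_cohort_config(n_total = 50, diagnostic_fraction = 0, gene_distribution = NULL),
    seed = 1
  )
  null <- simulate_null_yield(ref, n_draw = 20, reps = 25, seed = 1)
  expect_true(all(null$statistics == 0))
  expect_error(simulate_null_yield(ref, n_draw = 100, reps = 5, seed = 1), "exceeds")
})

test_that("empirical p uses the add-one convention and is monotone", {
  null <- simulate_null_yield(
    simulate_reference_cohort(seed = 3),
    n_draw = 100, reps = 200, seed = 3
  )
  lo <- empirical_p(null, observed = -1, direction = "greater")
  expect_equal(lo$empirical_p, 1)
  hi <- empirical_p(null, observed = 2, direction = "greater")
  expect_equal(hi$empirical_p, 1 / 201)
  obs_grid <- seq(0, 0.12, by = 0.005)
  ps <- vapply(
    obs_grid,
    function(o) empirical_p(null, o, "greater")$empirical_p,
    numeric(1)
  )
  expect_true(all(diff(ps) <= 0))
})

test_that("COL4A fraction null lies in [0, 1] and excludes empty draws", {
  ref <- simulate_reference_cohort(seed = 6)
  null <- simulate_col4a_fraction(ref, n_draw = 271, reps = 300, seed = 6)
  s <- null$statistics[!is.na(null$statistics)]
  expect_true(all(s >= 0 & s <= 1))
  expect_equal(null$n_excluded, sum(is.na(null$statistics)))
  # reference whose only detectable members are COL4A -> all fractions 1
  only_col4a <- simulate_reference_cohort(
    reference_cohort_config(
      n_total = 200, diagnostic_fraction = 0.5,
      gene_distribution = c(COL4A = 100)
    ),
    seed = 1
  )
  n1 <- simulate_col4a_fraction(only_col4a, n_draw = 50, reps = 40, seed = 2)
  expect_true(all(n1$statistics == 1))
})

test_that("exome-mode null centres on the reference diagnostic fraction", {
  ref <- simulate_reference_cohort(seed = 8)
  exome_panel <- structure(
    list(
      genes = unique(ref$gene[!is.na(ref$gene)]),
      detectable_types = c("SNV", "indel", "CNV", "mito_SNV"),
      chromosome_classes = c("autosome", "gonosome", "mitochondrial")
    ),
    class = "panel_definition"
  )
  null <- simulate_null_yield(ref, exome_panel, n_draw = 271, reps = 1500, seed = 8)
  expect_lt(abs(mean(null$statistics) - 0.093), 0.005)
})

test_that("null tidiers and plot expose replicate statistics", {
  ref <- simulate_reference_cohort(seed = 1)
  null <- empirical_p(
    simulate_null_yield(ref, n_draw = 271, reps = 100, seed = 1),
    observed = 30 / 271
  )
  td <- tidy(null)
  expect_equal(nrow(td), 100)
  g <- glance(null)
  expect_equal(g$reps, 100)
  expect_equal(g$observed, 30 / 271)
  p <- autoplot(null)
  expect_s3_class(p, "ggplot")
})
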