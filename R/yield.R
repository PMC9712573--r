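#' Diagnostic yield of a variant table
#'
#' The diagnostic yield is the fraction of sequenced individuals who
#' carry at least one class-4/5 (likely pathogenic / pathogenic) variant;
#' individuals with a dual diagnosis count once. Restricting
#' `include_types` and `chromosome_classes` to small variants on nuclear
#' chromosomes gives the exome-comparable yield (the reference exome
#' study analyzed neither CNVs nor the mitochondrial genome).
#'
#' @param variants Variant tibble with columns `individual_id`,
#'   `acmg_class`, `variant_type`, `chromosome_class`.
#' @param n_cohort Number of sequenced individuals (the denominator).
#' @param include_types Variant types counted towards the yield.
#' @param chromosome_classes Chromosome classes counted.
#' @param diagnostic_classes ACMG classes considered diagnostic.
#' @return One-row tibble: `n_diagnosed`, `n_cohort`, `yield`,
#'   `yield_pct`, and a list-column `ids` of diagnosed individuals.
#' @examples
#' diagnostic_yield(gckd_diagnostic_variants(), n_cohort = 271)
#' @export
diagnostic_yield <- function(variants, n_cohort,
                             include_types = variant_types(),
                             chromosome_classes = c(
                               "autosome", "gonosome", "mitochondrial"
                             ),
                             diagnostic_classes = c(4L, 5L)) {
  if (!is.numeric(n_cohort) || n_cohort <= 0) {
    stop("n_cohort must be positive", call. = FALSE)
  }
  variants <- tibble::as_tibble(variants)
  hits <- variants |>
    dplyr::filter(
      .data$acmg_class %in% diagnostic_classes,
      .data$variant_type %in% include_types,
      .data$chromosome_class %in% chromosome_classes
    )
  ids <- sort(unique(hits$individual_id))
  tibble::tibble(
    n_diagnosed = length(ids),
    n_cohort = as.integer(n_cohort),
    yield = length(ids) / n_cohort,
    yield_pct = round(100 * length(ids) / n_cohort, 1),
    ids = list(ids)
  )
}

#' Exact binomial enrichment test
#'
#' Two-sided exact binomial p value of observing `k` diagnosed among `n`
#' combinations when the pooled baseline rate is `p0`, computed by the
#' minimum-likelihood method (the sum of outcome probabilities no larger
#' than that of the observed count). For the rates arising here this
#' coincides with the upper-tail sum.
#'
#' @param k Diagnosed combinations in the category.
#' @param n Total combinations in the category.
#' @param p0 Pooled baseline diagnostic rate, in (0, 1).
#' @return The p value.
#' @examples
#' binomial_enrichment(10, 17, 39 / 292)
#' @export
binomial_enrichment <- function(k, n, p0) {
  if (any(p0 <= 0) || any(p0 >= 1)) {
    stop("baseline probability p0 must lie strictly between 0 and 1", call. = FALSE)
  }
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n", call. = FALSE)
  mapply(function(k, n, p0) stats::binom.test(k, n, p0)$p.value, k, n, p0)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param m Number of tests (here, the nine clinical categories).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 9)
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (any(m < 1)) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' Per-category enrichment of diagnostic findings
#'
#' Splits diagnosed individuals by clinical category (one count per
#' individual-category combination), tests each category against the
#' pooled baseline `k_total / n_total` with the exact binomial test, and
#' flags categories surviving the Bonferroni threshold. Categories whose
#' combination totals are not printed in the source material are marked
#' by the `source` column of `category_totals`.
#'
#' @param variants Diagnostic variant tibble carrying `individual_id` and
#'   `categories` (semicolon-separated labels).
#' @param category_totals Tibble `category`, `n_combinations` (and
#'   optionally `source`); defaults to the packaged cohort totals
#'   [gckd_category_counts()].
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @return Tibble with one row per category: `k`, `n`, `rate`,
#'   `p_binomial`, `significant`, plus the baseline and threshold as
#'   attributes `"baseline"` and `"threshold"`.
#' @examples
#' category_enrichment(gckd_diagnostic_variants())
#' @export
category_enrichment <- function(variants,
                                category_totals = gckd_category_counts(),
                                alpha = 0.05) {
  variants <- tibble::as_tibble(variants)
  category_totals <- tibble::as_tibble(category_totals)
  check_labels(category_totals$category, gckd_categories(), "category")

  combos <- diagnosed_combinations(variants)
  counts <- combos |>
    dplyr::count(.data$category, name = "k")

  n_total <- sum(category_totals$n_combinations)
  k_total <- nrow(combos)
  baseline <- k_total / n_total
  threshold <- bonferroni_threshold(alpha, nrow(category_totals))

  out <- category_totals |>
    dplyr::left_join(counts, by = "category") |>
    dplyr::mutate(
      k = dplyr::coalesce(.data$k, 0L),
      n = .data$n_combinations,
      rate = .data$k / .data$n,
      p_binomial = binomial_enrichment(.data$k, .data$n, baseline),
      significant = .data$p_binomial < threshold
    ) |>
    dplyr::select(-dplyr::any_of("n_combinations")) |>
    dplyr::arrange(.data$p_binomial)
  attr(out, "baseline") <- baseline
  attr(out, "threshold") <- threshold
  out
}

# (individual, category) combinations among diagnosed individuals:
# each individual contributes one row per category label it carries.
diagnosed_combinations <- function(variants) {
  variants |>
    dplyr::distinct(.data$individual_id, .data$categories) |>
    tidyr::separate_longer_delim("categories", delim = ";") |>
    dplyr::rename(category = "categories") |>
    dplyr::mutate(category = trimws(.data$category)) |>
    dplyr::filter(nzchar(.data$category)) |>
    dplyr::distinct(.data$individual_id, .data$category)
}

#' Gene-by-category combination matrix
#'
#' Counts each (individual, category, gene) triple once for individuals
#' with a class-4/5 variant in that gene. Individuals with diagnostic
#' variants in two genes contribute one triple per gene, so the matrix
#' total exceeds the individual-by-category combination count by the
#' dual-variant surplus.
#'
#' @param variants Diagnostic variant tibble with `individual_id`,
#'   `gene`, `categories`.
#' @return Tibble `gene`, `category`, `n` with one row per non-empty
#'   cell.
#' @examples
#' m <- gene_category_matrix(gckd_diagnostic_variants())
#' sum(m$n)
#' @export
gene_category_matrix <- function(variants) {
  tibble::as_tibble(variants) |>
    dplyr::distinct(.data$individual_id, .data$gene, .data$categories) |>
    tidyr::separate_longer_delim("categories", delim = ";") |>
    dplyr::rename(category = "categories") |>
    dplyr::mutate(category = trimws(.data$category)) |>
    dplyr::filter(nzchar(.data$category)) |>
    dplyr::distinct(.data$individual_id, .data$gene, .data$category) |>
    dplyr::count(.data$gene, .data$category, name = "n") |>
    dplyr::arrange(.data$gene, .data$category)
}

#' Overlap of genetic diagnosis, prior biopsy and hereditary suspicion
#'
#' Cross-tabulates diagnosed individuals (optionally against the rest of
#' the cohort) by whether a kidney biopsy was performed before inclusion
#' and whether a hereditary disorder was clinically suspected. Returns
#' the eight-cell overlap plus the derived fractions the screen reports:
#' biopsied among all diagnosed and among COL4A3/4/5-diagnosed, and
#' biopsied diagnosed individuals without prior suspicion.
#'
#' @param variants Diagnostic variant tibble with `individual_id`,
#'   `gene`, `biopsy`, `hereditary_suspected`.
#' @param cohort Optional registry tibble (columns `id`, `biopsy`,
#'   `hereditary_suspected`) supplying the non-diagnosed cells.
#' @return A list with class `"biopsy_crosstab"`: `cells` (tibble
#'   `diagnosis`, `biopsy`, `suspected`, `n`) and `fractions` (one-row
#'   tibble).
#' @examples
#' biopsy_crosstab(gckd_diagnostic_variants())$fractions
#' @export
biopsy_crosstab <- function(variants, cohort = NULL) {
  variants <- tibble::as_tibble(variants)
  diag <- variants |>
    dplyr::group_by(.data$individual_id) |>
    dplyr::summarise(
      biopsy = any(.data$biopsy),
      suspected = any(.data$hereditary_suspected),
      col4a = any(.data$gene %in% c("COL4A3", "COL4A4", "COL4A5")),
      .groups = "drop"
    ) |>
    dplyr::mutate(diagnosis = TRUE)

  people <- diag
  if (!is.null(cohort)) {
    rest <- tibble::as_tibble(cohort) |>
      dplyr::filter(!.data$id %in% diag$individual_id) |>
      dplyr::transmute(
        individual_id = .data$id,
        biopsy = .data$biopsy,
        suspected = .data$hereditary_suspected,
        col4a = FALSE,
        diagnosis = FALSE
      )
    people <- dplyr::bind_rows(diag, rest)
  }

  cells <- tidyr::expand_grid(
    diagnosis = c(TRUE, FALSE), biopsy = c(TRUE, FALSE), suspected = c(TRUE, FALSE)
  ) |>
    dplyr::left_join(
      dplyr::count(people, .data$diagnosis, .data$biopsy, .data$suspected),
      by = c("diagnosis", "biopsy", "suspected")
    ) |>
    dplyr::mutate(n = dplyr::coalesce(.data$n, 0L))

  n_diag <- sum(diag$diagnosis)
  fractions <- tibble::tibble(
    n_diagnosed = n_diag,
    biopsied_diagnosed = sum(diag$biopsy),
    biopsied_diagnosed_pct = round(100 * sum(diag$biopsy) / n_diag, 1),
    n_col4a = sum(diag$col4a),
    biopsied_col4a = sum(diag$biopsy & diag$col4a),
    biopsied_col4a_pct = round(100 * sum(diag$biopsy & diag$col4a) / sum(diag$col4a), 1),
    biopsied_unsuspected = sum(diag$biopsy & !diag$suspected)
  )

  structure(list(cells = cells, fractions = fractions), class = "biopsy_crosstab")
}

#' @export
print.biopsy_crosstab <- function(x, ...) {
  f <- x$fractions
  cat(
    "<biopsy_crosstab> biopsied among diagnosed: ", f$biopsied_diagnosed,
    "/", f$n_diagnosed, " (", f$biopsied_diagnosed_pct, "%); among COL4A: ",
    f$biopsied_col4a, "/", f$n_col4a, " (", f$biopsied_col4a_pct,
    "%); biopsied without suspicion: ", f$biopsied_unsuspected, "\n",
    sep = ""
  )
  invisible(x)
}

#' Rank-based comparison of kidney-function values between groups
#'
#' Two-sided rank-sum (Mann-Whitney) comparison of a measurement between
#' independent groups, e.g. ACR in diagnosed versus non-diagnosed
#' individuals. The groups compared here are independent and of unequal
#' size, so the rank-sum test for independent samples is the applicable
#' procedure (a signed-rank test requires paired observations).
#' Degenerate inputs in which every value ties return p = 1.
#'
#' @param values_a,values_b Numeric measurement vectors; both non-empty.
#' @return One-row tibble `statistic`, `p_value`, `method`.
#' @examples
#' group_compare(c(300, 500, 900), c(100, 150, 220, 90))
#' @export
group_compare <- function(values_a, values_b) {
  if (length(values_a) == 0 || length(values_b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(values_a, values_b))) == 1) {
    return(tibble::tibble(
      statistic = NA_real_, p_value = 1,
      method = "Wilcoxon rank sum (degenerate ties)"
    ))
  }
  wt <- suppressWarnings(stats::wilcox.test(values_a, values_b, alternative = "two.sided"))
  tibble::tibble(
    statistic = unname(wt$statistic),
    p_value = min(1, wt$p.value),
    method = wt$method
  )
}

#' Fold enrichment between two rates
#'
#' `(k1/n1) / (k2/n2)` — e.g. ADTKD small-variant carriage in the panel
#' cohort versus the reference exome cohort.
#'
#' @param k1,n1 Numerator rate counts.
#' @param k2,n2 Denominator rate counts.
#' @return The ratio; `NA` with a warning when the denominator rate is
#'   zero.
#' @examples
#' fold_enrichment(5, 271, 12, 3315)
#' @export
fold_enrichment <- function(k1, n1, k2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("cohort sizes must be positive", call. = FALSE)
  if (k2 == 0) {
    warning("denominator rate is zero; fold enrichment undefined")
    return(NA_real_)
  }
  (k1 / n1) / (k2 / n2)
}

#' Interpolate a prevalence to the full registry
#'
#' Assuming complete enrichment through the selection criteria, `k`
#' diagnosed carriers among the selected cohort are interpolated to the
#' full registry of `n_full_cohort` members as a percentage.
#'
#' @param k Diagnosed carriers.
#' @param n_full_cohort Full registry size.
#' @return Percentage `100 * k / n_full_cohort`.
#' @examples
#' interpolate_prevalence(7, 5217)
#' @export
interpolate_prevalence <- function(k, n_full_cohort) {
  if (n_full_cohort <= 0) stop("n_full_cohort must be positive", call. = FALSE)
  100 * k / n_full_cohort
}
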