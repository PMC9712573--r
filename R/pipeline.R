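#' Run configuration for the end-to-end analysis
#'
#' Bundles every tunable of the pipeline: the selection criteria, the
#' Bayesian classification constants, the panel definition, the
#' resampling design and the report precision, plus the single seed that
#' drives all randomness.
#'
#' @param seed Integer seed recorded in every output.
#' @param criteria A [filter_criteria()].
#' @param bayes A [bayes_params()].
#' @param panel A [panel_definition()].
#' @param n_draw,reps Resampling design (draw size and replicates).
#' @param alpha Family-wise error rate for the enrichment threshold.
#' @param report_precision Decimals for percentages in the report.
#' @return A list with class `"run_config"`.
#' @export
run_config <- function(seed = 1,
                       criteria = filter_criteria(),
                       bayes = bayes_params(),
                       panel = panel_definition(),
                       n_draw = 271, reps = 10000,
                       alpha = 0.05,
                       report_precision = 1) {
  if (!is.numeric(reps) || reps < 1) {
    stop("configuration error: 'reps' must be at least 1", call. = FALSE)
  }
  if (!is.numeric(n_draw) || n_draw < 1) {
    stop("configuration error: 'n_draw' must be at least 1", call. = FALSE)
  }
  structure(
    list(
      seed = as.integer(seed), criteria = criteria, bayes = bayes,
      panel = panel, n_draw = n_draw, reps = reps, alpha = alpha,
      report_precision = report_precision
    ),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys: `seed`, `n_draw`, `reps`, `alpha`,
#' `report_precision`, `bayes` (`prior`, `odds_pvst`), `panel`
#' (`genes`, `detectable_types`, `chromosome_classes`). Unknown keys are
#' an error so typos do not silently fall back to defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  parsed <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("seed", "n_draw", "reps", "alpha", "report_precision", "bayes", "panel")
  unknown <- setdiff(names(parsed), known)
  if (length(unknown) > 0) {
    stop("configuration error: unknown keys: ", paste(unknown, collapse = ", "),
      call. = FALSE
    )
  }
  args <- parsed[intersect(names(parsed), c("seed", "n_draw", "reps", "alpha", "report_precision"))]
  if (!is.null(parsed$bayes)) args$bayes <- do.call(bayes_params, parsed$bayes)
  if (!is.null(parsed$panel)) args$panel <- do.call(panel_definition, parsed$panel)
  do.call(run_config, args)
}

#' Run the full screen analysis
#'
#' Executes the pipeline end to end: selection funnel (when a registry
#' is supplied), variant classification (when evidence tokens are
#' present), diagnostic yield overall and in exome-comparable mode,
#' per-category enrichment, the gene-by-category matrix, the biopsy
#' cross-tabulation, the ADTKD fold-enrichment and full-registry
#' prevalence interpolation, and the resampling null against the
#' synthetic reference cohort. With no inputs it analyses the packaged
#' diagnostic-variant list against the printed cohort structure
#' (n = 271, full registry 5217).
#'
#' @param config A [run_config()].
#' @param cohort Optional registry tibble; defaults to the printed
#'   cohort structure of the screen.
#' @param variants Optional variant tibble; defaults to
#'   [gckd_diagnostic_variants()].
#' @param reference Optional reference cohort tibble; defaults to
#'   [simulate_reference_cohort()] under the default configuration.
#' @param category_totals Per-category combination totals for the
#'   enrichment test.
#' @param n_full_registry Full registry size for the prevalence
#'   interpolation.
#' @param out Optional path; when given, the report is written there as
#'   JSON.
#' @return A list with class `"tikd_report"` containing every computed
#'   statistic plus the seed and a config hash.
#' @examples
#' rep <- run_pipeline(run_config(seed = 1, reps = 200))
#' rep$yield$yield_pct
#' @export
run_pipeline <- function(config = run_config(),
                         cohort = NULL,
                         variants = NULL,
                         reference = NULL,
                         category_totals = gckd_category_counts(),
                         n_full_registry = 5217,
                         out = NULL) {
  stopifnot(inherits(config, "run_config"))
  message("stage: inputs")
  if (is.null(variants)) variants <- gckd_diagnostic_variants()

  funnel <- NULL
  n_cohort <- 271L
  if (!is.null(cohort)) {
    message("stage: selection funnel")
    selection <- cohort |>
      select_entries(config$criteria) |>
      dedupe_entries() |>
      apply_qc(cohort)
    funnel <- glance(selection)
    n_cohort <- funnel$n_final
  }

  if (!"acmg_class" %in% names(variants) && "evidence" %in% names(variants)) {
    message("stage: classification")
    variants <- classify_variants(variants, config$bayes) |>
      dplyr::rename(acmg_class = "categorical_class")
  }

  message("stage: yield")
  yield_all <- diagnostic_yield(variants, n_cohort)
  yield_small <- diagnostic_yield(
    variants, n_cohort,
    include_types = c("SNV", "indel"),
    chromosome_classes = c("autosome", "gonosome")
  )

  message("stage: enrichment")
  enrichment <- category_enrichment(variants, category_totals, alpha = config$alpha)
  matrix_gc <- gene_category_matrix(variants)
  crosstab <- biopsy_crosstab(variants, cohort)

  adtkd_genes <- c("MUC1", "UMOD", "REN", "HNF1B", "SEC61A1")
  adtkd_small <- variants |>
    dplyr::filter(
      .data$gene %in% adtkd_genes,
      .data$variant_type %in% c("SNV", "indel"),
      .data$acmg_class %in% c(4L, 5L)
    )
  adtkd_all <- variants |>
    dplyr::filter(.data$gene %in% adtkd_genes, .data$acmg_class %in% c(4L, 5L))
  fold <- fold_enrichment(nrow(adtkd_small), n_cohort, 12, 3315)
  prevalence <- interpolate_prevalence(
    length(unique(adtkd_all$individual_id)), n_full_registry
  )

  message("stage: resampling")
  if (is.null(reference)) {
    reference <- simulate_reference_cohort(reference_cohort_config(), seed = config$seed)
  }
  null_yield <- simulate_null_yield(
    reference, config$panel,
    n_draw = config$n_draw, reps = config$reps, seed = config$seed
  )
  null_yield <- empirical_p(null_yield, yield_small$yield, direction = "greater")

  col4a_small_ids <- variants |>
    dplyr::filter(
      .data$gene %in% c("COL4A3", "COL4A4", "COL4A5"),
      .data$variant_type %in% c("SNV", "indel"),
      .data$acmg_class %in% c(4L, 5L)
    ) |>
    dplyr::pull("individual_id") |>
    unique()
  observed_col4a_fraction <- length(col4a_small_ids) /
    max(1, yield_small$n_diagnosed)
  null_col4a <- simulate_col4a_fraction(
    reference, config$panel,
    n_draw = config$n_draw, reps = config$reps, seed = config$seed + 1L
  )
  null_col4a <- empirical_p(null_col4a, observed_col4a_fraction, direction = "two_sided")

  report <- structure(
    list(
      seed = config$seed,
      config_hash = rlang::hash(config),
      funnel = funnel,
      yield = yield_all,
      yield_small_nuclear = yield_small,
      enrichment = enrichment,
      enrichment_baseline = attr(enrichment, "baseline"),
      enrichment_threshold = attr(enrichment, "threshold"),
      gene_category = matrix_gc,
      biopsy = crosstab,
      adtkd_fold_enrichment = fold,
      adtkd_prevalence_pct = round(prevalence, 2),
      observed_col4a_fraction = observed_col4a_fraction,
      null_yield = null_yield,
      null_col4a = null_col4a
    ),
    class = "tikd_report"
  )
  if (!is.null(out)) write_report_json(report, out)
  report
}

#' @export
print.tikd_report <- function(x, ...) {
  cat("<tikd_report> seed ", x$seed, "\n", sep = "")
  cat(
    "  diagnostic yield: ", x$yield$n_diagnosed, "/", x$yield$n_cohort,
    " (", x$yield$yield_pct, "%); small nuclear variants: ",
    x$yield_small_nuclear$n_diagnosed, "/", x$yield_small_nuclear$n_cohort,
    " (", x$yield_small_nuclear$yield_pct, "%)\n",
    sep = ""
  )
  sig <- x$enrichment$category[x$enrichment$significant]
  cat(
    "  enriched categories (Bonferroni ",
    signif(x$enrichment_threshold, 3), "): ",
    if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
    sep = ""
  )
  cat(
    "  resampling null: empirical p (yield) ",
    signif(x$null_yield$empirical_p, 3), "; COL4A fraction p ",
    signif(x$null_col4a$empirical_p, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Write an analysis report as JSON
#'
#' @param report A `"tikd_report"` from [run_pipeline()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  null_summary <- function(nd) {
    g <- glance.tikd_null(nd)
    as.list(g)
  }
  payload <- list(
    seed = report$seed,
    config_hash = report$config_hash,
    funnel = if (is.null(report$funnel)) NULL else as.list(report$funnel),
    yield = as.list(report$yield[, c("n_diagnosed", "n_cohort", "yield", "yield_pct")]),
    yield_small_nuclear = as.list(
      report$yield_small_nuclear[, c("n_diagnosed", "n_cohort", "yield", "yield_pct")]
    ),
    enrichment = report$enrichment,
    enrichment_baseline = report$enrichment_baseline,
    enrichment_threshold = report$enrichment_threshold,
    gene_category = report$gene_category,
    biopsy_cells = report$biopsy$cells,
    biopsy_fractions = as.list(report$biopsy$fractions),
    adtkd_fold_enrichment = report$adtkd_fold_enrichment,
    adtkd_prevalence_pct = report$adtkd_prevalence_pct,
    observed_col4a_fraction = report$observed_col4a_fraction,
    null_yield = null_summary(report$null_yield),
    null_col4a = null_summary(report$null_col4a)
  )
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
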