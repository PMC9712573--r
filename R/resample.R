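#' Panel definition and detectability predicate
#'
#' A reference-cohort member counts towards the panel yield when it is
#' diagnostic, its gene is on the panel, its variant type is among the
#' detectable types and its chromosome class is covered. The comparison
#' mode used against the reference exome study restricts to small
#' variants (SNV, indel) on the nuclear chromosomes, since that study
#' analyzed neither CNVs nor the mitochondrial genome.
#'
#' @param genes Panel gene symbols (default [panel_genes()]).
#' @param detectable_types Variant types counted as detectable.
#' @param chromosome_classes Chromosome classes counted as detectable.
#' @return A list with class `"panel_definition"`.
#' @export
panel_definition <- function(genes = panel_genes(),
                             detectable_types = c("SNV", "indel"),
                             chromosome_classes = c("autosome", "gonosome")) {
  required <- c("COL4A3", "COL4A4", "COL4A5", "MUC1", "UMOD", "REN", "HNF1B", "SEC61A1")
  missing <- setdiff(required, genes)
  if (length(missing) > 0) {
    stop(
      "panel must always contain the COL4A and classical ADTKD genes; missing: ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  structure(
    list(
      genes = genes,
      detectable_types = detectable_types,
      chromosome_classes = chromosome_classes
    ),
    class = "panel_definition"
  )
}

#' @rdname panel_definition
#' @param members A reference-cohort tibble from
#'   [simulate_reference_cohort()] (columns `diagnostic`, `gene`,
#'   `variant_type`, `chromosome_class`).
#' @param panel A [panel_definition()].
#' @return For `is_panel_detectable()`, a logical vector over the rows of
#'   `members`.
#' @examples
#' ref <- simulate_reference_cohort(seed = 1)
#' sum(is_panel_detectable(ref, panel_definition()))
#' @export
is_panel_detectable <- function(members, panel = panel_definition()) {
  members <- tibble::as_tibble(members)
  members$diagnostic &
    !is.na(members$gene) & members$gene %in% panel$genes &
    members$variant_type %in% panel$detectable_types &
    members$chromosome_class %in% panel$chromosome_classes
}

new_null_distribution <- function(statistics, reps, n_draw, seed, statistic,
                                  n_excluded = 0L) {
  structure(
    list(
      statistics = statistics, reps = reps, n_draw = n_draw, seed = seed,
      statistic = statistic, n_excluded = n_excluded,
      observed = NULL, empirical_p = NULL, direction = NULL
    ),
    class = "tikd_null"
  )
}

#' Resampling null distribution of panel-detectable yield
#'
#' Repeatedly draws `n_draw` members without replacement from the
#' reference cohort and records the fraction detectable by the panel.
#' Because draws are without replacement, the per-replicate detectable
#' count follows the hypergeometric law, which serves as the closed-form
#' oracle for the null's moments.
#'
#' @param reference Reference cohort tibble from
#'   [simulate_reference_cohort()].
#' @param panel A [panel_definition()].
#' @param n_draw Members per draw (default 271, the screened cohort
#'   size).
#' @param reps Number of replicates (default 10000).
#' @param seed Integer seed; fully determines the replicate statistics.
#' @return A `"tikd_null"` object; see [empirical_p()], [tidy.tikd_null()]
#'   and [glance.tikd_null()].
#' @examples
#' ref <- simulate_reference_cohort(seed = 1)
#' null <- simulate_null_yield(ref, reps = 100, seed = 1)
#' glance(null)
#' @export
simulate_null_yield <- function(reference, panel = panel_definition(),
                                n_draw = 271, reps = 10000, seed) {
  detectable <- is_panel_detectable(reference, panel)
  n_pop <- length(detectable)
  if (n_draw > n_pop) {
    stop("n_draw (", n_draw, ") exceeds the reference cohort size (", n_pop, ")",
      call. = FALSE
    )
  }
  if (reps < 1) stop("reps must be at least 1", call. = FALSE)
  set.seed(seed)
  stats <- vapply(
    seq_len(reps),
    function(i) sum(detectable[sample.int(n_pop, n_draw)]) / n_draw,
    numeric(1)
  )
  new_null_distribution(stats, reps, n_draw, seed, statistic = "detectable_fraction")
}

#' Resampling null of the COL4A fraction among detectable draws
#'
#' Per replicate, the fraction of panel-detectable drawn members whose
#' variant falls in the COL4A3/4/5 bucket. Replicates with zero
#' detectable members have an undefined fraction; they are recorded as
#' `NA`, counted in `n_excluded` and skipped by [empirical_p()].
#'
#' @inheritParams simulate_null_yield
#' @export
simulate_col4a_fraction <- function(reference, panel = panel_definition(),
                                    n_draw = 271, reps = 10000, seed) {
  reference <- tibble::as_tibble(reference)
  detectable <- is_panel_detectable(reference, panel)
  col4a <- detectable & reference$bucket == "COL4A"
  n_pop <- length(detectable)
  if (n_draw > n_pop) {
    stop("n_draw (", n_draw, ") exceeds the reference cohort size (", n_pop, ")",
      call. = FALSE
    )
  }
  set.seed(seed)
  stats <- vapply(seq_len(reps), function(i) {
    idx <- sample.int(n_pop, n_draw)
    k <- sum(detectable[idx])
    if (k == 0) NA_real_ else sum(col4a[idx]) / k
  }, numeric(1))
  new_null_distribution(
    stats, reps, n_draw, seed,
    statistic = "col4a_fraction", n_excluded = sum(is.na(stats))
  )
}

#' Empirical p value of an observed statistic against a resampling null
#'
#' Uses the add-one convention `(b + 1) / (m + 1)` where `b` counts
#' replicates at least as extreme as the observation and `m` the valid
#' replicates, so the p value is never exactly zero and the smallest
#' reportable value at 10,000 replicates is just under 1e-4. The
#' two-sided p doubles the smaller tail (capped at 1).
#'
#' @param null A `"tikd_null"` object.
#' @param observed Observed value of the statistic.
#' @param direction `"greater"` (is the observation high?) or
#'   `"two_sided"`.
#' @return The `"tikd_null"` object with `observed`, `direction` and
#'   `empirical_p` set; use `$empirical_p` for the number.
#' @examples
#' ref <- simulate_reference_cohort(seed = 1)
#' null <- simulate_null_yield(ref, reps = 200, seed = 1)
#' empirical_p(null, observed = 30 / 271)$empirical_p
#' @export
empirical_p <- function(null, observed, direction = c("greater", "two_sided")) {
  stopifnot(inherits(null, "tikd_null"))
  direction <- match.arg(direction)
  s <- null$statistics[!is.na(null$statistics)]
  m <- length(s)
  if (m == 0) stop("null distribution has no valid replicates", call. = FALSE)
  p_hi <- (sum(s >= observed) + 1) / (m + 1)
  p_lo <- (sum(s <= observed) + 1) / (m + 1)
  p <- switch(direction,
    greater = p_hi,
    two_sided = min(1, 2 * min(p_hi, p_lo))
  )
  null$observed <- observed
  null$direction <- direction
  null$empirical_p <- p
  null
}

#' @exportS3Method generics::glance
#' @rdname tidy.tikd_null
glance.tikd_null <- function(x, ...) {
  s <- x$statistics[!is.na(x$statistics)]
  tibble::tibble(
    statistic = x$statistic,
    reps = x$reps,
    n_draw = x$n_draw,
    n_excluded = x$n_excluded,
    mean = mean(s),
    sd = stats::sd(s),
    observed = if (is.null(x$observed)) NA_real_ else x$observed,
    empirical_p = if (is.null(x$empirical_p)) NA_real_ else x$empirical_p,
    seed = x$seed
  )
}

#' Tidy a resampling null distribution
#'
#' @param x A `"tikd_null"` object.
#' @param ... Unused.
#' @return `tidy()`: one row per replicate; `glance()`: a one-row
#'   summary (mean, SD, observed value, empirical p, seed).
#' @exportS3Method generics::tidy
tidy.tikd_null <- function(x, ...) {
  tibble::tibble(replicate = seq_len(x$reps), statistic = x$statistics)
}

#' @export
print.tikd_null <- function(x, ...) {
  g <- glance.tikd_null(x)
  cat(
    "<tikd_null> ", x$statistic, ": ", x$reps, " draws of ", x$n_draw,
    "; mean ", signif(g$mean, 4), ", sd ", signif(g$sd, 4),
    sep = ""
  )
  if (!is.null(x$observed)) {
    cat(
      "; observed ", signif(x$observed, 4), ", p (", x$direction, ") ",
      signif(x$empirical_p, 4),
      sep = ""
    )
  }
  cat("\n")
  invisible(x)
}

#' Plot a resampling null with the observed statistic
#'
#' @param object A `"tikd_null"` object (run through [empirical_p()] to
#'   draw the observed line).
#' @param bins Histogram bin count.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.tikd_null <- function(object, bins = 40, ...) {
  df <- tidy.tikd_null(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$statistic)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey65", colour = "white") +
    ggplot2::labs(
      x = object$statistic,
      y = "replicates",
      title = sprintf("Resampling null (%d draws of %d)", object$reps, object$n_draw)
    ) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed)) {
    p <- p +
      ggplot2::geom_vline(
        xintercept = object$observed,
        colour = "firebrick", linewidth = 0.8
      ) +
      ggplot2::annotate(
        "text",
        x = object$observed, y = Inf, vjust = 2, hjust = -0.1,
        label = sprintf("observed (p = %.4g)", object$empirical_p),
        colour = "firebrick", size = 3
      )
  }
  p
}
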