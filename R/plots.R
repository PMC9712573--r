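#' Plot per-category enrichment against the pooled baseline
#'
#' Bar chart of the per-category diagnostic rate with the pooled
#' baseline as a dashed line; categories surviving the Bonferroni
#' threshold are highlighted.
#'
#' @param enrichment Output of [category_enrichment()].
#' @return A ggplot object.
#' @export
plot_enrichment <- function(enrichment) {
  baseline <- attr(enrichment, "baseline")
  df <- dplyr::mutate(
    enrichment,
    category = factor(.data$category, levels = rev(.data$category))
  )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$rate, y = .data$category, fill = .data$significant
  )) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_vline(xintercept = baseline, linetype = "dashed", colour = "firebrick") +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = "Bonferroni-significant"
    ) +
    ggplot2::labs(
      x = "diagnostic rate per category",
      y = NULL,
      title = "Category enrichment vs pooled baseline"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the selection funnel
#'
#' Stage counts of the selection funnel: entries, unique individuals,
#' after DNA-quality exclusion, final cohort.
#'
#' @param selection A `"selection_result"` after [apply_qc()].
#' @return A ggplot object.
#' @export
plot_funnel <- function(selection) {
  g <- glance(selection)
  df <- tibble::tibble(
    stage = factor(
      c("entries", "unique individuals", "quality-sufficient", "final cohort"),
      levels = c("entries", "unique individuals", "quality-sufficient", "final cohort")
    ),
    n = c(
      g$n_entries, g$n_unique,
      g$n_unique - g$n_quality_fail, g$n_final
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4, size = 3.2) +
    ggplot2::labs(x = NULL, y = "individuals", title = "Selection funnel") +
    ggplot2::theme_minimal()
}

#' Plot the gene-by-category combination matrix
#'
#' @param matrix_gc Output of [gene_category_matrix()].
#' @return A ggplot object (tile heat map with counts).
#' @export
plot_gene_category <- function(matrix_gc) {
  ggplot2::ggplot(matrix_gc, ggplot2::aes(
    x = .data$category, y = .data$gene, fill = .data$n
  )) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), size = 3) +
    ggplot2::scale_fill_gradient(low = "grey90", high = "firebrick", name = "combinations") +
    ggplot2::labs(x = NULL, y = NULL, title = "Diagnostic combinations by gene and category") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 40, hjust = 1))
}
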