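#' Selection criteria of the registry filtering funnel
#'
#' Individuals enter the screen through one of nine leading-diagnosis
#' categories, each with an age cutoff at registry inclusion: 50 years
#' for most categories, 40 years for "IgA nephropathy", "chronic
#' glomerulonephritis" and "analgesic nephropathy", and no cutoff for
#' "hereditary disorders". Cutoffs are inclusive (`age <= cutoff`). Six
#' annotated conditions (known postrenal or primary glomerular etiology,
#' systemic disease, status post acute kidney injury, polycystic kidneys,
#' single kidney) exclude an individual regardless of category.
#'
#' @param age_cutoff_by_category Named numeric vector over the nine
#'   category labels; `NA` means no cutoff.
#' @param excluded_conditions Character vector of exclusion flags.
#' @return A list with class `"filter_criteria"`.
#' @examples
#' filter_criteria()
#' @export
filter_criteria <- function(age_cutoff_by_category = default_age_cutoffs(),
                            excluded_conditions = gckd_exclusion_flags()) {
  labels <- gckd_categories()
  if (!setequal(names(age_cutoff_by_category), labels)) {
    stop("age cutoffs must be named by exactly the nine category labels",
      call. = FALSE
    )
  }
  structure(
    list(
      age_cutoff_by_category = age_cutoff_by_category[labels],
      excluded_conditions = excluded_conditions
    ),
    class = "filter_criteria"
  )
}

#' @rdname filter_criteria
#' @export
default_age_cutoffs <- function() {
  cutoffs <- stats::setNames(rep(50, 9), gckd_categories())
  cutoffs[c("IgA nephropathy", "chronic glomerulonephritis", "analgesic nephropathy")] <- 40
  cutoffs["hereditary disorders"] <- NA_real_
  cutoffs
}

#' Select (individual, category) entries from a registry
#'
#' Emits one entry per individual-category pair for which the individual
#' carries the category, passes its age cutoff and carries none of the
#' excluded condition flags. Each pair is judged independently: an
#' individual with two categories and discordant cutoffs enters through
#' whichever pair passes. Output is sorted by id then category, so the
#' result is invariant to input row order.
#'
#' @param cohort A registry tibble with at least `id`, `age`,
#'   `categories` (semicolon-separated labels) and `exclusion_flags`
#'   columns (see [read_cohort_csv()] for the schema).
#' @param criteria A [filter_criteria()] list.
#' @return A tibble with columns `id` and `category`.
#' @examples
#' cohort <- tibble::tibble(
#'   id = c("a", "b"), age = c(45, 45),
#'   categories = c("nephrosclerosis", "IgA nephropathy"),
#'   exclusion_flags = ""
#' )
#' select_entries(cohort) # only 'a': the IgA cutoff is 40
#' @export
select_entries <- function(cohort, criteria = filter_criteria()) {
  cohort <- tibble::as_tibble(cohort)
  check_labels(cohort$categories, gckd_categories(), "category", ids = cohort$id)
  if (!"exclusion_flags" %in% names(cohort)) cohort$exclusion_flags <- ""
  check_labels(
    cohort$exclusion_flags, gckd_exclusion_flags(),
    "exclusion flag", ids = cohort$id
  )

  flags <- split_labels(cohort$exclusion_flags)
  excluded <- vapply(
    flags, function(f) length(intersect(f, criteria$excluded_conditions)) > 0,
    logical(1)
  )

  entries <- cohort |>
    dplyr::mutate(.excluded = excluded) |>
    dplyr::select(dplyr::all_of(c("id", "age", "categories")), ".excluded") |>
    tidyr::separate_longer_delim("categories", delim = ";") |>
    dplyr::rename(category = "categories") |>
    dplyr::mutate(category = trimws(.data$category)) |>
    dplyr::filter(nzchar(.data$category))

  cutoff <- criteria$age_cutoff_by_category[entries$category]
  keep <- !entries$.excluded & (is.na(cutoff) | entries$age <= cutoff)

  entries |>
    dplyr::filter(keep) |>
    dplyr::select(dplyr::all_of(c("id", "category"))) |>
    dplyr::arrange(.data$id, .data$category)
}

#' Deduplicate selected entries into a selection result
#'
#' Category-based filtering can select the same individual through
#' several categories; the funnel's next stage works on unique
#' individuals while keeping entry multiplicity for the combination
#' denominators.
#'
#' @param entries A tibble of `(id, category)` pairs from
#'   [select_entries()].
#' @return A list with class `"selection_result"`: `entries`,
#'   `unique_ids`, and (after [apply_qc()]) `qc_excluded` and
#'   `final_ids`.
#' @export
dedupe_entries <- function(entries) {
  entries <- tibble::as_tibble(entries)
  structure(
    list(
      entries = entries,
      unique_ids = sort(unique(entries$id)),
      qc_excluded = tibble::tibble(id = character(), reason = character()),
      final_ids = sort(unique(entries$id))
    ),
    class = "selection_result"
  )
}

#' Apply DNA-quality and identity quality control to a selection
#'
#' Selected individuals are removed when their biobank DNA is of
#' insufficient quality or quantity (`dna_quality_ok`), when genomic
#' fingerprinting does not match (`fingerprint_match`), or when the
#' declared sex disagrees with the sex inferred from sequencing
#' (`sex_declared` vs `sex_inferred`). Reasons are prioritized
#' quality > fingerprint > sex mismatch so every excluded id carries
#' exactly one reason.
#'
#' @param selection A `"selection_result"` from [dedupe_entries()].
#' @param cohort The registry tibble the entries were selected from.
#' @return The selection with `qc_excluded` and `final_ids` populated.
#' @export
apply_qc <- function(selection, cohort) {
  stopifnot(inherits(selection, "selection_result"))
  cohort <- tibble::as_tibble(cohort)
  qc <- cohort |>
    dplyr::filter(.data$id %in% selection$unique_ids) |>
    dplyr::mutate(
      reason = dplyr::case_when(
        !.data$dna_quality_ok ~ "dna_quality",
        !.data$fingerprint_match ~ "fingerprint",
        .data$sex_inferred != "unknown" &
          .data$sex_declared != .data$sex_inferred ~ "sex_mismatch",
        TRUE ~ NA_character_
      )
    ) |>
    dplyr::filter(!is.na(.data$reason)) |>
    dplyr::select(dplyr::all_of(c("id", "reason"))) |>
    dplyr::arrange(.data$id)

  selection$qc_excluded <- qc
  selection$final_ids <- setdiff(selection$unique_ids, qc$id)
  selection
}

#' Count individual-by-category combinations in the final cohort
#'
#' The enrichment analysis splits individuals fulfilling several
#' categories by category, so its denominator is the number of
#' (individual, category) combinations rather than the number of
#' individuals: cohort size plus one extra count per additional label.
#'
#' @param entries A tibble of `(id, category)` pairs, or a
#'   `"selection_result"`; only entries of `final_ids` are counted for
#'   the latter.
#' @return Integer combination count.
#' @examples
#' expand_combinations(tibble::tibble(
#'   id = c("a", "a", "b"),
#'   category = c("gout", "unknown", "gout")
#' ))
#' @export
expand_combinations <- function(entries) {
  if (inherits(entries, "selection_result")) {
    entries <- dplyr::filter(entries$entries, .data$id %in% entries$final_ids)
  }
  nrow(dplyr::distinct(tibble::as_tibble(entries), .data$id, .data$category))
}

#' Funnel counts of a selection result
#'
#' @param x A `"selection_result"`.
#' @param ... Unused.
#' @return One-row tibble: entries, unique individuals, exclusions by
#'   stage, final cohort size, and final combination count.
#' @exportS3Method generics::glance
glance.selection_result <- function(x, ...) {
  tibble::tibble(
    n_entries = nrow(x$entries),
    n_unique = length(x$unique_ids),
    n_quality_fail = sum(x$qc_excluded$reason == "dna_quality"),
    n_identity_fail = sum(x$qc_excluded$reason %in% c("fingerprint", "sex_mismatch")),
    n_final = length(x$final_ids),
    n_combinations = expand_combinations(x)
  )
}

#' @exportS3Method generics::tidy
tidy.selection_result <- function(x, ...) {
  x$entries |>
    dplyr::mutate(
      qc_pass = !.data$id %in% x$qc_excluded$id,
      final = .data$id %in% x$final_ids
    )
}

#' @export
print.selection_result <- function(x, ...) {
  g <- glance.selection_result(x)
  cat(
    "<selection_result> ", g$n_entries, " entries / ", g$n_unique,
    " unique individuals; QC removed ", g$n_quality_fail + g$n_identity_fail,
    "; final cohort ", g$n_final, " (", g$n_combinations, " combinations)\n",
    sep = ""
  )
  invisible(x)
}
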