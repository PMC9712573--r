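#' Read and write registry cohort tables
#'
#' The cohort CSV schema is one row per registry member with columns
#' `id`, `age`, `sex_declared`, `sex_inferred`, `categories`
#' (semicolon-separated labels from [gckd_categories()]),
#' `exclusion_flags` (semicolon-separated, from
#' [gckd_exclusion_flags()]), `creatinine` (mg/dL), `acr` (mg/g),
#' `biopsy`, `hereditary_suspected`, `dna_quality_ok`,
#' `fingerprint_match`. eGFR columns are recomputed from creatinine, age
#' and sex on read. Unknown category labels and non-numeric ages are
#' data errors reported with the offending record.
#'
#' @param path File path.
#' @return A registry tibble.
#' @export
read_cohort_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c(
    "id", "age", "sex_declared", "sex_inferred", "categories",
    "exclusion_flags", "creatinine", "acr", "biopsy",
    "hereditary_suspected", "dna_quality_ok", "fingerprint_match"
  )
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("cohort file lacks required columns: ", paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  if (!is.numeric(raw$age) || any(is.na(raw$age))) {
    bad <- which(!grepl("^\\s*[0-9.]+\\s*$", as.character(raw$age)))
    stop("non-numeric age in cohort row ", paste(utils::head(bad, 3), collapse = ", "),
      call. = FALSE
    )
  }
  raw$categories <- as.character(raw$categories)
  raw$exclusion_flags <- dplyr::coalesce(as.character(raw$exclusion_flags), "")
  check_labels(raw$categories, gckd_categories(), "category", ids = raw$id)
  check_labels(raw$exclusion_flags, gckd_exclusion_flags(), "exclusion flag", ids = raw$id)
  raw |>
    dplyr::mutate(
      egfr_ckdepi = egfr_ckdepi(.data$creatinine, .data$age, .data$sex_declared),
      egfr_mdrd = egfr_mdrd(.data$creatinine, .data$age, .data$sex_declared)
    ) |>
    tibble::as_tibble()
}

#' @rdname read_cohort_csv
#' @param cohort A registry tibble.
#' @export
write_cohort_csv <- function(cohort, path) {
  drop <- intersect(c("egfr_ckdepi", "egfr_mdrd"), names(cohort))
  readr::write_csv(dplyr::select(cohort, -dplyr::all_of(drop)), path, progress = FALSE)
  invisible(path)
}

#' Read a variant table (TSV or VCF)
#'
#' TSV is the primary format: one row per variant with columns `gene`,
#' `hgvs_c`, `hgvs_p`, `variant_type`, `chromosome_class`,
#' `individual_id` and either `acmg_class` (a precomputed 1-5 class,
#' optionally with `posterior`) or an `evidence` token column for
#' [classify_variants()]. HGVS strings are carried verbatim, never
#' parsed. The VCF adapter reads a VCF 4.x file whose INFO field carries
#' `GENE`, `VTYPE`, and either `ACMG` evidence tokens or `CLASS`;
#' mitochondrial records are recognized from the `chrM`/`MT` chromosome.
#'
#' @param path File path.
#' @param dialect `"tsv"` or `"vcf"`.
#' @return A variant tibble.
#' @export
read_variant_table <- function(path, dialect = c("tsv", "vcf")) {
  dialect <- match.arg(dialect)
  if (dialect == "tsv") read_variant_tsv(path) else read_variant_vcf(path)
}

read_variant_tsv <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_variant_table(raw)
}

validate_variant_table <- function(raw) {
  if (!"gene" %in% names(raw) || any(is.na(raw$gene) | raw$gene == "")) {
    stop("variant table rows must carry a gene symbol", call. = FALSE)
  }
  if ("variant_type" %in% names(raw)) {
    bad <- !raw$variant_type %in% variant_types()
    if (any(bad)) {
      stop("unknown variant_type in row ", which(bad)[1], ": ",
        shQuote(raw$variant_type[which(bad)[1]]),
        call. = FALSE
      )
    }
  }
  if ("categories" %in% names(raw)) {
    check_labels(raw$categories, gckd_categories(), "category", ids = raw$individual_id)
  }
  tibble::as_tibble(raw)
}

read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF ingestion needs the 'vcfR' package", call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- tibble::as_tibble(as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE))
  info_get <- function(key) unlist(vcfR::extract.info(v, element = key))
  chrom <- fix$CHROM
  mito <- chrom %in% c("chrM", "MT", "chrMT", "M")
  vtype <- info_get("VTYPE")
  vtype[mito & vtype == "SNV"] <- "mito_SNV"
  out <- tibble::tibble(
    gene = info_get("GENE"),
    hgvs_c = dplyr::coalesce(info_get("HGVSC"), NA_character_),
    hgvs_p = dplyr::coalesce(info_get("HGVSP"), NA_character_),
    variant_type = vtype,
    chromosome_class = dplyr::case_when(
      mito ~ "mitochondrial",
      chrom %in% c("chrX", "chrY", "X", "Y") ~ "gonosome",
      TRUE ~ "autosome"
    ),
    individual_id = dplyr::coalesce(info_get("INDIVIDUAL"), NA_character_),
    evidence = dplyr::coalesce(info_get("ACMG"), NA_character_)
  )
  cls <- suppressWarnings(as.integer(info_get("CLASS")))
  if (!all(is.na(cls))) out$acmg_class <- cls
  validate_variant_table(out)
}

#' Packaged transcription of the screen's diagnostic-variant list
#'
#' The published list of diagnostic (class-4/5) variants of the GCKD
#' tubulointerstitial screen: 36 variants in six genes across 34 unique
#' individuals, with gene, HGVS notation, variant type, ACMG class, the
#' printed Bayesian posterior, the carrier's clinical categories, biopsy
#' status and whether the genetic diagnosis was anticipated clinically.
#' Two individuals carry a dual diagnosis. `hereditary_suspected` is
#' derived as membership in the "hereditary disorders" filtering
#' category. CNV rows carry no printed posterior.
#'
#' @return A variant tibble of 36 rows.
#' @examples
#' dplyr::count(gckd_diagnostic_variants(), gene)
#' @export
gckd_diagnostic_variants <- function() {
  path <- system.file("extdata", "gckd_diagnostic_variants.tsv",
    package = "tikdscreen", mustWork = TRUE
  )
  out <- readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      acmg_class = readr::col_integer(),
      posterior = readr::col_double(),
      biopsy = readr::col_logical(),
      anticipated_clinically = readr::col_logical()
    )
  )
  if (nrow(out) != 36 || length(unique(out$individual_id)) != 34) {
    stop("packaged variant list failed its integrity check", call. = FALSE)
  }
  out$hereditary_suspected <- has_label(out$categories, "hereditary disorders")
  validate_variant_table(out)
}

#' Packaged per-category combination totals of the screened cohort
#'
#' Individual-by-category combination counts of the final cohort of 271
#' (292 combinations in total). Six categories carry counts printed in
#' the source material (`source = "printed"`); the remaining 30
#' combinations are allocated across the three categories without
#' printed counts (`source = "assumed"`).
#'
#' @return Tibble `category`, `n_combinations`, `source`.
#' @export
gckd_category_counts <- function() {
  path <- system.file("extdata", "gckd_category_counts.tsv",
    package = "tikdscreen", mustWork = TRUE
  )
  readr::read_tsv(path,
    show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(n_combinations = readr::col_integer())
  )
}
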