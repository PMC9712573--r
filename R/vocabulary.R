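#' Closed vocabularies of the GCKD tubulointerstitial screen
#'
#' The registry filtering works on nine annotated leading-diagnosis
#' categories; six annotated conditions exclude an individual outright.
#' Both vocabularies are closed and case-sensitive: any other label in an
#' input table is a data error, not a new level.
#'
#' @return A character vector of labels.
#' @examples
#' gckd_categories()
#' @export
gckd_categories <- function() {
  c(
    "nephrosclerosis",
    "gout",
    "IgA nephropathy",
    "chronic glomerulonephritis",
    "analgesic nephropathy",
    "interstitial nephritis",
    "hereditary disorders",
    "others",
    "unknown"
  )
}

#' @rdname gckd_categories
#' @export
gckd_exclusion_flags <- function() {
  c(
    "postrenal",
    "primary_glomerular",
    "systemic_disease",
    "post_AKI",
    "polycystic",
    "single_kidney"
  )
}

# Variant type / chromosome vocabularies shared by the variant tables.
variant_types <- function() c("SNV", "indel", "CNV", "mito_SNV")
chromosome_classes <- function() c("autosome", "gonosome", "mitochondrial")

#' Gene panel of the tubulointerstitial kidney disease screen
#'
#' The screen targets the five classical ADTKD genes (*MUC1*, *UMOD*,
#' *REN*, *HNF1B*, *SEC61A1*), three recently described differential
#' diagnoses (*DNAJB11*, *GATM*, *PARN*), the collagen IV alpha-345 genes
#' (*COL4A3/4/5*, frequent Alport-spectrum phenocopies of
#' tubulointerstitial disease), a configurable set of 17 nephronophthisis
#' genes, and the mitochondrial genome (represented here by mitochondrial
#' tRNA genes such as *MT-TF*).
#'
#' @param nphp_genes Character vector of nephronophthisis gene symbols to
#'   include; the default lists 17 established NPHP genes.
#' @return Character vector of gene symbols.
#' @examples
#' length(panel_genes())
#' @export
panel_genes <- function(nphp_genes = default_nphp_genes()) {
  c(
    "MUC1", "UMOD", "REN", "HNF1B", "SEC61A1",
    "DNAJB11", "GATM", "PARN",
    "COL4A3", "COL4A4", "COL4A5",
    nphp_genes,
    "MT-TF"
  )
}

#' @rdname panel_genes
#' @export
default_nphp_genes <- function() {
  c(
    "NPHP1", "INVS", "NPHP3", "NPHP4", "IQCB1", "CEP290", "GLIS2",
    "RPGRIP1L", "NEK8", "SDCCAG8", "TMEM67", "TTC21B", "WDR19",
    "ZNF423", "CEP164", "ANKS6", "CEP83"
  )
}

# Split a semicolon-separated label field into a list of character vectors.
split_labels <- function(x) {
  out <- strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
  lapply(out, function(v) trimws(v[nzchar(trimws(v))]))
}

# Validate semicolon-separated labels against a closed vocabulary.
# `what` names the field in the error message; `ids` gives row context.
check_labels <- function(x, vocabulary, what, ids = NULL) {
  labs <- split_labels(x)
  bad <- vapply(labs, function(v) any(!v %in% vocabulary), logical(1))
  if (any(bad)) {
    i <- which(bad)[1]
    offending <- setdiff(labs[[i]], vocabulary)
    where <- if (!is.null(ids)) paste0(" (record ", ids[i], ")") else paste0(" (row ", i, ")")
    stop("unknown ", what, " label", where, ": ",
      paste(shQuote(offending), collapse = ", "),
      call. = FALSE
    )
  }
  invisible(x)
}

has_label <- function(x, label) {
  vapply(split_labels(x), function(v) label %in% v, logical(1))
}
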