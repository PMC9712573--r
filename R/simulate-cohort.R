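#' Configuration of the synthetic registry generator
#'
#' The generator emulates the nine-category stratum of a large adult CKD
#' registry from which a tubulointerstitial screen selects its cohort:
#' leading-diagnosis categories with the printed selected-cohort mix,
#' a male:female ratio of 1.40, per-category age distributions honouring
#' the age cutoffs, log-normal serum creatinine (by sex) and urinary
#' albumin-creatinine ratio calibrated so the selected cohort reproduces
#' the printed median eGFR (55.5 mL/min/1.73 m^2 by CKD-EPI) and median
#' ACR (182.1 mg/g), exclusion-condition and QC-failure rates shaping the
#' selection funnel, and a planted spectrum of class-4/5 variants
#' mirroring the published diagnostic-variant list (including the
#' recurrent COL4A5 hotspot and dual-diagnosis carriers).
#'
#' @param n_total Registry members to generate (the nine-category
#'   stratum, not the full registry).
#' @param category_prevalence Named probabilities over the nine category
#'   labels (primary category assignment); must sum to 1.
#' @param dual_category_rate Probability that a member carries a second
#'   category label.
#' @param sex_ratio Male:female ratio.
#' @param age_model Tibble with columns `category`, `min`, `max`,
#'   `median`: ages are drawn from a scaled beta distribution on
#'   `[min, max]` whose median is steered to `median`.
#' @param creatinine_model List with `male` and `female` elements, each
#'   `c(meanlog, sdlog)` of a log-normal serum creatinine (mg/dL).
#' @param acr_model List `meanlog`, `sdlog` of log-normal ACR (mg/g) and
#'   `as_multiplier`, the multiplicative ACR shift applied to carriers of
#'   planted COL4A3/4/5 variants (Alport-spectrum proteinuria).
#' @param exclusion_flag_rates Named probabilities for the six exclusion
#'   conditions.
#' @param qc_fail_rates Named probabilities `dna_quality`, `fingerprint`,
#'   `sex_mismatch`.
#' @param variant_spectrum Tibble `gene`, `variant_type`, `n` of planted
#'   class-4/5 variants.
#' @param hotspot_recurrence How many of the planted COL4A5 SNVs are the
#'   recurrent c.1871G>A, p.(Gly624Asp) founder allele.
#' @param dual_diagnosis_count Number of carriers planted with two
#'   diagnostic variants in different genes.
#' @param biopsy_rate Probability of a kidney biopsy before inclusion.
#' @return A list with class `"cohort_config"`.
#' @examples
#' cfg <- cohort_config(n_total = 100)
#' @export
cohort_config <- function(n_total = 915,
                          category_prevalence = default_category_prevalence(),
                          dual_category_rate = 0.077,
                          sex_ratio = 1.40,
                          age_model = default_age_model(),
                          creatinine_model = list(
                            male = c(meanlog = log(1.535), sdlog = 0.30),
                            female = c(meanlog = log(1.205), sdlog = 0.30)
                          ),
                          acr_model = list(
                            meanlog = log(165), sdlog = 1.3,
                            as_multiplier = 3
                          ),
                          exclusion_flag_rates = stats::setNames(
                            rep(0.035, 6), gckd_exclusion_flags()
                          ),
                          qc_fail_rates = c(
                            dna_quality = 0.053,
                            fingerprint = 0.028,
                            sex_mismatch = 0.028
                          ),
                          variant_spectrum = default_variant_spectrum(),
                          hotspot_recurrence = 9,
                          dual_diagnosis_count = 2,
                          biopsy_rate = 0.461) {
  cfg <- structure(
    list(
      n_total = n_total,
      category_prevalence = category_prevalence,
      dual_category_rate = dual_category_rate,
      sex_ratio = sex_ratio,
      age_model = tibble::as_tibble(age_model),
      creatinine_model = creatinine_model,
      acr_model = acr_model,
      exclusion_flag_rates = exclusion_flag_rates,
      qc_fail_rates = qc_fail_rates,
      variant_spectrum = tibble::as_tibble(variant_spectrum),
      hotspot_recurrence = hotspot_recurrence,
      dual_diagnosis_count = dual_diagnosis_count,
      biopsy_rate = biopsy_rate
    ),
    class = "cohort_config"
  )
  validate_cohort_config(cfg)
}

#' @rdname cohort_config
#' @export
default_category_prevalence <- function() {
  # selected-cohort combination mix; the three non-printed categories are
  # assigned the remainder of the 292 combinations
  counts <- c(
    "nephrosclerosis" = 94, "IgA nephropathy" = 71, "unknown" = 48,
    "interstitial nephritis" = 23, "hereditary disorders" = 17,
    "gout" = 9, "chronic glomerulonephritis" = 15, "others" = 9,
    "analgesic nephropathy" = 6
  )
  counts[gckd_categories()] / sum(counts)
}

#' @rdname cohort_config
#' @export
default_age_model <- function() {
  cats <- gckd_categories()
  tibble::tibble(
    category = cats,
    min = 18,
    max = ifelse(cats == "hereditary disorders", 75, 70),
    median = ifelse(cats == "hereditary disorders", 45, 50)
  )
}

#' @rdname cohort_config
#' @export
default_variant_spectrum <- function() {
  tibble::tribble(
    ~gene, ~variant_type, ~n,
    "COL4A5", "SNV", 15L,
    "COL4A5", "CNV", 1L,
    "COL4A4", "SNV", 6L,
    "COL4A4", "indel", 2L,
    "COL4A3", "SNV", 4L,
    "HNF1B", "SNV", 2L,
    "HNF1B", "CNV", 2L,
    "UMOD", "SNV", 3L,
    "MT-TF", "mito_SNV", 1L
  )
}

validate_cohort_config <- function(cfg) {
  check_prob <- function(x, field) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
      stop("configuration error: '", field, "' must contain probabilities in [0, 1]",
        call. = FALSE
      )
    }
  }
  if (!is.numeric(cfg$n_total) || cfg$n_total < 0) {
    stop("configuration error: 'n_total' must be a non-negative count", call. = FALSE)
  }
  if (!setequal(names(cfg$category_prevalence), gckd_categories())) {
    stop("configuration error: 'category_prevalence' keys must be exactly the nine category labels",
      call. = FALSE
    )
  }
  check_prob(cfg$category_prevalence, "category_prevalence")
  if (abs(sum(cfg$category_prevalence) - 1) > 1e-8) {
    stop("configuration error: 'category_prevalence' must sum to 1", call. = FALSE)
  }
  check_prob(cfg$dual_category_rate, "dual_category_rate")
  check_prob(cfg$exclusion_flag_rates, "exclusion_flag_rates")
  check_prob(cfg$qc_fail_rates, "qc_fail_rates")
  check_prob(cfg$biopsy_rate, "biopsy_rate")
  known <- c(panel_genes(), "MT-TF")
  if (!all(cfg$variant_spectrum$gene %in% known)) {
    stop("configuration error: 'variant_spectrum' genes must come from the configured panel",
      call. = FALSE
    )
  }
  cfg
}

# Scaled beta draw on [min, max] with median steered towards `med`
# (shape b fixed at 2; a chosen by mean matching, adequate at this skew).
draw_ages <- function(n, min, max, med) {
  m <- (med - min) / (max - min)
  a <- 2 * m / (1 - m)
  min + (max - min) * stats::rbeta(n, a, 2)
}

gene_chromosome_class <- function(gene) {
  dplyr::case_when(
    gene == "COL4A5" ~ "gonosome",
    gene == "MT-TF" ~ "mitochondrial",
    TRUE ~ "autosome"
  )
}

#' Generate a synthetic registry with planted diagnostic variants
#'
#' Draws `config$n_total` registry members (categories, ages, sex,
#' kidney-function values, exclusion and QC flags), runs the selection
#' funnel internally, and plants the configured spectrum of class-4/5
#' variants among members of the final cohort, including dual-diagnosis
#' carriers who receive a recurrent COL4A5 variant plus a second variant
#' in another gene. Carriers of COL4A3/4/5 variants get their ACR shifted
#' upward by `acr_model$as_multiplier` (the Alport-spectrum proteinuria
#' signal). Identical `(config, seed)` yields identical output.
#'
#' @param config A [cohort_config()].
#' @param seed Integer seed; fully determines the output.
#' @return A list with class `"tikd_cohort"`: `individuals` (registry
#'   tibble), `variants` (planted variant tibble in the schema of
#'   [gckd_diagnostic_variants()]), `config`, `seed`.
#' @examples
#' sim <- simulate_cohort(cohort_config(n_total = 60), seed = 1)
#' nrow(sim$individuals)
#' @export
simulate_cohort <- function(config = cohort_config(), seed) {
  validate_cohort_config(config)
  set.seed(seed)
  n <- as.integer(config$n_total)
  labels <- gckd_categories()

  if (n == 0) {
    return(structure(
      list(
        individuals = empty_individuals(), variants = empty_variants(),
        config = config, seed = seed
      ),
      class = "tikd_cohort"
    ))
  }

  id <- sprintf("Sim_%05d", seq_len(n))
  sex <- ifelse(
    stats::runif(n) < config$sex_ratio / (1 + config$sex_ratio),
    "male", "female"
  )

  primary <- sample(labels, n, replace = TRUE, prob = config$category_prevalence[labels])
  dual <- stats::runif(n) < config$dual_category_rate
  second <- vapply(
    primary, function(p) sample(setdiff(labels, p), 1),
    character(1), USE.NAMES = FALSE
  )
  categories <- ifelse(dual, paste(primary, second, sep = ";"), primary)

  am <- config$age_model
  age <- numeric(n)
  for (k in seq_len(nrow(am))) {
    idx <- primary == am$category[k]
    if (any(idx)) age[idx] <- draw_ages(sum(idx), am$min[k], am$max[k], am$median[k])
  }

  flags <- vapply(seq_len(n), function(i) {
    hit <- gckd_exclusion_flags()[
      stats::runif(6) < config$exclusion_flag_rates[gckd_exclusion_flags()]
    ]
    paste(hit, collapse = ";")
  }, character(1))

  crea <- numeric(n)
  for (s in c("male", "female")) {
    idx <- sex == s
    p <- config$creatinine_model[[s]]
    crea[idx] <- stats::rlnorm(sum(idx), p[["meanlog"]], p[["sdlog"]])
  }
  acr <- stats::rlnorm(n, config$acr_model$meanlog, config$acr_model$sdlog)

  dna_ok <- stats::runif(n) >= config$qc_fail_rates[["dna_quality"]]
  fp_ok <- stats::runif(n) >= config$qc_fail_rates[["fingerprint"]]
  sex_flip <- stats::runif(n) < config$qc_fail_rates[["sex_mismatch"]]
  sex_inferred <- ifelse(sex_flip, ifelse(sex == "male", "female", "male"), sex)

  individuals <- tibble::tibble(
    id = id,
    age = age,
    sex_declared = sex,
    sex_inferred = sex_inferred,
    categories = categories,
    exclusion_flags = flags,
    creatinine = crea,
    egfr_ckdepi = egfr_ckdepi(crea, age, sex),
    egfr_mdrd = egfr_mdrd(crea, age, sex),
    acr = acr,
    biopsy = stats::runif(n) < config$biopsy_rate,
    hereditary_suspected = has_label(categories, "hereditary disorders"),
    dna_quality_ok = dna_ok,
    fingerprint_match = fp_ok
  )

  variants <- plant_variants(individuals, config)

  # Alport-spectrum carriers: shift ACR upward, keeping everything else
  as_ids <- unique(variants$individual_id[
    variants$gene %in% c("COL4A3", "COL4A4", "COL4A5")
  ])
  individuals$acr[individuals$id %in% as_ids] <-
    individuals$acr[individuals$id %in% as_ids] * config$acr_model$as_multiplier

  structure(
    list(individuals = individuals, variants = variants, config = config, seed = seed),
    class = "tikd_cohort"
  )
}

empty_individuals <- function() {
  tibble::tibble(
    id = character(), age = numeric(), sex_declared = character(),
    sex_inferred = character(), categories = character(),
    exclusion_flags = character(), creatinine = numeric(),
    egfr_ckdepi = numeric(), egfr_mdrd = numeric(), acr = numeric(),
    biopsy = logical(), hereditary_suspected = logical(),
    dna_quality_ok = logical(), fingerprint_match = logical()
  )
}

empty_variants <- function() {
  tibble::tibble(
    gene = character(), hgvs_c = character(), hgvs_p = character(),
    variant_type = character(), chromosome_class = character(),
    acmg_class = integer(), posterior = numeric(),
    individual_id = character(), categories = character(),
    biopsy = logical(), hereditary_suspected = logical()
  )
}

# Plant the configured variant spectrum among final-cohort members.
plant_variants <- function(individuals, config) {
  spec <- config$variant_spectrum
  n_var <- sum(spec$n)
  if (n_var == 0) {
    return(empty_variants())
  }

  selection <- individuals |>
    select_entries() |>
    dedupe_entries() |>
    apply_qc(individuals)
  eligible <- selection$final_ids

  n_dual <- config$dual_diagnosis_count
  n_carriers <- n_var - n_dual
  if (length(eligible) < n_carriers) {
    stop(
      "configuration error: 'variant_spectrum' plants ", n_carriers,
      " carriers but only ", length(eligible), " individuals pass selection",
      call. = FALSE
    )
  }

  rows <- spec[rep(seq_len(nrow(spec)), spec$n), c("gene", "variant_type")]
  rows$chromosome_class <- gene_chromosome_class(rows$gene)
  is_hot <- rows$gene == "COL4A5" & rows$variant_type == "SNV"
  hot_idx <- which(is_hot)[seq_len(min(config$hotspot_recurrence, sum(is_hot)))]
  rows$hgvs_c <- sprintf("c.sim%03d", seq_len(nrow(rows)))
  rows$hgvs_c[hot_idx] <- "c.1871G>A"
  rows$hgvs_p <- NA_character_
  rows$hgvs_p[hot_idx] <- "p.(Gly624Asp)"
  # recurrent founder, structural, and mitochondrial alleles planted as
  # class 5; the remainder as class 4
  rows$acmg_class <- ifelse(
    seq_len(nrow(rows)) %in% hot_idx | rows$variant_type %in% c("CNV", "mito_SNV"),
    5L, 4L
  )
  rows$posterior <- ifelse(rows$variant_type == "CNV", NA_real_,
    ifelse(rows$acmg_class == 5L, 1.00, 0.90)
  )

  carriers <- sample(eligible, n_carriers)

  # dual-diagnosis carriers: one recurrent COL4A5 allele + one variant in
  # a different gene
  order_idx <- seq_len(nrow(rows))
  dual_first <- hot_idx[seq_len(min(n_dual, length(hot_idx)))]
  partner_pool <- which(rows$gene != "COL4A5")
  dual_second <- partner_pool[seq_len(min(n_dual, length(partner_pool)))]
  if (length(dual_first) < n_dual || length(dual_second) < n_dual) {
    stop("configuration error: 'dual_diagnosis_count' exceeds pairable variants",
      call. = FALSE
    )
  }

  assignment <- character(nrow(rows))
  dual_carriers <- carriers[seq_len(n_dual)]
  if (n_dual > 0) {
    assignment[dual_first] <- dual_carriers
    assignment[dual_second] <- dual_carriers
  }
  rest <- setdiff(order_idx, c(dual_first, dual_second))
  assignment[rest] <- carriers[n_dual + seq_along(rest)]

  rows$individual_id <- assignment
  carrier_info <- individuals[match(rows$individual_id, individuals$id), ]
  rows$categories <- carrier_info$categories
  rows$biopsy <- carrier_info$biopsy
  rows$hereditary_suspected <- carrier_info$hereditary_suspected

  tibble::as_tibble(rows[, names(empty_variants())])
}

#' @export
print.tikd_cohort <- function(x, ...) {
  cat(
    "<tikd_cohort> ", nrow(x$individuals), " registry members, ",
    nrow(x$variants), " planted variants (seed ", x$seed, ")\n",
    sep = ""
  )
  invisible(x)
}
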