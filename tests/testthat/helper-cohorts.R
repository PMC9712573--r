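# Minimal registry builder: sensible defaults for every required column,
# overridable per call.
mk_cohort <- function(id, age = 30, sex = "male",
                      categories = "nephrosclerosis",
                      exclusion_flags = "",
                      creatinine = 1.4, acr = 150,
                      biopsy = FALSE,
                      dna_quality_ok = TRUE,
                      fingerprint_match = TRUE,
                      sex_inferred = NULL) {
  n <- length(id)
  sex <- rep_len(sex, n)
  tibble::tibble(
    id = id,
    age = rep_len(age, n),
    sex_declared = sex,
    sex_inferred = if (is.null(sex_inferred)) sex else rep_len(sex_inferred, n),
    categories = rep_len(categories, n),
    exclusion_flags = rep_len(exclusion_flags, n),
    creatinine = rep_len(creatinine, n),
    acr = rep_len(acr, n),
    biopsy = rep_len(biopsy, n),
    hereditary_suspected = has_hereditary(rep_len(categories, n)),
    dna_quality_ok = rep_len(dna_quality_ok, n),
    fingerprint_match = rep_len(fingerprint_match, n)
  )
}

has_hereditary <- function(categories) {
  vapply(
    strsplit(categories, ";", fixed = TRUE),
    function(v) "hereditary disorders" %in% trimws(v),
    logical(1)
  )
}

# Selection funnel shortcut used throughout the tests.
run_funnel <- function(cohort, criteria = filter_criteria()) {
  apply_qc(dedupe_entries(select_entries(cohort, criteria)), cohort)
}

# Final-cohort individuals of a simulated registry.
final_individuals <- function(sim) {
  sel <- run_funnel(sim$individuals)
  sim$individuals[sim$individuals$id %in% sel$final_ids, ]
}
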