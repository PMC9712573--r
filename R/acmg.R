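#' ACMG/AMP evidence profile
#'
#' An evidence profile holds the number of met criteria at each ACMG/AMP
#' strength level: pathogenic very strong (PVS), strong (PS), moderate
#' (PM) and supporting (PP), plus benign stand-alone (BA), strong (BS)
#' and supporting (BP). The counts are what the categorical combining
#' rules and the Bayesian posterior both consume; which criteria were met
#' and why is upstream curation, not modelled here.
#'
#' @param pvs,ps,pm,pp,ba,bs,bp Non-negative integer criterion counts;
#'   `ba` can only be 0 or 1 (BA1 is a stand-alone criterion).
#' @return A one-row tibble with the seven count columns.
#' @examples
#' evidence_profile(ps = 1, pm = 2)
#' @export
evidence_profile <- function(pvs = 0, ps = 0, pm = 0, pp = 0,
                             ba = 0, bs = 0, bp = 0) {
  prof <- tibble::tibble(
    pvs = as.integer(pvs), ps = as.integer(ps), pm = as.integer(pm),
    pp = as.integer(pp), ba = as.integer(ba), bs = as.integer(bs),
    bp = as.integer(bp)
  )
  validate_profile(prof)
  prof
}

validate_profile <- function(prof) {
  counts <- as.matrix(prof[, c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")])
  if (any(is.na(counts)) || any(counts < 0)) {
    stop("evidence counts must be non-negative integers", call. = FALSE)
  }
  if (any(prof$ba > 1)) {
    stop("ba is a stand-alone criterion and must be 0 or 1", call. = FALSE)
  }
  invisible(prof)
}

#' Parse ACMG criterion tokens into evidence counts
#'
#' Turns strings such as `"PS1;PM2;PP3"` into per-strength counts by the
#' token prefix (`PVS`, `PS`, `PM`, `PP`, `BA`, `BS`, `BP`). The numeric
#' suffix identifies which criterion was met and does not affect the
#' count; duplicated tokens are counted once.
#'
#' @param tokens Character vector; each element a `;`-separated token list.
#' @return A tibble with one row per input element and the seven count
#'   columns of [evidence_profile()].
#' @examples
#' parse_evidence(c("PVS1;PM2", "PS1;PM1;PM2;PP3"))
#' @export
parse_evidence <- function(tokens) {
  levels <- c("PVS", "PS", "PM", "PP", "BA", "BS", "BP")
  rows <- lapply(split_labels(tokens), function(tk) {
    tk <- unique(tk)
    pre <- sub("^(PVS|PS|PM|PP|BA|BS|BP).*$", "\\1", tk)
    bad <- !pre %in% levels | !grepl("^(PVS|PS|PM|PP|BA|BS|BP)", tk)
    if (any(bad)) {
      stop("unrecognized ACMG evidence token: ",
        paste(shQuote(tk[bad]), collapse = ", "),
        call. = FALSE
      )
    }
    counts <- table(factor(pre, levels = levels))
    tibble::as_tibble(stats::setNames(as.list(as.integer(counts)), tolower(levels)))
  })
  out <- dplyr::bind_rows(rows)
  validate_profile(out)
  out
}

#' Constants of the Bayesian pathogenicity framework
#'
#' The odds-of-pathogenicity framework assigns the very-strong level an
#' odds of `odds_pvst` and each weaker level the 2^-k-th root of it
#' (strong 1/2, moderate 1/4, supporting 1/8 in the exponent); benign
#' criteria contribute the negated exponents. Defaults `prior = 0.10`,
#' `odds_pvst = 350` reproduce the per-variant posterior values printed
#' in the screen's diagnostic-variant list (0.90 for the modal
#' likely-pathogenic combination, values rounding to 1.00 for pathogenic
#' ones).
#'
#' @param prior Prior probability of pathogenicity, in (0, 1).
#' @param odds_pvst Odds of pathogenicity assigned to one very-strong
#'   criterion; must exceed 1.
#' @return A list with class `"bayes_params"`.
#' @export
bayes_params <- function(prior = 0.10, odds_pvst = 350) {
  if (!is.numeric(prior) || prior <= 0 || prior >= 1) {
    stop("prior must lie strictly between 0 and 1", call. = FALSE)
  }
  if (!is.numeric(odds_pvst) || odds_pvst <= 1) {
    stop("odds_pvst must exceed 1", call. = FALSE)
  }
  structure(list(prior = prior, odds_pvst = odds_pvst), class = "bayes_params")
}

#' Combined odds of pathogenicity for an evidence profile
#'
#' Multiplies the per-criterion odds:
#' `odds = odds_pvst ^ (pvs + ps/2 + pm/4 + pp/8 - bs/2 - bp/8)`.
#' The empty profile has odds 1, and odds are multiplicative over
#' concatenated profiles. BA1 is a categorical short-circuit and carries
#' no odds exponent.
#'
#' @param profile A data frame with the seven count columns of
#'   [evidence_profile()] (one or more rows).
#' @param params A [bayes_params()] list.
#' @return Numeric vector of combined odds, one per profile row.
#' @examples
#' combined_odds(evidence_profile(pm = 2, pp = 2))
#' @export
combined_odds <- function(profile, params = bayes_params()) {
  validate_profile(profile)
  expo <- profile$pvs + profile$ps / 2 + profile$pm / 4 + profile$pp / 8 -
    profile$bs / 2 - profile$bp / 8
  params$odds_pvst^expo
}

#' Posterior probability of pathogenicity
#'
#' Bayes' rule on the odds scale:
#' `posterior = odds * prior / ((odds - 1) * prior + 1)`.
#' Equals the prior at odds 1 and is strictly increasing in the odds.
#'
#' @param odds Positive combined odds of pathogenicity.
#' @param prior Prior probability of pathogenicity.
#' @return Posterior probabilities in (0, 1).
#' @examples
#' posterior_pathogenicity(350, prior = 0.10)
#' @export
posterior_pathogenicity <- function(odds, prior = 0.10) {
  if (any(odds <= 0)) stop("odds must be positive", call. = FALSE)
  odds * prior / ((odds - 1) * prior + 1)
}

#' Categorical five-tier ACMG class
#'
#' Applies the published ACMG/AMP 2015 combining rules to an evidence
#' profile and returns the five-tier class (1 benign, 2 likely benign,
#' 3 uncertain significance, 4 likely pathogenic, 5 pathogenic).
#' Combinations are read as monotone: a profile satisfies a rule if its
#' counts meet or exceed one of the listed combinations. BA1 is
#' stand-alone benign and short-circuits to class 1. Profiles carrying
#' both pathogenic- and benign-direction evidence (other than BA1) are
#' conflicting and classed 3.
#'
#' @inheritParams combined_odds
#' @return Integer vector of classes in 1..5, one per profile row.
#' @examples
#' acmg_class(evidence_profile(pvs = 1, ps = 1)) # pathogenic
#' acmg_class(evidence_profile(ps = 1, pm = 2)) # likely pathogenic
#' @export
acmg_class <- function(profile) {
  validate_profile(profile)
  with(profile, {
    pathogenic <-
      (pvs >= 1 & ps >= 1) | (pvs >= 1 & pm >= 2) |
      (pvs >= 1 & pm >= 1 & pp >= 1) | (pvs >= 1 & pp >= 2) |
      (pvs >= 2) |
      (ps >= 2) |
      (ps >= 1 & pm >= 3) | (ps >= 1 & pm >= 2 & pp >= 2) |
      (ps >= 1 & pm >= 1 & pp >= 4)
    likely_path <-
      (pvs >= 1 & pm >= 1) | (ps >= 1 & pm >= 1) | (ps >= 1 & pp >= 2) |
      (pm >= 3) | (pm >= 2 & pp >= 2) | (pm >= 1 & pp >= 4)
    benign <- bs >= 2
    likely_ben <- (bs >= 1 & bp >= 1) | (bp >= 2)

    path_evidence <- (pvs + ps + pm + pp) > 0
    ben_evidence <- (bs + bp) > 0

    cls <- rep(3L, length(pvs))
    only_path <- path_evidence & !ben_evidence
    only_ben <- ben_evidence & !path_evidence
    cls[only_path & likely_path] <- 4L
    cls[only_path & pathogenic] <- 5L
    cls[only_ben & likely_ben] <- 2L
    cls[only_ben & benign] <- 1L
    cls[ba >= 1] <- 1L
    cls
  })
}

bayes_tier <- function(posterior) {
  dplyr::case_when(
    posterior >= 0.99 ~ "pathogenic",
    posterior >= 0.90 ~ "likely_pathogenic",
    posterior <= 0.001 ~ "benign",
    posterior <= 0.10 ~ "likely_benign",
    TRUE ~ "VUS"
  )
}

#' Classify variants categorically and by posterior probability
#'
#' Runs both arms of the classification on a variant table: the
#' categorical five-tier class from the combining rules and the Bayesian
#' posterior from the combined odds. A variant is flagged `discordant`
#' when the posterior reaches the pathogenic band (>= 0.99) while the
#' combining rules stop at likely pathogenic (class 4) — the rules require
#' a strong criterion for class 5, so heaped moderate/supporting evidence
#' can out-run them.
#'
#' @param data A data frame of variants carrying either the seven count
#'   columns of [evidence_profile()] or an `evidence` column of criterion
#'   tokens (see [parse_evidence()]).
#' @param params A [bayes_params()] list.
#' @param evidence_col Name of the token column used when the count
#'   columns are absent.
#' @return The input tibble with columns `odds`, `posterior`,
#'   `categorical_class`, `bayes_tier` and `discordant` appended.
#' @examples
#' classify_variants(tibble::tibble(evidence = c("PS1;PM1;PM2", "PM1;PP1")))
#' @export
classify_variants <- function(data, params = bayes_params(),
                              evidence_col = "evidence") {
  data <- tibble::as_tibble(data)
  count_cols <- c("pvs", "ps", "pm", "pp", "ba", "bs", "bp")
  if (all(count_cols %in% names(data))) {
    prof <- data[count_cols]
    prof[] <- lapply(prof, as.integer)
  } else if (evidence_col %in% names(data)) {
    prof <- parse_evidence(data[[evidence_col]])
  } else {
    stop(
      "variant table needs either the evidence count columns (",
      paste(count_cols, collapse = ", "), ") or a '", evidence_col,
      "' token column",
      call. = FALSE
    )
  }
  validate_profile(prof)
  odds <- combined_odds(prof, params)
  post <- posterior_pathogenicity(odds, params$prior)
  cls <- acmg_class(prof)
  dplyr::mutate(
    data,
    odds = odds,
    posterior = post,
    categorical_class = cls,
    bayes_tier = bayes_tier(post),
    discordant = bayes_tier == "pathogenic" & categorical_class == 4L
  )
}

#' Format a posterior probability the way the variant list prints it
#'
#' The published list reports posteriors at two decimals; for some
#' combinations the last digit is truncated rather than rounded (0.9749
#' printed as 0.97). Both conventions are supported; truncation is the
#' default display convention, full precision is always kept internally.
#'
#' @param posterior Numeric posterior probabilities.
#' @param digits Decimals to keep.
#' @param convention `"truncate"` or `"round"`.
#' @return Numeric vector formatted per the convention.
#' @export
format_posterior <- function(posterior, digits = 2,
                             convention = c("truncate", "round")) {
  convention <- match.arg(convention)
  if (convention == "truncate") {
    trunc(posterior * 10^digits) / 10^digits
  } else {
    round(posterior, digits)
  }
}
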