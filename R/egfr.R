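#' Estimated glomerular filtration rate from serum creatinine
#'
#' `egfr_ckdepi()` implements the 2009 CKD-EPI creatinine equation and
#' `egfr_mdrd()` the original 4-variable MDRD study equation, both without
#' the race coefficient: the cohort these tools model was recruited as
#' exclusively Caucasian, so the term is constant and omitted.
#'
#' CKD-EPI: `eGFR = a * min(Scr/k, 1)^b1 * max(Scr/k, 1)^-1.209 * 0.993^age`
#' with `(a, k, b1)` = (144, 0.7, -0.329) for females and
#' (141, 0.9, -0.411) for males.
#'
#' MDRD: `eGFR = 186 * Scr^-1.154 * age^-0.203 * (0.742 if female)`.
#'
#' @param creatinine Serum creatinine in mg/dL; must be positive.
#' @param age Age in years (adult cohort, >= 18).
#' @param sex `"male"` or `"female"`.
#' @return eGFR in mL/min/1.73 m^2, vectorized over the inputs.
#' @examples
#' egfr_ckdepi(1.2, 50, "female")
#' egfr_mdrd(1.5, 40, "male")
#' @export
egfr_ckdepi <- function(creatinine, age, sex) {
  check_egfr_inputs(creatinine, age, sex)
  female <- sex == "female"
  a <- ifelse(female, 144, 141)
  k <- ifelse(female, 0.7, 0.9)
  b1 <- ifelse(female, -0.329, -0.411)
  r <- creatinine / k
  a * pmin(r, 1)^b1 * pmax(r, 1)^-1.209 * 0.993^age
}

#' @rdname egfr_ckdepi
#' @export
egfr_mdrd <- function(creatinine, age, sex) {
  check_egfr_inputs(creatinine, age, sex)
  186 * creatinine^-1.154 * age^-0.203 * ifelse(sex == "female", 0.742, 1)
}

check_egfr_inputs <- function(creatinine, age, sex) {
  if (any(!is.finite(creatinine)) || any(creatinine <= 0)) {
    stop("serum creatinine must be positive", call. = FALSE)
  }
  if (any(age < 18)) {
    stop("eGFR equations are applied to the adult cohort (age >= 18)", call. = FALSE)
  }
  if (any(!sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'", call. = FALSE)
  }
  invisible(NULL)
}
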