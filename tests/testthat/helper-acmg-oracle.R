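# Independent oracle: the written ACMG/AMP rule table as explicit minimal
# combinations (a profile meets a tier if its counts dominate one of the
# listed combinations componentwise), with BA1 stand-alone and mixed
# pathogenic/benign evidence resolving to class 3.
oracle_class <- function(pvs, ps, pm, pp, ba, bs, bp) {
  dominates <- function(combo) {
    pvs >= combo[1] && ps >= combo[2] && pm >= combo[3] && pp >= combo[4]
  }
  path_combos <- list(
    c(1, 1, 0, 0), c(1, 0, 2, 0), c(1, 0, 1, 1), c(1, 0, 0, 2), c(2, 0, 0, 0),
    c(0, 2, 0, 0), c(0, 1, 3, 0), c(0, 1, 2, 2), c(0, 1, 1, 4)
  )
  lp_combos <- list(
    c(1, 0, 1, 0), c(0, 1, 1, 0), c(0, 1, 0, 2),
    c(0, 0, 3, 0), c(0, 0, 2, 2), c(0, 0, 1, 4)
  )
  if (ba >= 1) {
    return(1L)
  }
  path_ev <- (pvs + ps + pm + pp) > 0
  ben_ev <- (bs + bp) > 0
  if (path_ev && ben_ev) {
    return(3L)
  }
  if (path_ev) {
    if (any(vapply(path_combos, dominates, logical(1)))) {
      return(5L)
    }
    if (any(vapply(lp_combos, dominates, logical(1)))) {
      return(4L)
    }
    return(3L)
  }
  if (ben_ev) {
    if (bs >= 2) {
      return(1L)
    }
    if ((bs >= 1 && bp >= 1) || bp >= 2) {
      return(2L)
    }
    return(3L)
  }
  3L
}

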