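test_that("categorical classifier matches rule-table enumeration for all counts <= 4", {
  grid <- expand.grid(
    pvs = 0:4, ps = 0:4, pm = 0:4, pp = 0:4, ba = 0:1, bs = 0:4, bp = 0:4
  )
  got <- acmg_class(grid)
  want <- mapply(
    oracle_class, grid$pvs, grid$ps, grid$pm, grid$pp, grid$ba, grid$bs, grid$bp
  )
  expect_identical(got, as.integer(want))
})

test_that("combined odds follow the exponent scheme and multiply over profiles", {
  expect_equal(combined_odds(evidence_profile()), 1)
  expect_equal(combined_odds(evidence_profile(pvs = 1)), 350)
  expect_equal(combined_odds(evidence_profile(pm = 2, pp = 2)), 350^0.75)
  expect_equal(combined_odds(evidence_profile(pm = 2, pp = 2)), 80.92, tolerance = 1e-3)
  # multiplicativity over concatenated evidence
  a <- evidence_profile(ps = 1, pp = 1)
  b <- evidence_profile(pm = 2, bp = 1)
  ab <- evidence_profile(ps = 1, pp = 1, pm = 2, bp = 1)
  expect_equal(combined_odds(ab), combined_odds(a) * combined_odds(b))
})

test_that("posterior transform is Bayes' rule on the odds scale", {
  expect_equal(posterior_pathogenicity(1, prior = 0.10), 0.10)
  post <- function(o, pr = 0.1) o * pr / ((o - 1) * pr + 1)
  # modal likely-pathogenic combination prints as 0.90
  o <- combined_odds(evidence_profile(pm = 2, pp = 2))
  expect_equal(round(posterior_pathogenicity(o), 2), 0.90)
  # 1 PS + 2 PM: 0.975 exact, printed 0.97 under truncation
  o2 <- combined_odds(evidence_profile(ps = 1, pm = 2))
  expect_equal(posterior_pathogenicity(o2), post(350), tolerance = 1e-12)
  expect_equal(format_posterior(posterior_pathogenicity(o2)), 0.97)
  expect_equal(format_posterior(0.975, convention = "round"), 0.98)
  # 1 PVS + 2 PM crosses the pathogenic band
  o3 <- combined_odds(evidence_profile(pvs = 1, pm = 2))
  expect_gte(posterior_pathogenicity(o3), 0.99)
  # strictly increasing in odds
  oo <- c(0.1, 0.5, 1, 5, 50, 5000)
  expect_true(all(diff(posterior_pathogenicity(oo)) > 0))
})

test_that("posterior is monotone in evidence", {
  set.seed(42)
  params <- bayes_params()
  for (i in 1:200) {
    prof <- evidence_profile(
      pvs = sample(0:2, 1), ps = sample(0:3, 1), pm = sample(0:4, 1),
      pp = sample(0:4, 1), bs = sample(0:2, 1), bp = sample(0:3, 1)
    )
    base <- posterior_pathogenicity(combined_odds(prof, params), params$prior)
    for (crit in c("pvs", "ps", "pm", "pp")) {
      up <- prof
      up[[crit]] <- up[[crit]] + 1L
      expect_gte(posterior_pathogenicity(combined_odds(up, params), params$prior), base)
    }
    for (crit in c("bs", "bp")) {
      up <- prof
      up[[crit]] <- up[[crit]] + 1L
      expect_lte(posterior_pathogenicity(combined_odds(up, params), params$prior), base)
    }
  }
})

test_that("classification flags the posterior/categorical discordance", {
  res <- classify_variants(tibble::tibble(evidence = c(
    "PM1;PM2;PM4;PP1;PP2;PP3;PP4", # 3 PM + 4 PP: heaped moderate evidence
    "PS1;PM1;PM2",
    ""
  )))
  expect_equal(res$categorical_class, c(4L, 4L, 3L))
  expect_gte(res$posterior[1], 0.99)
  expect_true(res$discordant[1])
  expect_false(res$discordant[2])
  expect_equal(res$posterior[3], 0.10)
  expect_equal(res$bayes_tier[1], "pathogenic")
})

test_that("evidence parsing counts tokens by strength prefix", {
  prof <- parse_evidence("PVS1;PM2;PM5;PP3;BP4")
  expect_equal(prof$pvs, 1L)
  expect_equal(prof$pm, 2L)
  expect_equal(prof$pp, 1L)
  expect_equal(prof$bp, 1L)
  expect_error(parse_evidence("PX9"), "unrecognized")
})

test_that("profile validation rejects impossible inputs", {
  expect_error(evidence_profile(pm = -1), "non-negative")
  expect_error(evidence_profile(ba = 2), "stand-alone")
  expect_error(bayes_params(prior = 0), "prior")
  expect_error(bayes_params(odds_pvst = 1), "odds_pvst")
})
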