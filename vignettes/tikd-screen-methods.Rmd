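---
title: "Methods: screening CKD registries for hereditary tubulointerstitial disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening CKD registries for hereditary tubulointerstitial disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tikdscreen)
```

Hereditary tubulointerstitial kidney diseases (ADTKD, MITKD,
nephronophthisis, and their frequent Alport-spectrum phenocopies in
*COL4A3/4/5*) lack pathognomonic clinical or histological signs, so
their prevalence in adult CKD registries is uncertain. `tikdscreen`
implements the analysis of a targeted-panel screen of such a registry:
who gets selected, how variants are classified, and how the panel's
diagnostic yield is compared against an exome-scale reference. This
vignette documents the statistical model behind each stage, the
tunable parameters, and what the synthetic generators do and do not
emulate.

## Selection funnel

Registry members carry one or two of nine leading-diagnosis category
labels. A member enters the screen through a category if their age at
inclusion passes that category's cutoff and none of six exclusion
conditions (postrenal etiology, primary glomerular disease, systemic
disease, status post acute kidney injury, polycystic kidneys, single
kidney) applies. Choices worth noting:

- **Cutoffs are inclusive** (`age <= cutoff`): 50 years for most
  categories, 40 for "IgA nephropathy", "chronic glomerulonephritis"
  and "analgesic nephropathy", none for "hereditary disorders".
- **Pairs are judged independently.** A member with two labels and
  discordant cutoffs enters if at least one pair passes; the passing
  pairs are the *entries*, and the combination denominator of the
  enrichment analysis counts them per individual.
- **QC reasons are prioritized** DNA quality > fingerprint mismatch >
  declared/inferred sex mismatch, so every excluded individual carries
  exactly one reason even when several gates would fire. The funnel
  report keeps the DNA-quality and identity stages separate.
- Selection is idempotent and invariant to input row order (output is
  sorted by id, then category). The category vocabulary is closed and
  case-sensitive; unknown labels are data errors naming the record, not
  silently dropped rows.

## Variant classification

Evidence assignment (population frequency, segregation, in-silico
scores) is upstream curation; the package consumes per-variant
criterion counts and classifies them along two routes.

**Categorical route.** The five-tier combining rules are applied with
three conventions. First, combinations are read as *monotone*: a
profile satisfies a rule if its counts meet or exceed one of the listed
minimal combinations (so e.g. two very-strong criteria classify as
pathogenic even though the written table only lists "1 very strong
and ..."). Second, BA1 is stand-alone benign and short-circuits to
class 1 before anything else. Third, profiles carrying both
pathogenic- and benign-direction evidence are *conflicting* and return
class 3 categorically — while the Bayesian posterior still combines
both signs multiplicatively.

**Bayesian route.** Combined odds of pathogenicity are
`odds_pvst ^ (PVS + PS/2 + PM/4 + PP/8 - BS/2 - BP/8)` and the
posterior follows Bayes' rule on the odds scale. The defaults
`prior = 0.10`, `odds_pvst = 350` reproduce the per-variant posteriors
printed in the screen's variant list: 0.90 for the modal
likely-pathogenic combination (2 PM + 2 PP), 0.97 for 1 PS + 2 PM
(0.9749 exact — the printed value corresponds to truncation at two
decimals, so both `"truncate"` and `"round"` display conventions are
supported, truncation being the default; full precision is always kept
internally). Posterior tiers are ≥ 0.99 pathogenic, ≥ 0.90 likely
pathogenic, ≤ 0.001 benign, ≤ 0.10 likely benign, else VUS.

The two routes disagree systematically in one direction: class 5
requires a strong criterion, so profiles like 3 PM + 4 PP reach a
pathogenic posterior (0.994) while the rules stop at class 4. Such
variants are flagged `discordant` rather than silently reconciled.

```{r}
classify_variants(tibble::tibble(evidence = "PM1;PM2;PM4;PP1;PP2;PP3;PP4"))[
  , c("posterior", "categorical_class", "discordant")
]
```

## Yield, enrichment and group comparisons

Diagnostic yield counts unique individuals with at least one class-4/5
variant; class-3 VUS are excluded, dual diagnoses count once. The
*exome-comparable* mode restricts to SNVs and indels on nuclear
chromosomes, because the reference exome study analyzed neither CNVs
nor the mitochondrial genome.

Per-category enrichment is a two-sided exact binomial test
(minimum-likelihood convention, as in `binom.test`) of each category's
diagnosed combinations against the pooled rate; for the rates arising
here the two-sided value coincides with the upper-tail sum, which the
test suite verifies against direct summation of the binomial mass.
The Bonferroni threshold defaults to `0.05 / 9 ≈ 0.0056`; the numerator
is exposed as configuration.

Group comparisons of kidney-function values (e.g. ACR in diagnosed vs
non-diagnosed individuals) use the **two-sided rank-sum test for
independent samples**. The groups compared are independent and of
unequal size (34 vs 237), so the signed-rank test — which requires
paired observations — is not applicable to this design; this package
deliberately uses the independent-samples test. Degenerate all-tied
input returns p = 1.

Two pieces of published arithmetic are first-class operations:
`fold_enrichment(k1, n1, k2, n2) = (k1/n1)/(k2/n2)` (ADTKD
small-variant carriage, panel vs reference: (5/271)/(12/3315) ≈ 5.1)
and `interpolate_prevalence(k, n) = 100·k/n` (7/5217 ≈ 0.13% under the
assumption of complete enrichment by the selection criteria). A
zero-rate denominator makes the fold undefined and is reported as `NA`
with a warning, never as infinity.

## Resampling null

The panel-vs-exome comparison draws `n_draw = 271` members **without
replacement** from the reference cohort, `reps = 10000` times, and
scores each draw with the detectability predicate (diagnostic, panel
gene, detectable variant type, covered chromosome class). Without
replacement, each draw's detectable count is hypergeometric; the test
suite checks the null's mean and variance against the closed-form
hypergeometric moments within three Monte-Carlo standard errors — the
module's primary oracle.

The empirical p uses the add-one convention `(b + 1)/(m + 1)`, so it is
never exactly zero and the smallest reportable value at 10,000
replicates is just below 1e-4; human-readable output should render that
as "< 1/reps". Two-sided p doubles the smaller tail, capped at 1. For
the COL4A-fraction null, replicates with zero detectable draws have an
undefined ratio; they are recorded as missing, counted, and excluded
from the p computation.

**Reference population.** Draws are taken from the full reference
cohort (diagnostic and non-diagnostic members alike), which is the only
construction that puts the null on the yield scale; sub-sampling only
diagnostic members would simulate a different quantity.

## Synthetic generators

`simulate_reference_cohort()` allocates the printed reference counts
**deterministically** (3315 members; 9.3% diagnostic; 108 COL4A; 12
ADTKD small variants; remainder in non-panel genes) and only shuffles
member order under the seed, so configured counts are matched exactly
rather than in expectation. The non-COL4A, non-ADTKD composition of the
real reference study's detectable variants is *not* public at gene
level; the default places the remainder outside the panel. As a
consequence the COL4A-share null is composition-sensitive: under the
default composition the two-sided empirical p for the observed share
26/30 ≈ 86.7% computes to ≈ 0.64, and re-creating any particular
published value requires configuring `gene_distribution` to the actual
composition. The package reports what it computes.

`simulate_cohort()` generates the nine-category stratum of a registry:

| parameter | default | rationale |
|---|---|---|
| `n_total` | 915 | yields a final cohort of ≈ 271 under the default rates |
| `category_prevalence` | printed selected-cohort mix | 94/71/48/23/17/9 printed; 15/9/6 assumed for the three unprinted categories (sum 292) |
| `dual_category_rate` | 0.077 | printed share of individuals in two filtering groups |
| `sex_ratio` | 1.40 | printed male:female ratio |
| age model | scaled beta on [18, 70] ([18, 75] hereditary), median 50 (45) | only median/range printed; beta gives bounded, mildly skewed ages |
| creatinine (mg/dL) | log-normal, meanlog log(1.535)/log(1.205) m/f, sdlog 0.30 | calibrated so selected-cohort median CKD-EPI eGFR ≈ 55.5 mL/min/1.73 m² |
| ACR (mg/g) | log-normal, meanlog log(165), sdlog 1.3 | right-skewed (printed mean ≪ SD); calibrated to median ≈ 182.1, SD of order 900 |
| `as_multiplier` | 3 | multiplicative ACR shift for COL4A carriers, making the Alport proteinuria signal detectable at n ≈ 26 vs 245 with ≥ 95% power |
| QC fail rates | 0.053 / 0.028 / 0.028 | reproduce the printed funnel attrition in expectation |
| variant spectrum | 16 COL4A5 (9 hotspot) / 8 COL4A4 / 4 COL4A3 / 4 HNF1B / 3 UMOD / 1 MT-TF; 2 dual diagnoses | mirrors the published variant list |

Ages, kidney-function values and flags are drawn per member; the
generator then runs the selection funnel internally and plants the
variant spectrum among final-cohort members, pairing each
dual-diagnosis carrier with one recurrent COL4A5 allele plus a variant
in another gene. Identical `(config, seed)` is bit-identical output.

The log-normal choice for creatinine and ACR is a modelling
convenience: the source material prints only medians and SDs, and a
right-skewed two-parameter family reproduces both. Calibration was done
once against those printed medians (pooled over ≥ 1000 selected
individuals) and frozen. What the generator does **not** emulate: the
full registry beyond the nine-category stratum (so registry-wide
selection percentages are out of scope), per-category age/sex
interactions, correlation between eGFR and ACR, sequencing coverage or
genotype quality, and any real linkage between clinical category and
carrier status — variants are planted uniformly among eligible members.
Passing tests therefore demonstrate the statistics' correctness and
calibration under this structure, not distributional fidelity to any
real registry.

## Numerical conventions and degenerate inputs

- Percentages are reported at one decimal (two for prevalence),
  matching the source formatting; posteriors display at two decimals
  under the truncation convention.
- `n_total = 0` yields empty tibbles; empty variant sets yield 0/0.0
  rather than errors; `k = n` and `p0 → 1` degenerate binomial cases
  return 1.
- Probabilities in configurations are validated to [0, 1] with errors
  naming the offending field; draw sizes exceeding the population and
  spectra exceeding the eligible cohort are errors, not silent clamps.
- eGFR equations reject non-positive creatinine and ages below 18
  (adult registry); the race coefficient is omitted throughout because
  the modelled registry was recruited as exclusively Caucasian, making
  the term constant. The MDRD implementation uses the original
  coefficient 186 (the registry's inclusion-era equation).

## Problem sizes

The test suite exercises the generators at registry sizes 40–915 with
up to 20 replicates, rule-table enumeration over all 31,250 evidence
profiles with counts ≤ 4, and resampling nulls at 300–10,000
replicates; the acceptance script runs the full 10,000 × 271 null.
These sizes were chosen to hold Monte-Carlo error well inside the
tolerances stated above while keeping a full run in the tens of
seconds.

## Known limitations

- Evidence criteria are inputs; the package does not derive them from
  annotations, and the two third-party automated classifiers used in
  the source study's sensitivity analysis are out of scope, as are all
  wet-lab assays (SNaPshot MUC1-dupC genotyping, MLPA/Sanger
  confirmation, CNV-calling internals).
- The packaged category totals for three of the nine categories are
  assumed (marked `source = "assumed"`), so enrichment p-values for
  those categories are indicative only.
- The COL4A-fraction null depends on the reference cohort's gene
  composition, as discussed above.
- HGVS strings are carried verbatim and never parsed semantically.
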