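---
title: "Comparing cumulative-deficit frailty indices across data modalities"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing cumulative-deficit frailty indices across data modalities}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ficompare)
library(dplyr)
```

## The measurement problem

A cumulative-deficit frailty index (FI) is the proportion of measured
deficits present in a person. Its appeal is portability: an FI built from 36
coded primary-care deficits and one built from 58 self-reported survey items
should, if the cumulative-deficit theory holds, describe the same population
similarly — even though the individual items differ in kind, granularity and
capture mechanism. `ficompare` provides the machinery to put that claim
under test: a ground-truth synthetic cohort generator for both modalities,
the ascertainment rules of each index, harmonisation of the two deficit
lists, and the population-level comparison battery.

Because the real data this design targets (licensed primary-care extracts
and restricted survey microdata) cannot be redistributed, the package treats
the synthetic generator as a first-class, tested component: every downstream
stage is validated against the generator's known parameters, and all shipped
codelists are deliberately synthetic stand-ins.

## The generator

### Population structure

`generate_population()` draws ages as integers uniformly within 5-year bands
(65–69 … 85–89, with 90+ uniform on 90–99) under configurable band weights,
sex as Bernoulli(`prob_female`), and — for EHR cohorts — a registration
start date uniform over a configurable window before the index date. The
default band weights and sex fractions per source are stored in
`inst/extdata/generator_defaults.yaml` and reflect the published composition
of a large English primary-care cohort (53.6% female, heavier top age bands)
and an English ageing survey wave (56.3% female, lighter top bands). The
default index date is 1 January 2018.

### Deficit prevalence model

Each deficit follows a logistic model

$$\operatorname{logit} p_{ij} = \beta_{0j} + \beta_{\text{age},j}(a_i - 65)
  + \beta_{\text{sex},j} s_i + \beta_{\text{src},j} d_i + \lambda_j u_i,$$

with sex coded 0 = male / 1 = female and source 0 = survey / 1 = EHR (the
coding used throughout the package), and $u_i \sim N(0,1)$ a shared
per-person latent factor. The latent factor is the simplest mechanism that
(a) makes deficits positively correlated within person, and (b) produces the
right-skewed, gamma-like FI distribution with an effective upper bound well
below 1 that is consistently observed in real cohorts. It is a modelling
convenience, not a claim about the true dependence structure; it is
generator-internal and never exported with analysis inputs.

Default parameters were fixed once, at design time:

* Baseline prevalences (age-65 male, survey side) span the published
  per-deficit prevalence range (≈ 0.6% to ≈ 50%), assigned per deficit with
  plausible sex and age gradients (e.g. strongly female-skewed osteoporosis
  and thyroid disease, male-skewed ischaemic heart disease, steep age
  gradients for cognitive and mobility items).
* The source log-odds of the 14 directly comparable deficit pairs are the
  published adjusted odds ratios (13.50 for visual impairment down to 0.16
  for falls). These enter only as generating parameters; the pairs share
  their remaining coefficients exactly, so the configured source log-odds is
  the true conditional contrast.
* A single calibration simulation (n = 20 000 per source) fixed the overall
  prevalence scale (0.72 EHR side, 0.66 for survey-specific items) and the
  latent loading $\lambda = 0.55$ so that default cohorts have mean FI
  ≈ 0.13, a right skew (mean > median), and maxima comfortably below 0.75.
  These values were then frozen in the versioned YAML defaults file.

### Records and responses

`generate_ehr_records()` materialises the drawn presence flags as raw
inputs: at least one codelist event strictly before the index date per
present coded deficit (dates uniform over the preceding 9 years),
prescriptions spanning at least five distinct BNF paragraphs inside the
84-day window for polypharmacy-positive persons (and at most four for
negative persons), plus distractor codes matching no codelist and
prescriptions outside the medication chapters. Only ordering relative to
the index date matters to ascertainment, so uniform dates suffice. By
construction the ascertainment module must recover the drawn flags exactly;
that round trip is a core test.

`generate_survey_responses()` emits the drawn flags directly as a wide
person × item table and then blanks cells completely at random (MCAR) at a
per-item probability. The default (0.005) reproduces the high completeness
reported for the survey instrument (≈ 98% of participants with at most one
missing item of 58). A uniform MCAR rate cannot simultaneously reproduce
the ~5% of participants excluded for missing more than 20 items — real
missingness is person-clustered — so the completeness filter is exercised in
tests with deliberately elevated missingness instead. No informative
missingness or carry-forward from earlier waves is modelled.

## Ascertainment conventions

* "Before the index date" is strict (`<`); an event on the index date does
  not count.
* "65+ years" and "9+ years of registration" are inclusive (`>=`), the
  conventional reading; registration is compared calendar-exactly (nine
  years earlier to the day qualifies). Survey persons are exempt from the
  registration criterion.
* The polypharmacy window is half-open, `[index, index + 84 days)`, i.e.
  "84 days since baseline".
* Coded absence is absence: EHR matrices contain no missing cells. Survey
  matrices keep missing cells missing — they are never recoded to 0.
* Code matching is exact string equality after whitespace trimming; the
  shipped toy codelists are flat, so no hierarchy expansion is attempted.
* Prescriptions without a BNF paragraph are dropped by default with a
  logged count; `polypharmacy_spec(missing_bnf = "count_distinct")` instead
  counts each such row as its own paragraph, an explicit upper bound. No
  imputation is attempted, since no recoverable method exists for it.
* Non-medication exclusions are modelled as a configurable excluded-
  paragraph set, the only representation available without product-level
  dictionaries.

## Scoring conventions

The score is `n_present / n_assessed` with `n_assessed` the person's
non-missing item count — standard cumulative-deficit practice under item
missingness, and bounded in its distortion by the completeness filter
(at least 38 of 58 items). A fixed-denominator variant
(`denominator = "total"`) is provided because published survey indices do
not always state their convention. Categories use half-open intervals
closed on the left: 0.12 is mild, 0.24 moderate, 0.36 severe. Quartiles use
the linear-interpolation convention (R type 7) and SD is the n−1 sample
standard deviation; both choices are recorded in report metadata. A
single-observation group reports SD 0 rather than NA, matching how cohort
tables print degenerate cells.

## Harmonisation

The shipped mapping (`inst/extdata/deficit_mapping.csv`) relates the
36-deficit EHR index to the 58-item survey index: 14 one-to-one pairs
(named, directly comparable constructs such as diabetes, hypertension,
falls), 6 broader EHR deficits fanning out to 31 finer survey items
(mobility, activities of daily living, respiratory disease, memory, weight
loss), 16 EHR-only deficits (including polypharmacy) and 13 survey-only
items (largely psychological wellbeing). Group memberships beyond the
published examples are synthesised with realistic cardinalities and marked
`placeholder` in the `note` column. Validation enforces the partition
property — every deficit of each index in exactly one relation — with an
explicit `overlap` annotation available for items whose capture genuinely
overlaps another deficit's.

## Comparison battery

* **Standardised prevalence** — direct standardisation over the 12
  (age band × sex) strata. The reference weights default to the pooled
  two-source population, which treats both sources symmetrically; the
  scheme is injectable. Unobserved strata are dropped and weights
  renormalised with a warning, avoiding 0/0 while keeping weights summing
  to 1.
* **Per-deficit odds ratios** — maximum-likelihood logistic fits with Wald
  95% intervals (the conventional default; profile intervals would also be
  defensible). Constant outcomes, single-source tables and apparent
  separation are flagged rather than returned as NaN. No multiple-testing
  adjustment is applied across the 14 pair models — each pair is reported
  at its own p-value — and report metadata says so.
* **Kolmogorov–Smirnov** — D computed exactly as the supremum of the ECDF
  difference over the pooled jump points (correct under the heavy ties of
  FI scores); the p-value is the two-sided asymptotic approximation, exact
  for practical purposes at the sample sizes involved.
* **Linear model** — least squares on
  `(age − 65) + sex + source` plus all three pairwise interactions. The
  default generating coefficient set stored alongside the generator
  defaults is the published seven-coefficient estimate (age 0.0046, female
  sex 0.0241, source −0.0029, age×sex 0.0002, age×source 0.0009,
  sex×source −0.0163); the companion residual SD 0.071 is derived from the
  published R² ≈ 0.198 given the default covariate spread.
  `simulate_linear_scores()` deliberately does not clamp simulated scores
  to [0, 1], so least squares stays unbiased for recovery checks.
* **Distribution report** — normalised histograms with one bin per possible
  deficit count (36 EHR, 58 survey), ECDF tables and quartiles by age band.

## Parameter recovery and the latent factor

A subtlety worth recording: logistic regression is non-collapsible. When
cohorts are generated *with* the latent factor, the marginal source log-odds
recovered by a model omitting $u$ is attenuated by roughly
$1/\sqrt{1 + 0.35\,\lambda^2}$ (≈ 5% at $\lambda = 0.55$) relative to the
conditional parameter. At n = 20 000 per source that attenuation exceeds
three standard errors for the most precisely estimated deficits, so exact
recovery of the configured coefficients is a true proposition only under the
conditional model. The recovery checks therefore generate with
$\lambda = 0$, where the fitted logistic is exactly the data-generating
model; runs under the shipped defaults are reported descriptively, and the
attenuation is visible there as slightly shrunken extreme odds ratios.

## Problem sizes and determinism

The test suite uses cohorts of a few hundred to 10 000 persons for
distributional checks and 20 000 per source for recovery checks, and 500
replicates for the null-coverage experiment — sizes at which binomial and
asymptotic tolerances (3–4 SEs) are meaningful without excessive runtime.
All generator stages draw from one root seed split deterministically per
stage; identical configurations yield byte-identical outputs, which the
tests assert.

## Limitations

* The generator emulates structure (prevalence gradients, correlation,
  skew, missingness rate), not clinical realism: no consultation behaviour,
  coding habits, informative observation, care-home coverage differences or
  person-clustered item missingness. Passing tests demonstrate correctness
  of the pipeline under known conditions, not fidelity to any real cohort.
* The published headline comparisons from real data (mean FI 0.13 in both
  sources, medians 0.138 vs 0.086, K–S D 0.176, R² 0.198) require licensed
  microdata and are intentionally *not* reproduced as outputs; they appear
  only as generating defaults and layout references.
* Shipped codelists are synthetic; mapping group memberships beyond the
  published examples are placeholders with correct cardinalities.
* Survey design weights and linkage to hospital or mortality data are out
  of scope.

## A minimal run

```{r example, eval = FALSE}
bundle <- run_frailty_pipeline(run_config(n_ehr = 2000, n_survey = 2000,
                                          seed = 1))
bundle$manifest
tidy(bundle$or_fit)
plot_score_ecdf(bundle$distribution)
```
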