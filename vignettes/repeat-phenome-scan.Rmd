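---
title: "Scanning a trinucleotide-repeat genotype against a phenome: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scanning a trinucleotide-repeat genotype against a phenome: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repeatscan)
```

## The problem

Variable trinucleotide repeats — here the GCC repeat at the FRAXE fragile
site in *AFF2/FMR2* on the X chromosome — are natural candidates for
pleiotropy: a single genotype that might nudge many phenotypes at once,
none of them strongly.  A phenome scan turns the usual association study
around.  Instead of asking whether one pre-specified phenotype is linked to
the genotype, it tests the genotype against an entire battery of outcomes
(here 1,951 items across six neurocognitive domains) and then asks a
second-order question: *are there more significant associations than chance
would produce?*  Because males are hemizygous for X-linked loci, each boy
contributes exactly one repeat count, which keeps the genotype model simple.

`repeatscan` implements that design as a reusable, fully testable pipeline:

1. **Dual per-item testing.** Every item is tested twice —
   (a) a *binary split*: subjects with more than 24 repeats (the mode of the
   second peak of the repeat distribution) versus the rest, fitted as a
   logistic model of high-repeat status on the item's category score
   (categorical items) or a two-group mean-difference linear model
   (continuous items); and
   (b) a *linear trend*: a regression of the repeat count on the item's
   numeric score, reported as the slope in repeat units per category step.
2. **Enrichment counting.** For each domain, topic, and the battery as a
   whole, the number of tests significant at `p < alpha` (strictly) is
   compared with the chance expectation `n_items * alpha` via
   `(obs - exp)^2 / exp`, flagged when the statistic exceeds the
   chi-square(1 df) 0.95 quantile (3.84).
3. **Concordance filtering.** An item counts as showing evidence of
   association only when both methods are significant *and* agree in
   direction.
4. **Drill-down.** Flagged excess domains are broken out by topic, and each
   significant categorical item gets a per-category summary: n, % (and
   count) with >24 repeats, mean [SD] repeats, with counts under 5 rendered
   `"<5"` in reports.

The analyses are deliberately unadjusted — no covariates, no multiplicity
correction.  The design treats the scan as a hypothesis generator: an excess
of small p-values across a domain, not any single item, is the signal, and
no Bonferroni-style cut point is applied because single-phenotype causality
is not the claim being made.

## Model orientation

Published descriptions of this design say only "logistic regression
comparing the high-repeat group with the rest", which leaves open which
variable is the response.  We model **high-repeat status as the logistic
response** with the item score as predictor, for two reasons: it matches the
repeat-side category summaries the drill-down tables present (mean repeats
and % high per response category), and for a single categorical predictor
the score test is identical in either orientation, so only Wald p-values
can differ, and then only slightly.  For continuous items the binary arm is
a two-group mean-difference model, matching the way such results are
reported (e.g. "mean difference +2.13").  Ordinal items are scored
`0, 1, 2, ...` in their stated category order.

Both tests are two-sided Wald tests.  Analyses are complete-case per item;
subjects with missing genotypes are excluded by construction (a property
the test suite checks: adding a genotype-missing subject changes nothing).

## Degenerate inputs

No item may abort the scan.  Items with zero variance among complete cases,
groups with fewer than 2 subjects, logistic non-convergence, or complete
separation (detected by non-convergence or fitted linear predictors beyond
±30) yield a machine-readable `not estimable` flag with a reason, never a
p-value of 0 or 1 by construction.  Enrichment expectations use the count
of *estimable* items; with complete data this coincides with the nominal
count.

Ties at the significance boundary count as not significant (`p < alpha`
strictly), and the flag comparison uses the full-precision chi-square
quantile (3.8415); 3.84 is only the display form.  The flag is two-sided —
a severe deficit of associations also departs from chance — but drill-down
is permitted only for excesses, since "which items drive the excess" is the
question drill-down answers.

## The synthetic-cohort generator

The real cohort behind this design is under managed access, so the package
ships a generator reproducing the statistical structure the scan assumes.
Its defaults are the study conditions, fixed once:

* **Repeat counts.** A two-component mixture of *discretized, truncated
  normal* distributions on integer support [4, 59] (the normal-range
  framing: below ~60 repeats, far under the >200 full mutation the original
  assay could not detect).  Modes 15 and 24 are as published.  The
  published sources give no component weights or spreads, so those are the
  package's own calibration: `dispersion_low = 2.0`, `dispersion_high =
  3.0`, `weight_high = 0.14`, chosen analytically so the exact pmf has true
  local modes at 15 and 24, a marginal SD near 3.8 (consistent with the
  repeat SDs reported in category summaries), and tail mass
  `P(count > 24) = 0.0607`, matching the ~5–7% high-repeat fractions those
  summaries print.  Sampling uses the exact pmf, so the configured tail
  mass *is* the sampling-design value.
* **Battery.** Six domains with the published item counts
  (525/636/271/102/248/169, totalling 1,951) and the published topic
  subdivisions.  Measurement types cycle deterministically within each
  topic: 30% binary, 45% three-category ordinal, 25% continuous — a
  questionnaire-dominated mix with a minority of continuous test scores,
  which is what such batteries look like.  Binary items threshold a latent
  normal at the 70th percentile; ordinal-3 items at the 50th and 80th
  (a "No / A little / A lot" shape).
* **Effects.** Injected on the latent scale: `trend` adds
  `magnitude x standardized repeat count`; `high_shift` adds a
  `magnitude`-SD offset above the threshold.  Magnitude 0 is byte-identical
  to no effect (tested), so effect plumbing cannot contaminate null runs.
* **Correlation.** Optional block structure — consecutive items share one
  latent factor with a configurable loading.  This exists to quantify the
  design's acknowledged limitation that items are treated as mutually
  independent when they are not: block correlation leaves the *mean*
  observed count unbiased but inflates its *variance*, which the property
  suite demonstrates.
* **Missingness.** Completely at random only.  Differential availability
  (richer families more likely genotyped, in the real cohort) is a selection
  phenomenon out of scope here.
* **Seeding.** One master seed; per-stage substreams are derived
  deterministically so stages can be re-run independently.  Identical
  configs are byte-identical end-to-end, through the TSV round-trip
  included.

What passing tests on this generator do **not** show: robustness to
non-random missingness, to instrument-specific item distributions (skewed
scales, floor/ceiling effects), or to the real correlation geometry of a
longitudinal battery, which is not block-diagonal.  The generator verifies
the *machinery* under the scan's own assumptions; external validity of any
real finding still rests on replication cohorts.

## Numerical choices

* Per-item public functions use `stats::lm()`/`stats::glm()`.  The
  batch engine behind `run_scan()` computes the same statistics from
  sufficient statistics — closed-form simple-regression algebra, and
  logistic IRLS (`stats::glm.fit`, epsilon `1e-10`) on per-category
  aggregated counts, which is exact for the likelihood.  The test suite
  asserts per-item agreement between the two routes (1e-10 for the linear
  fits; 1e-4 relative for logistic, the IRLS stopping-point scale).
* Calibration suites in the tests use 200 replicate null cohorts of
  n = 2000 at the full 1,951-item battery, and 100 replicate
  effect-recovery cohorts of n = 5000 — sizes at which the binomial
  standard error of the mean observed count is well under 1 count.
* Display rounding (expected counts to 1 dp, percentages to 1 dp, means/SDs
  to 2 dp) uses half-away-from-zero, as such tables are conventionally
  printed, and only ever at render time.

## A small worked run

```{r example, eval = FALSE}
cfg <- sim_config(
  n_subjects = 2000, seed = 42,
  effects = list(effect_spec(target_domain = "Addictions",
                             mechanism = "trend", magnitude = 0.1)))
run <- run_pipeline(run_config(cfg, tempfile()))
subset(run$enrichment$domain, alpha == 0.05 & method == "linear_trend")
```

The flagged `Addictions` row shows the recovery behaviour the acceptance
experiments quantify: with a standardized trend slope of 0.08 on one
domain at n = 5000, that domain is flagged in essentially every replicate
while effect-free domains are flagged at roughly the nominal chi-square
rate.

## Known limitations

* The enrichment flag treats the observed count as binomial; correlated
  items make it anticonservative (variance inflation), which the package
  quantifies but does not correct — matching the design it implements.
* Logistic Wald p-values are asymptotic; in very small categories the
  per-category exact alternatives are not provided (the 2x2 closed form is
  used only as a test oracle).
* The generator's latent-threshold items are probit-flavoured while the
  analysis model is logistic; this mild misspecification is intentional —
  analysis models in the field never match the data-generating process.
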