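---
title: "Quantifying gingival colour change: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gingival colour change: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gingicol)
```

This vignette explains the models and procedures behind `gingicol`, the
assumptions they make, and the design choices taken where the methodology
was genuinely open.

## The measurement model

Each subject contributes replicate spectrophotometric CIELAB readings
(nominally three) at four gingival zones — distal papilla, free gingival
margin, middle attached gingiva, mucogingival line (the last also called
the upper zone of the attached gingiva; both labels are accepted) — at two
timepoints, before and four weeks after periodontal debridement. Replicates
are averaged coordinate-wise (`average_replicates()`) and the mean is the
analysis value: replicate noise is treated as zero-mean measurement error,
so the mean is the natural point estimate and no replicate-level modelling
is attempted. Subjects missing a zone/timepoint cell are excluded listwise
from any comparison needing that cell, never imputed, and every exclusion
is reported; with complete data the two policies coincide.

## Colour differences and perceptibility

Two metrics are implemented. The Euclidean `delta_e_ab()` is the classic
straight-line distance in CIELAB space. `delta_e_00()` implements the full
CIEDE2000 formulation — G chroma correction of a\*, adjusted chroma and hue,
the S~L~/S~C~/S~H~ weighting functions and the R~T~ rotation term — with
the widely adopted computational conventions: hue angles in degrees via the
two-argument arctangent mapped to [0°, 360°); the hue of a neutral colour
(C′ = 0) defined as 0; the branch rules for mean hue and hue difference
when the two hue angles are more than 180° apart; and
ΔH′ = 2√(C′₁C′₂)·sin(Δh′/2). The parametric factors k~L~ = k~C~ = k~H~ = 1
by default (the reference viewing conditions; no study-specific factors are
assumed) and are overridable. The test suite checks the implementation
against a structurally independent reference implementation (radians,
scalar, explicit branches) on 1,000 random pairs to 1e-9, against published
reference test pairs, and against the neutral-axis closed form
ΔE₀₀ = ΔL/(k~L~S~L~) to 1e-12.

A colour difference counts as *perceptible* when it strictly exceeds the
gingiva-specific 50:50% perceptibility threshold: 3.1 for ΔE~ab~ and 2.1
for ΔE₀₀. Strict inequality follows the usual "ΔE > threshold" notation; a
difference exactly at the threshold is not perceptible. Both defaults are
configurable (`perceptibility_thresholds()`) because such thresholds are
colour-space- and tissue-specific; no separate acceptability threshold is
modelled beyond that configurability.

## Clinical aggregation rules

Two dichotomies turn site-level index scores into analysis groups, both
count-based and therefore invariant to site order (fixed in all I/O as
distal-vestibular, vestibular, mesial-vestibular):

* **Plaque**: a subject is "plaque" only when plaque is present at all
  three sites; one or two positive sites count as "no plaque".
* **Severity**: "moderate/severe" when a Löe–Silness grade of 2 or 3 is
  recorded at two or more of the three sites. Grade ≥ 2 is what counts
  toward the rule — moderate and severe are pooled throughout, so there is
  no separate severe tier. One documented edge: a subject with a single
  grade-3 site and nothing else above grade 1 is grouped "mild" under the
  two-of-three rule; the rule is applied as stated rather than guessing an
  intent for that case.

## Statistical toolbox

Unpaired comparisons use Student's pooled-variance t-test
(df = n₁ + n₂ − 2), not Welch: re-deriving published table annotations from
printed group means/SDs matches the pooled formulation, and the
summary-statistic entry point (`unpaired_t_cohen_from_summary()`) exists
precisely to make such re-derivations reproducible from rounded cells.
Cohen's d = (mean₁ − mean₂)/pooled SD, with the conventional bands
(negligible < 0.2 ≤ small < 0.5 ≤ medium < 0.8 ≤ large; boundary values
fall upward). Paired comparisons test the within-subject differences with
d = mean(diff)/SD(diff) under a pre-minus-post sign convention, so
post-treatment lightening yields negative t and d. All p-values are
two-sided at α = 0.05 and no multiplicity adjustment is applied (matching
the analysis style the pipeline reproduces); the run log records the number
of tests performed so readers can judge the familywise error themselves.
The two-proportion z-test uses the pooled estimate without continuity
correction; a degenerate pooled proportion (all successes or failures)
returns a flagged p = 1 rather than NaN. McNemar's test uses the chi-square
form for b + c ≥ 25 (continuity correction off by default, since there is
no reference result to calibrate a corrected variant against) and the exact
two-sided binomial form below that.

Degenerate variances (identical constant samples, or a constant paired
shift with zero noise) raise an explicit error in the direct calls and
propagate as flagged NA rows — not failures — inside the pipeline's
table-building loops.

## The synthetic cohort generator

No subject-level data are distributed with the package, so the generator
exists to make the whole pipeline testable under the cohort structure the
analysis assumes. Its defaults *are* the reference study conditions:

* 43 subjects: 18 thin / 25 thick biotype; 30/13 plaque groups and 27/16
  severity groups after aggregation. Group labels are assigned first and
  site tuples constructed to aggregate back to them exactly (never
  rejection sampling), with the site-tuple mix chosen to reproduce the
  published per-site margins (36/30/36 plaque-positive sites; 28/23/29
  moderate-severe sites at the default sizes).
* Zone colours are multivariate normal per (zone, group) cell, with the
  published means and SDs as parameters. Only means and SDs are published,
  so normality is the minimal distributional assumption consistent with the
  t-tests applied downstream. Cross-coordinate correlation defaults to 0
  (none is published) and is configurable for sensitivity analysis.
* Pre-treatment colours are drawn biotype-conditionally; post-treatment
  colours are drawn conditionally on the pre colours with per-zone
  within-subject correlation ρ, regressing against the pooled pre-treatment
  marginals so the post marginals keep their configured parameters.
* Replicate noise is independent N(0, 0.5²) per coordinate — a plausible
  instrument repeatability figure of half a CIELAB unit, chosen once as no
  replicate dispersion is published — and is small against the
  between-subject SDs (4–6.5 units), inflating recovered SDs by under 0.01.
* L\* values falling outside [0, 100] are resampled, not truncated, to
  avoid biasing means (with these parameters, ≈8 SDs from the boundaries,
  resampling essentially never triggers).
* Ages are drawn N(46.5, 14) clamped to the published 20–79 range; the SD
  is the package's own choice of a realistic spread for that range, as no
  usable dispersion is published.

**What the generator does not emulate.** The joint cross-tabulation of
biotype × plaque × severity is not published, so the three groupings are
calibrated marginally and assigned independently: plaque and severity
colour effects are therefore *not* planted in a default cohort, and group
comparisons on those factors behave as null analyses. Equally, real
gingival colour is bounded, plausibly skewed, spatially correlated across
zones, and correlated across coordinates; the generator is none of these.
Passing tests therefore demonstrate that the pipeline's arithmetic,
aggregation and calibration are correct under the stated model — not that
the model captures every feature of real gingiva.

## Calibrating the pre/post correlation

The published pre/post difference summaries imply substantial within-subject
correlation, but its value cannot be recovered from summary tables.
`calibrate_rho()` therefore treats it as an explicit free parameter: given
pre and post marginals and a target mean paired ΔE~ab~ (e.g. the published
6.07 at the distal papilla), it bisects ρ ∈ [0, 1) until the Monte-Carlo
mean matches the target within 0.1. The mean paired difference is monotone
non-increasing in ρ, and common random numbers across evaluations make the
objective a smooth deterministic function of ρ, so bisection converges
cleanly; an unattainable target reports the attainable range instead of
silently clamping. With the default marginals this lands near ρ ≈ 0.5–0.7
per zone. Default Monte-Carlo size is 20,000 subjects per evaluation,
giving a standard error on the mean of about 0.02 — an order below the 0.1
tolerance.

## Numerical and reproducibility choices

Every stochastic entry point takes a seed; a seed is mandatory in
`simulation_config()` and recorded in the cohort CSV header, and identical
config + seed yields byte-identical cohort CSVs and report bundles. Report
tables round percentages to one decimal and colour differences/statistics
to two, matching the precision such tables are conventionally reported at;
the in-memory tables returned by `run_study()` stay unrounded. The
percent-perceptible figure is always computed on exactly the same pair set
as the summary moments.

The test suite exercises the stochastic claims at deliberate problem
sizes: 200 seeded replicates for the two perceptibility properties, 10,000
null simulations for t-test type-I calibration (binomial SE ≈ 0.2
percentage points against the ±1-point band), exact permutation
enumeration at n ≤ 8, and 10,000 subjects per group for parameter
recovery at a 0.2-unit tolerance.

## Known limitations

* The generator's normal-marginal, independent-coordinate model is a
  modelling convenience, not an empirical fit (see above).
* Only two-level groupings are supported; the severity dichotomy discards
  the ordinal structure of the underlying 0–3 index, as does the analysis
  it reproduces.
* Published t/d values that are inconsistent with their own printed table
  cells cannot be — and are not — reproduced; the package reports what it
  computes from its inputs.
* No confidence intervals for Cohen's d, and no regression/ANOVA
  modelling: the pipeline mirrors a comparison-based analysis design.
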