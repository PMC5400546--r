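---
title: "PSA derivatives and stratified tumor-volume cutoffs: models and methods"
author: "psadens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PSA derivatives and stratified tumor-volume cutoffs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psadens)
```

This vignette is the package's account of its science: the measurement
model behind the PSA derivatives, the cutoff-selection procedure, what the
synthetic-cohort generator does and does not emulate, and the numerical
and design choices a maintainer should know about.

## The measurement model

Serum PSA in a man with Grade Group 1 (Gleason 3+3=6) prostate cancer is
treated as the sum of two production sources diluted into his plasma:

* benign prostate tissue, producing PSA roughly in proportion to prostate
  weight (PW, grams, without seminal vesicles), and
* the tumor, producing PSA in proportion to tumor volume (TV, cm³) at a
  rate that differs across race/ethnic groups.

Because concentration, not mass, is measured, a larger plasma volume reads
as a lower PSA at equal production ("hemodilution"). The derivatives are
the standard corrections:

* `psad = psa / pw` (ng/mL per g) divides out gland size;
* `psam = psa * plasma_volume` (μg) converts concentration to circulating
  mass, undoing hemodilution;
* `psamd = psam / pw` (μg per g) applies both corrections at once.

Plasma volume is `1.67 * bsa`, and BSA is evaluated as
`0.007184 * weight^0.425 * height^0.72` **with height in meters**. This is
deliberately not the classic Du Bois formula (height in centimeters,
exponent 0.725): the meters convention produces PSAM values on the
microgram scale on which the published PSAM summaries and PSAMD cutoffs
(e.g. the 0.012 screening threshold) live. The classic convention yields
values ≈27× larger, on which those cutoffs are meaningless. Both are
available (`compute_bsa(mode = "meters")`, the default, vs
`mode = "dubois-cm"`); the mode is recorded on every derived cohort.

Tumor volume comes from pathology: total mm² of tumor counted on 1-mm²
gridded slide photocopies × 3 (section thickness, mm) × 1.12 (formalin
shrinkage), reported in cm³. TV ≥ 0.5 cm³ — threshold inclusive, so the
boundary value itself is significant — defines significant disease; 149
mm² is the smallest integer grid count that crosses it.

## Cutoff selection

For each race/ethnic group and each derivative, the ROC curve of the
score against significant TV is built with one operating point per
distinct observed score value, calling positive when `score >= threshold`
(so a published cutoff value itself screens positive — the convention the
whole package uses), plus the all-negative point. The AUC is the
trapezoidal area, which on this construction equals the pair-counting
concordance statistic; the test suite verifies that identity exhaustively
on small instances and against pROC on larger ones.

The optimal cutoff is the **upper-left point**: the operating point
minimizing the Euclidean distance from (FPR, sensitivity) to (0, 1).
Youden's J (maximizing sensitivity + specificity − 1) is available as an
alternative criterion. Numerical choices, all visible in the tests:

* thresholds are evaluated at observed score values, never midpoints —
  reproducible on discrete data;
* distance ties (which arise exactly on small discrete curves and to
  machine precision on rational sens/spec values) are resolved with a
  1e-12 tolerance, then toward higher specificity, then toward the higher
  threshold — a screening-conservative rule;
* rates with a zero denominator (PPV with no positive calls) are reported
  absent (NA), never 0.

Sensitivity "at 80% specificity" is read conservatively: the sensitivity
of the point with the smallest achievable specificity at or above the
target, with no interpolation. Two derivatives on the same records are
compared with a seeded paired percentile bootstrap (default 2000
resamples) of that fixed-specificity sensitivity difference; resamples
that lose one outcome class are redrawn. A bootstrap was chosen because
the comparison is of a nonsmooth functional of two correlated ROC curves,
for which no standard closed-form paired test applies; the method is
labelled in the result object.

## Statistics

Group comparisons use the classic pooled-variance Student t test for two
groups and a one-way ANOVA F test when more than two groups are compared
at once (a single p-value across four groups requires an omnibus test;
both interfaces are exported). Categorical tables use the Pearson
chi-square without continuity correction. Correlations are Pearson's r,
with the age-partial form
r_xy·z = (r_xy − r_xz·r_yz) / √((1 − r_xz²)(1 − r_yz²)), which the tests
verify equals the correlation of residuals after regressing both
variables on age. Linear association of TV with each derivative is
ordinary least squares, univariable or age-adjusted (age is the only
added covariate). No multiple-testing correction is applied anywhere;
p ≤ 0.05 is flagged in the report layer. Records missing height/weight
are excluded from BMI-dependent quantities only, and the exclusion count
is attached to the derived cohort.

## The synthetic-cohort generator

No patient-level data ship with the package; the generator exists so that
every downstream stage has realistic, seeded input. It emulates a
589-man, four-group (NHW 390 / NHB 87 / Hispanic-Latino 78 / Other 34),
two-institution radical-prostatectomy series:

* **Prostate weight and tumor volume** are lognormal per group. Medians
  are the published group medians (PW 44.9/51.5/42/41 g; TV
  0.35/0.51/0.35/0.39 cm³); dispersions were derived once from the
  published mean/median ratios (right-skew implies
  mean/median = exp(σ²/2)). Draws are rejection-truncated to the
  observed envelopes, and the lognormal location is solved (numerically,
  per group) so the *truncated* distribution has the target median —
  naive truncation would shift medians up by up to 9% where the lower
  bound carries mass.
* **Serum PSA** follows the mechanistic model
  `psa = (alpha * pw + beta_g * tv) * (pv_ref / pv)^gamma * noise`,
  truncated to the observed 0.3–13 ng/mL. `alpha` (benign rate, 0.073
  ng/mL per g) and `beta_NHW` (tumor rate, 2.29 ng/mL per cm³) were fit
  once, by least squares on the generator's own large-sample group
  medians against the four published group PSA medians, and frozen.
  `beta_NHB = 0.75 * beta_NHW` encodes the reported 25% lower PSA
  production by NHB tumors; the Hispanic/Latino deficit (15%) has no
  published value and is a documented free parameter. `gamma = 1` makes
  hemodilution a simple inverse proportionality to plasma volume.
  The residual noise is median-preserving lognormal with sdlog 0.15, the
  floor corresponding to the ~15% biological/assay coefficient of
  variation of serum PSA — the published PSA mean/median ratio leaves
  essentially no room for additional residual dispersion beyond the
  structural terms.
* **BMI** is a per-group category mixture (normal/overweight/obese at the
  published proportions) with uniform values within category; weight is
  back-solved from BMI and a normal height (1.75 ± 0.07 m). Age is
  truncated normal per group.

One structural tension is worth knowing: with a *common* benign rate and
the 25% NHB tumor deficit, no parameter choice reproduces all four
published group PSA medians exactly, because NHB men have both heavier
prostates and larger tumors yet the same published median PSA. The
best-fit calibration leaves the NHB median ≈ +13% and the
Hispanic/Latino median ≈ −10%; the calibration tests therefore assert
group medians within ±15%, on a 20×-scaled cohort so that sampling error
(~17% relative for a median of a lognormal with σ ≈ 1.2 at n = 78) does
not mask what is being checked.

What the generator does **not** emulate: inter-variable correlations
(PW–BMI, TV–age) beyond weak ones implied by the construction; Gleason
pattern mixtures; tumor location; the upper tail of PSA beyond the
truncation envelope (a handful of extreme structural values are clamped
to it); and any real measurement error in PW or TV. Its synthetic
cohorts also discriminate more cleanly than clinical data — with a small
residual noise term, PSAD/PSAMD carry more signal about TV than they do
in practice — so passing tests demonstrate correctness of the machinery,
not clinical performance. The shipped surname list is likewise a ~50-name
synthetic fixture spanning the five association tiers, not the census
surname list; a full list can be supplied as a two-column file.

`recover_parameters()` closes the loop: per-group no-intercept least
squares of PSA on (PW, TV) recovers `alpha` and `beta_g` — exactly on
noiseless cohorts, and with the between-group `beta` *ratio* robust to
hemodilution (the average hemodilution factor multiplies both groups'
estimates and cancels). Ignoring hemodilution does bias within-stratum
estimates low in high-BMI strata, which a test demonstrates.

## The null comparison design

To show that the NHB-below-NHW cutoff ordering is driven by the race
effect, the generator offers `null_no_race_effect`: identical tumor
rates *and* identical PW, TV, BMI and age distributions in every group
(equalizing only the rate would leave the BMI mixture acting through
hemodilution — a residual systematic difference our own testing caught).
One subtlety remains even under a perfect null: the finite-sample
distribution of the upper-left cutoff depends on group *size*, so with
identical populations but 87-vs-390 sampling, the two cutoffs are not
exchangeable and their ordering is not a fair coin (we measured
P ≈ 0.44 over 1000 replicates). The null sign-test check is therefore
run at equal NHW/NHB sizes, where exchangeability makes the ordering
exactly symmetric; note the unequal-size artifact points *against* the
race effect, so the effect-direction check at the study's own sizes is
conservative.

## Degenerate inputs and edge cases

Single-class strata are reported as not-estimable rows, never dropped or
guessed. Cohort validation is strict by default (any invalid record is an
error); lenient mode drops invalid rows, keeps them with reasons on an
attribute, and warns. Missing surnames assign Non-Hispanic with a
warning; compound surnames match as whole normalized strings (no
tokenization). Unknown race/ethnicity becomes its own UNKNOWN level,
analysed within the "Other" group convention. BMI bins follow the WHO
boundaries with 18.5/25/30 inclusive on the upper side, i.e.
[18.5, 25), [25, 30), [30, ∞).

## Problem sizes used in the checks

The test-suite simulations use: 1000 random small instances for the
ROC-vs-brute-force identities; 10⁴ replicates per test for the type-I
error calibration of t/F/χ²/Pearson; 100 replicates at 5000 men per
group for tumor-rate recovery; and 100 replicates at the study's group
sizes for the cutoff-ordering checks. These sizes give Monte Carlo
standard errors comfortably inside the asserted bands while keeping a
full run in the low minutes on one core.

## Known limitations

The package estimates cutoffs; it does not validate them clinically.
Upper-left cutoffs on small strata (n < 100) are noisy and should be
read with their operating characteristics, not as free-standing
thresholds. PW here is the pathological weight without seminal vesicles,
available only after prostatectomy; preoperative use requires an imaging
estimate. The PSAM/PSAMD scale is convention-bound: values and cutoffs
transfer only between implementations using the same meters-based BSA
formula.
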