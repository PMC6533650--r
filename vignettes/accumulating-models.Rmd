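---
title: "Accumulating risk scores for prostate cancer: models, evaluation and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Accumulating risk scores for prostate cancer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

An accumulating model summarises one patient's pre-biopsy risk as an
integer. The inputs are the radiologist's PI-RADS v2 category
(1–5, taken as-is, not re-binned) and the three serum markers, each
mapped to an ordinal level 1–4 by fixed clinical cut-offs:

* **PSA** (ng/mL): levels split at 4, 10, 20 — ascending risk.
* **PSAD** (ng/mL/mL): splits at 0.1, 0.19, 0.23 — ascending risk.
  PSAD is total PSA divided by prostate volume; when only the three
  orthogonal dimensions are recorded the volume is the ellipsoid
  approximation `length × width × height × 0.52` (cm → mL).
* **f/t PSA** (dimensionless): splits at 0.14, 0.18, 0.24 —
  *descending*: a small free fraction is the high-risk end, so
  f/t ≥ 0.24 is level 1 and f/t < 0.14 is level 4.

A model is a vector of non-negative integer weights
`(w_pirads, w_psad, w_ft, w_psa)` and the score is the weighted sum.
The registry (`model_registry()`) fixes the fourteen vectors studied:
unit-weight combinations (`model1`–`model6`), a 2×PI-RADS + 3×PSAD
family (`model7`–`model10`), a 2×PI-RADS + 2×PSAD family
(`model11`–`model13`) and the PI-RADS-only `baseline`. The weights are
registry constants, not a fitting procedure: this package evaluates
the given scores, it does not search for weights.

Ground truth is the biopsy: the four-tier Gleason grouping (group 1 =
benign, 2 = GS 6, 3 = GS 7, 4 = GS 8–10; GS < 6 lesions are treated
with the benign stratum), the PCa flag (group ≥ 2) and the clinically
significant flag (CS PCa: Gleason sum ≥ 7 and/or maximum cancer core
length ≥ 4 mm, so groups 3–4 are always significant and GS 6 records
are decided by core length).

## Boundary and degenerate-input conventions

The printed cut-offs do not say which level owns an exact boundary
value. The package uses left-closed/right-open intervals on the
ascending ladders (PSA = 10 is level 3, PSA = 20 is level 4, so the
four levels partition `[0, ∞)` without gaps) and honours the closed
bounds of the top PSAD stratum (`≥ 0.23`) and the low-risk f/t stratum
(`≥ 0.24`). Exact boundary membership is clinically immaterial —
marker values are continuous — but a total partition keeps every
record scorable.

When the laboratory reports only "PSA > 1000 ng/mL" no explicit free
fraction exists; such records carry `psa_censored_high = TRUE`, a
stored total of 1000, and the conventional sentinel f/t = 0.001. Since
0.001 < 0.14 the sentinel always lands in f/t level 4: it can never
move a censored record into a lower-risk stratum than any true ratio
would.

Other conventions, chosen once:

* Explicitly supplied volume (or f/t ratio) wins over the value
  derivable from dimensions (or free/total PSA); a disagreement
  beyond 0.005 in the ratio logs a consistency warning.
* A missing pathology label is tolerated while scoring but rejected by
  every evaluation routine (confusion metrics need labels).
* Operating-point metrics with a zero denominator (all-positive or
  all-negative cohorts) are reported as `NA`, never silently 0 or 1.
* Reported metrics round half-up: 3 decimals for proportions,
  matching clinical reporting practice.
* The positive test is `score ≥ cutoff`; the Youden-optimal cut-off
  maximises `J = sensitivity + specificity − 1`, ties broken toward
  the larger cut-off (the higher-specificity side).

## Evaluation suite

The ROC curve sweeps the threshold over the observed scores (plus a
sentinel above the maximum); the AUC is the trapezoid area, which for
tied integer scores equals the Mann–Whitney probability
`P(score⁺ > score⁻) + ½·P(tie)` — the test suite asserts this identity
against an exhaustive pairwise oracle. Group summaries use the sample
sd (n−1) and Student-t intervals `mean ± t(1−α/2, n−1)·sd/√n`; the t
quantile (not a normal one) is what reproduces published group
intervals at these group sizes. One-way ANOVA is the classical
fixed-effects F on (k−1, N−k) df, with an explicit branch for zero
within-group variance. Kendall tau-b (tie-corrected) measures the
association between the ordinal levels; logistic odds ratios are
maximum-likelihood (IRLS via `stats::glm`), dummy-coded against the
reference strata PI-RADS 1–2, PSAD < 0.1, f/t ≥ 0.24, PSA < 4, with
Wald 95 % intervals, and any coefficient beyond ±15 on the log scale
is flagged as separation rather than reported as a plain estimate.

## The synthetic cohort generator

No patient-level dataset of this design is publicly deposited, so the
generator supplies labelled cohorts whose *summary structure* matches
a 357-patient biopsy referral population. Generation is group-first —
the four Gleason groups have fixed sizes 174/34/74/75 (the 8–10
stratum split 47/22/6), because every published summary is conditional
on group — and within a group each record draws a latent trivariate
normal `z = (z_psa, z_vol, z_ft)` with correlation matrix

```
        psa   vol    ft
psa    1.00  0.40 -0.10
vol    0.40  1.00  0.50
ft    -0.10  0.50  1.00
```

transformed to log-normal PSA and volume and a logit-normal f/t
ratio; PSAD is *derived* as PSA/volume (never drawn independently), so
the serum triplet stays physically consistent and the PSAD
correlations are controlled indirectly through the PSA–volume latent
correlation.

Calibration proceeded in two layers, and the result is frozen in
`default_config()`:

1. **Locations solved analytically.** For a log-normal marker the
   expected ordinal level is `1 + Σ_c Φ((µ − log c)/σ)`, so given a
   spread σ the location µ that achieves any target mean level has a
   closed-form root. Per group, the three marker-level targets were
   chosen to sum to the target model-6 group mean (10.02, 12.03,
   14.12, 15.44) minus the group's expected PI-RADS contribution
   (fixed by the category counts: the pooled 154/35/168 split with
   benign/cancer detection counts 119/25/30 and 35/10/138,
   apportioned across cancer groups so higher groups read higher).
   Each group's expected score therefore equals its target *exactly*
   in expectation.
2. **Spreads and correlations tuned once.** The σ's and the three
   latent correlations were adjusted against the pooled quartile
   targets (PSA 6.79/11.06/21.34, f/t 0.08/0.13/0.19, PSAD
   0.15/0.24/0.56) computed from the mixture CDF, and the level tau-b
   targets (0.626/0.422/0.253) by Monte-Carlo. Achieved values at
   n ≈ 5000: tau-b 0.626/0.424/0.226 and all quartiles within 15 % —
   the psa–ft tau sits ~0.03 below its target, the price of hitting
   the other two exactly with a positive-definite 3×3 matrix.

GS-6 records draw a core length exceeding 4 mm with probability 14/34
(so roughly 14 of the 34 GS-6 cases are clinically significant, and
the expected CS count is 163 = 74 + 75 + 14); groups 3–4 are
significant by grade alone. Age is a clipped normal (mean 68, sd 8,
range 50–90) and plays no role downstream. Defaults never generate
censored-PSA records; `default_config(censor_frac = ...)` injects them
to exercise the sentinel path.

`n_scale` pro-rates the group sizes with `base::round` per group and a
largest-remainder split inside group 4, so scaled cohorts keep the
group proportions. `calibration_report()` recomputes every target on a
generated cohort and flags misses.

**What the generator does not emulate:** the joint distribution of
PI-RADS with the serum markers *within* a group (PI-RADS is drawn
independently given the group), biopsy sampling error, MRI appearance,
or the clinical referral process. Consequently cohort-level operating
points at a fixed cut-off (e.g. score ≥ 11) need not match a real
hospital cohort even when all calibrated marginals do — passing tests
show the pipeline arithmetic and the calibrated summary structure are
right, not that the synthetic joint distribution is the clinical one.
Only qualitative orderings (e.g. AUC(model6) > AUC(baseline)) are
expected to transfer, and they do.

## Problem sizes and numerics

The test suite runs the deterministic worked examples at toy size;
property suites use 10⁴ random draws for the level-function oracle,
n ≤ 200 for the exhaustive Mann–Whitney identity, 1000 replicates for
the ANOVA null-uniformity KS check, n ≈ 5000 for the tau-b
calibration and n ≈ 50 000 for generator parameter recovery (group
means within ±0.2) — sizes at which Monte-Carlo error is well inside
each tolerance while the whole suite stays interactive. Logistic
fits converge by IRLS (tolerance 1e-10, ≤ 100 iterations). Kendall
tau-b is quadratic in n, which is why calibration checks it at
n ≈ 5000 rather than on the largest simulations.

## Limitations

* The integer weights are taken as given; nothing here re-derives them
  from a regression, and no data-driven model search is provided.
* No age-stratified PSA ladders; the ladders are population-wide.
* The generator's per-group serum distributions are non-unique: they
  are pinned only by pooled quartiles, group sizes, tau-b targets and
  group score means, so other parameterisations could match the same
  summaries.
* PI-RADS is an input; the package never infers it from imaging.
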