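---
title: "Somatic maturation assessment and method agreement: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Somatic maturation assessment and method agreement: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(somamat)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters and why their defaults
are what they are, what the synthetic cohort generator does and does not
emulate, and the numerical and design choices made where the design was
genuinely open.

## The maturation model

### Maturity offset

Adolescents of the same chronological age can be years apart biologically.
The standard non-invasive proxy is the *maturity offset* (MO): the
predicted signed time, in years, from the measurement occasion to peak
height velocity (PHV), the moment of fastest standing-height growth.
Negative MO means the athlete is still before their growth spurt.

The package implements the classic sex-specific interaction-term
regressions on simple anthropometry. With `age` in decimal years, standing
height `Ht` and sitting height `SH` in cm, leg length `LL = Ht − SH`,
weight `Wt` in kg:

* boys: `MO = −9.236 + 0.0002708·LL·SH − 0.001663·age·LL + 0.007216·age·SH + 0.02292·(Wt/Ht·100)`
* girls: `MO = −9.376 + 0.0001882·LL·SH + 0.0022·age·LL + 0.005841·age·SH − 0.002658·age·Wt + 0.07693·(Wt/Ht·100)`

The girls' equation has an `age·Wt` term the boys' equation lacks; both
are used exactly as published (packaged as
`inst/extdata/maturity_offset_coefficients.csv`), never re-fitted. The
regression is a smooth function of its predictors — there are no lookups —
so small measurement perturbations move MO proportionally to the published
coefficients.

The equations were validated on ages roughly 8–18. `maturity_offset()`
warns and computes a best-effort value outside that range by default
(`age_policy = "warn"`); strict pipelines can set `"error"`. The default
suits the intended field population (10–17 yr), which sits comfortably
inside the validated range.

*PHV age* is the defining identity `age − MO`; it is exact in real
arithmetic, and the test suite asserts it at 1e-12 relative tolerance to
allow for floating-point rounding.

### Predicted adult height

Adult stature is forecast with the Khamis-Roche functional form

`PAH = β0 + β1·Ht + β2·Wt + β3·midparent`,

with coefficients indexed by sex and half-year age over 4.0–17.5 yr, and
`midparent` the plain mean of the two parental statures. Sex-specific
parental adjustments are deliberately *not* applied to midparent height:
the coefficient table is the place where sex enters, mirroring how the
published method was fit. A profile missing either parent yields an absent
PAH rather than an imputed one — silent imputation would misrepresent the
forecast's basis.

**The packaged coefficient table is synthetic.** The published
Khamis-Roche coefficient values are not redistributed here; instead
`inst/extdata/pah_coefficients_synthetic.csv` carries a smooth stand-in
with the published method's structure: the stature coefficient rises with
age towards ~0.95, the midparent coefficient falls towards zero at
maturity (and is strictly positive everywhere, so PAH is strictly
increasing in midparent stature), and the intercept is calibrated so that
a child growing along the package's default synthetic growth curves
predicts its own adult height at every tabulated age. It demonstrates and
tests the machinery; for real prediction, supply a transcription of the
published table via `pah_coefficients(path = ...)`.

Lookup is nearest-half-year by default, matching the tabulated form of the
published method; `interpolate = TRUE` switches to linear interpolation
between the bracketing rows for users who prefer a continuous-in-age
forecast. *Percent of adult height* (`100·Ht/PAH`) is the status index of
this family: unlike MO it is monotone in attained growth and insensitive
to the timing of the spurt.

### Status and timing classification

Maturity *status* partitions the MO axis: pre-pubertal below −1 yr,
post-pubertal above +1 yr, pubertal in the closed band between (boundaries
belong to pubertal, so the partition is total and monotone). The ±1 yr
circa-PHV band is the conventional three-stage choice; it is a
configuration default (`classification_config()`), not a constant, since
classification conventions differ between programmes. The classifier input
is MO rather than %PAH — with the synthetic PAH table, %PAH is
demonstration-grade, while MO comes from the published regression; users
who prefer %PAH thresholds can classify on that column directly.

Maturity *timing* compares PHV age with sex-specific population norms:
early below `mean − 1·SD`, late above `mean + 1·SD`. Defaults (13.8 ± 1.0
yr boys, 11.8 ± 1.0 yr girls) are the values conventionally cited for
Western adolescent populations; both the norms and the band width are
configurable because timing is explicitly population-relative.

The 3×3 (status × timing) → recommendation-category mapping shipped by
`default_recommendation_table()` is documentation of a mechanism — a
deterministic, configurable lookup raising an error on unmapped pairs —
not sports-science advice; the shipped categories are placeholders a
practitioner should replace.

## Photogrammetry

The capture protocol is a levelled camera 200 cm from a background wall
and 100 cm above the floor, subject against the wall. Under a pinhole
model with horizontal optical axis and fronto-parallel wall, vertical
extents at the wall plane obey similar triangles:

`length_cm = Δy_px · wall_distance_cm / focal_px`.

That single equation gives `vertical_extent_cm()` (stature or
vertex-to-seat extent), `world_height_of_pixel()` (back-projection of an
image row to a height above the floor), and `validate_calibration()` (the
floor-contact keypoint of a standing capture should back-project to height
0; its residual is a quality gate, default tolerance 2 cm).

Assumptions worth restating: lens distortion is ignored, and the subject
is assumed exactly at the wall — a subject standing `d` cm in front of it
is overestimated by roughly `d / wall_distance`. Both are documented error
sources of the single-plane model; keypoint detection itself (the
computer-vision stage) is upstream of this package, which consumes its
output coordinates. Image coordinates follow the usual convention: origin
top-left, y down, principal point defaulting to the image centre; the
focal length must be supplied in pixels.

## The agreement battery

Comparing an automated method against expert anthropometry is a
two-method, n-subject agreement problem. The package reports, per metric:

* **Mean difference (SD)** of `expert − app` differences (sample SD,
  n − 1), the Bland-Altman summary of bias and spread.
* **ICC**: the two-way, absolute-agreement, *single-measure* intraclass
  correlation — ICC(A,1) — from the ANOVA mean squares:
  `(MS_R − MS_E) / (MS_R + (k−1)MS_E + (k/n)(MS_C − MS_E))` with k = 2.
  Absolute agreement is the only reading consistent with a mixed-effects,
  agreement-oriented validation of two fixed methods: unlike the
  consistency form it penalises systematic offsets (adding a constant to
  one arm strictly lowers it; adding it to both leaves it unchanged — both
  properties are asserted in tests). The 95% CI uses the standard F-based
  construction with Satterthwaite denominator degrees of freedom; the
  model and CI method are recorded in the report metadata. The closed form
  is verified in tests against an independent `stats::aov` mean-squares
  route on 200 random datasets to 1e-10, and the CI was validated against
  an external mixed-effects implementation on frozen fixtures.
* **TEM**: `sqrt(Σ d² / 2n)`, the classic technical error of measurement;
  under independent N(0, σ) noise in each arm it estimates σ. Relative TEM
  is `100·TEM / grand mean` of all 2n values — the denominator convention
  is stated in the output because the literature varies, and relative TEM
  is misleading for signed, zero-crossing metrics such as MO (the grand
  mean can sit near zero).
* **Cross-tabulation** of status labels with percent agreement and
  unweighted Cohen's kappa. Kappa is a derived statistic offered alongside
  the raw table (and cross-checked against `e1071::classAgreement`).

Because it is ambiguous whether an automated system's "speed"-type output
is MO in years or a velocity in cm/yr, the battery is metric-agnostic:
`agreement_report()` takes a metric selector and treats MO, PHV age,
stature, or any other paired column identically, so either reading of a
published comparison is testable.

## The synthetic cohort generator

`generate_cohort()` exists so that every stage — assessment, agreement,
photogrammetry, I/O — is testable against known truth. Defaults reproduce
a cross-sectional validation design: 144 athletes (76 boys, 68 girls)
aged 10–17, each measured once by both arms on the same day.

* **Truth curves**: Preece-Baines model 1,
  `h(t) = h1 − 2(h1 − hθ)/(exp(s0(t−θ)) + exp(s1(t−θ)))`, chosen because
  it is the standard parametric adolescent curve with an explicit,
  analytically differentiable spurt. Priors are loosely anthropometric
  (adult stature 178 ± 6.5 cm boys / 164 ± 6 cm girls, spurt timing
  θ = 14 ± 0.9 / 12 ± 0.9 yr), truncated by redraw to the valid region.
* **True PHV age** is the argmax of the analytic velocity, located on a
  0.01-yr grid over θ ± 4 yr and refined with `optimize()` to 1e-6 yr
  (documented accuracy 1e-4 yr). The window matters: PB1 velocity rises
  again on the early-childhood branch (unboundedly as t → −∞), so a global
  argmax is meaningless. The prior truncations (s0 ∈ [0.08, 0.13],
  s1 ∈ [0.9, 1.4]) keep the spurt peak interior to the window; an edge
  argmax raises an error rather than silently returning a boundary.
* **Measurements**: sitting height is a linear-in-age fraction of stature
  (0.53 at age 10 to 0.52 at 18) plus 0.5 cm individual noise — a
  documented stand-in with no claim of auxological accuracy; weight comes
  from a stature-indexed BMI normal. The error model defaults to 0.3 cm
  expert noise vs 0.5 cm + 0.2 cm bias app noise (plausible magnitudes for
  careful manual anthropometry vs an image-based estimate); draws
  violating the measurement invariants are redrawn and counted.
* **Seeding**: all randomness flows from one seed through a per-athlete
  derived stream, so cohorts are byte-identical under the same seed and
  athlete *i*'s data do not change when the cohort grows or reorders.

What the generator does *not* emulate: secular trends, population
covariance between timing and adult height, measurement drift, posture
errors, or the real error structure of any specific camera pipeline.
Passing tests therefore demonstrate internal consistency of the methods
and correct implementation of the statistics — not field validity of
either measurement arm.

Two calibration-style properties tie the pieces together (both asserted
in tests, at sizes chosen to keep the default suite fast): on a
zero-noise cohort of 500, predicted PHV age correlates with the
simulator's true PHV age (Spearman ρ > 0.5) — a joint consistency check
on simulator plus equations, not a validity claim, since the regression
compresses between-athlete variance; and with 0.4 cm noise per arm at
n = 5000 pairs, TEM recovers 0.4 cm within 10%.

## Numerical and I/O choices

* **Decimal age** uses the mean Gregorian year, 365.2425 days:
  deterministic, leap-year-robust, and exactly additive over concatenated
  intervals. (Calendar-based conventions differ by up to a day across
  leap years; the choice is stated rather than hidden.)
* **Units** are cm, kg and decimal years everywhere; conversion belongs at
  I/O boundaries.
* **Degenerate inputs** fail loudly and early: sitting ≥ standing height,
  non-positive weight, observation before birth, zero total variance in
  the ICC, zero grand mean in relative TEM (absolute TEM still returned),
  unmapped recommendation pairs, keypoints with non-positive pixel extent,
  subjects outside the camera's field of view.
* **Batch processing** is fail-soft by default — per-row and per-athlete
  errors are collected with line numbers or athlete ids while the batch
  continues — and fail-fast under `strict`. Reports render to JSON at full
  precision (byte-stable through a serialise/parse round trip) and to flat
  CSV rounded to 3 decimals, the granularity of printed agreement tables.

## Known limitations

* The maturity-offset regression compresses variance: late/early maturers
  regress toward the mean, and cross-sectional PHV-age estimates are
  structurally less reliable than longitudinal ones. This is a property of
  the method family, visible here in the moderate Spearman recovery on
  simulated cohorts.
* The packaged PAH table is synthetic (see above); %PAH values from it are
  for demonstration.
* The photogrammetry model is single-plane; it does not reproduce any
  specific computer-vision pipeline's internal behaviour.
* Timing norms are population-relative; the defaults are not universal
  reference values.
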