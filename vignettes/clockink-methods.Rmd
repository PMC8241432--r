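---
title: "Methods: from pen strokes to composite cognitive scores"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from pen strokes to composite cognitive scores}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

ClockInk implements an analysis chain for digitally captured clock
drawings: graphomotor/temporal feature extraction, rank-based inverse
normal transformation, a covariate-adjusted mass-univariate association
scan against an 18-test neuropsychological battery with Bonferroni
control, per-test weighted composite scores, and logistic models for mild
cognitive impairment (MCI). This vignette is the package's account of the
statistical model, the synthetic-data design, and the numerical and design
choices a maintainer should know about.

## The data model

A `ClockDrawing` is an ordered list of pen-down strokes; each stroke is a
time-ordered run of samples `(t, x, y)` in milliseconds and millimeters
(page coordinates, y increasing down the page). Time is strictly
increasing within a stroke; stroke intervals may touch but not overlap;
the drawing's origin is the first sample of the first stroke. Strokes
carry component labels (`clockface`, `number`, `hand`, `other`,
`unlabeled`). Labels are *carried, never inferred*: the synthetic
generator emits ground-truth labels, and externally captured data may be
unlabeled — automatic stroke classification is out of scope. Pen pressure
and hover trajectories are not modeled; every feature below is a function
of position and time only.

Two plain-text dialects (flat CSV with a `stroke_id` column; nested JSON)
are defined by this package, since no vendor format is public. Reading
and writing are exact inverses on the data model. The digital pen this
emulates samples nominally at 80 Hz (12.5 ms); `validateSampling()` is an
advisory check of within-stroke gaps against that rate, and a documented
constant of 0.002 in ≈ 0.0508 mm records the nominal spatial resolution
for reference.

## Features

The default registry computes 21 features per drawing, spanning four
families: drawing efficiency (total completion time, ink time, think
time, percent-think), simple motor operation (ink length, mean/peak pen
speed, stroke count and duration), processing speed (inter-stroke
latencies, including the pause before the first hand stroke and the pause
after the clock-face stroke), and spatial organization (clock-face area,
circularity and center offset from a least-squares circle fit, number
placement error, hand-angle error against the "ten past eleven" targets,
bounding-box area). Command and copy drawings yield separate feature
columns (`_command` / `_copy`) treated as distinct features throughout;
whether to pool conditions is an open question in this literature, and
separation is the more conservative choice. The registry is an open
extension point — the reference catalog in the motivating work runs to
105 features whose exact definitions are not public, so the package ships
a documented representative subset rather than guessed reconstructions.

Circle fitting uses Kasa's algebraic least squares (linear in
`(a, b, c)` for `x² + y² = ax + by + c`), which is exact on three
non-collinear points (the circumcircle) and reports the RMS radial
residual; collinear input is a degeneracy error. Hand-angle targets place
the minute hand at the 2 o'clock position (60° clockwise from 12) and the
hour hand a sixth of the way from 11 to 12 (335°); both are package
constants, configurable by replacing the registry entry.

A feature undefined for a drawing (no hand strokes, degenerate clock
face) is recorded missing, never silently zero. Two invariants are
asserted in the tests: think + ink time equals total completion time
exactly, and all features are invariant to rigid translation of the
drawing (every geometric feature is defined relative to the drawing
itself, not the page).

## Statistical core

**Normalization.** Rank-based inverse normal transformation with the Blom
offset, `qnorm((r − 3/8)/(n + 1/4))` with average ranks for ties — the
prevailing epidemiology default; no variant is canonical, and the choice
only matters at third decimals of the normal scores. The transform is
computed on the analysis sample, per feature; constant features are set
to missing with a warning. This removes the strong right skew of latency
features while preserving order.

**Linear scan.** One OLS model per (feature, test):
`test ~ intercept + V_j + age + sex`, complete cases per pair (so n
varies by pair when scores are missing; no imputation). Standard errors
from σ̂²(XᵀX)⁻¹, two-sided p from t on n − p df. Exact fits report SE 0
with an `exact_fit` flag and NA p-values rather than NaNs. Rank-deficient
designs error naming the collinear columns. Sex is coded female = 1
(arbitrary, documented); education enters only the MCI models,
dummy-coded against a no-high-school reference.

**Selection.** Feature j is selected for test k when
p_jk < α/n_features — the Bonferroni family is the feature catalog,
applied per test, not features × tests. With α = 0.05 this is 4.76×10⁻⁴
for a 105-feature catalog and 0.05/42 ≈ 1.2×10⁻³ for the default
registry.

**Composites.** score_i = (1/m) Σ β_j V_ij over the m selected features.
The available description of this construction names the symbols but not
the scaling, so the package implements the weighted mean with a
`scale = "sum"` switch; because the two differ by the constant 1/m, the
composite's regression t-statistic and p-value are identical either way
(asserted in the tests) — only the coefficient scale changes. A
participant missing any contributing V_ij gets a missing composite by
default; `renormalize = TRUE` averages over available features instead.

**Reuse caveat.** Selecting features and testing the composite on the
same sample is the procedure being reproduced, and it is anti-conservative
under the null: the weights are fit to the same noise the association is
then tested on. The package therefore also provides
`splitSampleComposite()` — selection on one random half, association on
the held-out half (each half re-normalized on its own sample, since
rank-INT is sample-relative) — whose null p-values are calibrated. The
same-sample mode remains the default because it is the published
procedure; the tests demonstrate the inflation and the split-sample fix.

**MCI models.** `logit P(MCI) ~ predictor + age + sex + education` by
IRLS, Wald SEs from the inverse observed information. Separation is
flagged when the fit classifies every observation essentially perfectly,
or when boundary fitted probabilities coincide with a per-SD coefficient
magnitude above 15 (the per-SD scaling stops rare outcomes — whose
intercepts are legitimately very negative — from being mistaken for
separation). Flagged or non-converged fits are never tabulated. The
function refuses to run below a configurable minimum of 10 events,
because Wald inference is unstable with fewer. Timed tests keep their
natural sign (positive coefficients expected), and reports annotate score
direction rather than flipping signs.

## The synthetic cohort

The generator emulates a community-based cohort of dementia-free adults:
age ~ N(62, 13²) truncated to [30, 95]; 51.6% women; education
11.1/18.7/26.7/43.4% across four levels; MCI prevalence 36/2062. A single
standard-normal latent cognition trait ties everything together:

* g = −0.5·standardize(age) + e, e ~ N(0, 1 − 0.5²): older participants
  tend to score lower.
* Test k: score = mean_k + sd_k·(±load_k·g + noise), noise SD
  √(1 − load²) so the marginal SD matches the battery catalog (means/SDs
  typical of such cohorts, e.g. Logical Memory immediate recall 12 (3),
  Trail Making B 88 (73) s). Timed tests load negatively (lower cognition
  ⇒ longer times) and are floored at 5 s; integer-scale tests are rounded
  and clipped to [0, mean + 4sd]. Default loading 0.5 for every test; 0
  gives an exact null battery.
* Drawing kinematics: radius 30 + 2g mm, pen speed 40·exp(0.15g) mm/s,
  inter-stroke pause 600·exp(−0.3g) ms, tremor SD 0.25·exp(−0.2g) mm.
  Lower g therefore means a smaller clock face, slower pen, longer
  think pauses and more tremor — the qualitative picture reported for
  impaired drawers — and these links are asserted as monotone over a g
  grid in the tests. The copy condition is 1.1× faster with
  proportionally shorter pauses (copying is less demanding than drawing
  to command).
* Idiosyncratic within-person variability: each drawing additionally
  draws log-normal multipliers on speed and pause (log-SD 0.25) and a
  N(0, 1.5²) mm perturbation of the radius. Without this, kinematics are
  a deterministic function of g, single features correlate near-perfectly
  with latent cognition, and composites *completely separate* the
  tail-defined MCI label — a degenerate regime no real cohort shows.
  The chosen SDs put single-feature correlations with g in the 0.3–0.6
  range typical of single-task cognitive measures, while composites
  remain strong proxies.
* MCI: the round(n·prevalence) lowest-g participants. This deterministic
  tail guarantees the clinical direction (older, worse scores) by
  construction; it also makes the MCI label an *exact* function of g, so
  at small n with few events composites can still legitimately separate
  it — the package flags rather than reports such fits.

A clock is drawn as: the clock-face circle starting at 12, clockwise;
twelve short two-segment number glyphs at 0.8r (legible digits are not
needed — downstream features use timing and position only); the minute
then hour hand for "ten past eleven", drawn center-outward. Paths are
sampled at exactly 1000/80 ms steps at constant pen speed, with path
vertices four per sample so polygon discretization error stays below the
pen's nominal spatial resolution. Everything is reproducible from one
master seed, with per-stage and per-drawing sub-seeds derived
deterministically (and kept below 2³¹).

**What the generator does not emulate.** Inter-feature correlation beyond
what g and the shared kinematic parameters induce; handwriting realism;
omissions, perseverations, and misplacements of clock elements; digital
(digit-display) clock drawings; pen pressure. Passing tests on this
generator therefore show that the *pipeline* is correct and calibrated —
they do not validate the features' clinical sensitivity on real drawings.

## Numerical choices and problem sizes

* Exact-fit detection: residual SS ≤ 1e-12 × max(1, Σy²).
* IRLS convergence: glm control `epsilon = 1e-10`, `maxit = 50`.
* Circle-fit degeneracy: QR rank of the 3-column design.
* Zero-variance features after complete-case restriction are excluded
  from the scan with a warning, never silently.
* The calibration suites run at deliberately reduced scale so the whole
  test suite stays fast: family-wise error of the null scan with 50
  features × n = 300 × 500 replicates; CI coverage of planted slopes
  with 1000 replicates at n = 120; pipeline byte-identity at n = 500.
  Null-calibration replicates draw feature matrices directly from the
  null (Gaussian features independent of scores) rather than rendering
  hundreds of thousands of pen drawings — with zero loadings the two are
  distributionally equivalent for the scan, and the direction/monotonicity
  checks do run the actual drawing generator.

## Known limitations

* The feature catalog is a representative subset; results on real data
  depend on the much larger proprietary catalogs.
* Same-sample composite inference is anti-conservative (see above); use
  the split-sample mode for honest null calibration.
* The MCI label is cross-sectional and synthetic; nothing here addresses
  longitudinal prediction of decline.
* Stroke classification is assumed given; drawings with unlabeled
  strokes lose the component-dependent features (they are reported
  missing).
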