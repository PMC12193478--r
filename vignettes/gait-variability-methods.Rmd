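---
title: "Gait variability from pose keypoints: models and methods"
author: "gaitvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gait variability from pose keypoints: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaitvar)
```

## The problem

Markerless, single-camera gait analysis produces per-frame skeletal
keypoints rather than calibrated kinematics. For older adults performing a
twice-repeated short walking test (the walking component of the Short
Physical Performance Battery, SPPB, here called Test 2 with trials 2.1 and
2.2), the quantity of interest is not walking speed but *gait variability*:
how much the frame-to-frame movement of each foot fluctuates within a
trial, and how that fluctuation relates to test durations and ordinal test
scores. `gaitvar` implements that analysis end to end, from keypoint JSON
streams to an annotated mixed-type correlation matrix, together with a
synthetic-data generator that emulates the statistical structure of such a
study.

## The measurement model

A trial is a `PoseSequence`: an ordered set of frames, each holding 17
keypoints `(x, y, confidence)` in pixel units. Feet are identified purely
by keypoint index — 15 is the left foot, 16 the right — never by geometry,
so a subject walking right-to-left is handled identically.

For one foot, consecutive surviving frames give the displacement series

$$d_k = \sqrt{(x_{k+1}-x_k)^2 + (y_{k+1}-y_k)^2}, \qquad k = 1, \dots, N-1,$$

and its fluctuation magnitude is the unbiased sample variance

$$\mathrm{Var}(d) = \frac{1}{N-1}\sum_{k=1}^{N-1}\left(d_k - \bar d\right)^2,$$

where $\bar d$ is the mean of the *same trial's* series. (The reference
mean is not defined elsewhere; the per-trial mean is the only reading
consistent with an unbiased within-trial estimator, and it makes the
statistic translation-invariant and scale-equivariant, both of which the
test suite asserts.)

Each subject contributes four variances — left/right foot by trial 2.1/2.2
— and the composite index averages them:

$$\mathrm{var\_mean} = \tfrac14\left(\mathrm{var15}_{2.1} +
\mathrm{var16}_{2.1} + \mathrm{var15}_{2.2} + \mathrm{var16}_{2.2}\right),$$

with per-trial means `var_mean_2_j` averaging the two feet of one trial.
These identities are enforced exactly, and a missing foot or trial is a
named error rather than a silently shrunken average.

### Confidence filtering

Real pose estimators emit low-confidence detections. `extractFootTracks()`
drops every frame in which *either* foot falls below `min_confidence`
(default 0.3), keeping the two tracks aligned in time. Dropped frames are
removed, not interpolated: the two flanking displacements merge into one
displacement across the gap, which is conservative and adds no fabricated
coordinates. Displacements that span a gap are flagged, and
`frameDisplacements(..., include_gap_spanning = FALSE)` excludes them for
sensitivity analyses. A threshold of 0 is the identity filter; fewer than
two surviving frames is an explicit error, since the displacement series
needs at least one interval and the variance at least two.

## The PCA gait index

`fitPCAIndex()` z-scores the four variance columns and eigendecomposes
their sample **correlation** matrix, keeping two components; explained
ratios are eigenvalues divided by 4. Correlation-matrix (rather than
covariance) PCA was chosen because the four features share units but not
magnitudes — trial-2 variances are often systematically smaller — and
because the symmetric $\pm 0.5$ loading pattern that motivates the
component interpretation is attainable only after standardization. A
covariance variant remains available via `standardize = FALSE`.

Eigenvector signs are arbitrary in exact arithmetic, so the package fixes
them deterministically: PC1 is oriented so its loading sum is positive (an
index that *grows* with overall gait variability), PC2 so the trial-1
loadings are positive (positive scores flag trial-1 variance exceeding
trial-2). Eigenvalue ties fall back to the same orientation rules and then
to a lexicographic rule on the loading vector, making output reproducible
across linear-algebra backends.

The interpretation step is deliberately conservative:
`interpretComponents()` labels PC1 *muscle-control reserve* only when all
four loadings share a sign, and PC2 *learning-fatigue response* only when
trial-1 and trial-2 loadings oppose; any other pattern is reported as
`unstructured` instead of forcing a narrative onto an arbitrary rotation.

A useful analytic anchor: if the sample correlation matrix is
block-exchangeable — within-trial left-right correlation $a$, all
cross-trial correlations $b$ — the foot-swap and trial-swap symmetries
force the leading eigenvectors to $(1,1,1,1)/2$ and $(1,1,-1,-1)/2$ with
eigenvalues $1+a+2b$ and $1+a-2b$. `blockExchangeableCorrelation()`
constructs such matrices and `simulateFeatureMatrix()` can generate data
whose *sample* correlation hits them exactly (empirical whitening followed
by recoloring), which is how the test suite pins the loadings to 0.5 at
tolerance 1e-6 rather than "approximately".

## The mixed-type correlation engine

Variables are classified as binary (two observed values, e.g. gender),
ordinal (integer-valued with at most 6 levels by default, e.g. SPPB
scores), or continuous; explicit overrides always win, and constant
columns are excluded with a warning. The coefficient per pair follows the
kind table:

| pair | method |
|---|---|
| binary × binary | undefined default (blank cell) |
| binary × ordinal/continuous | point-biserial (Pearson on 0/1) |
| ordinal × ordinal | Kendall's τ-b |
| continuous × continuous | Pearson |
| ordinal × continuous | Spearman |

Decisions worth recording:

* **Binary × binary** returns a *missing* coefficient rendered blank, not a
  numeric default: inventing a number would fabricate an association the
  methods cannot support.
* **Kendall τ-b** (tie-corrected) is used because SPPB scores tie heavily;
  the untied τ variants would be biased toward zero.
* **Ordinal preprocessing** converts to midranks and z-scores. This leaves
  the rank-based coefficients untouched (they are invariant to monotone
  transforms) while giving downstream consumers standardized columns.
* **LOWESS smoothing** of continuous variables (span `f = 0.5` against
  subject presentation order) is implemented via `stats::lowess()` but is
  **off by default**: pre-smoothing alters the sampling distribution of
  classical coefficients, and the choice of abscissa is not part of any
  standard definition. It is exposed as an option (`smooth = TRUE`) so its
  effect can be studied; printed coefficients from analyses that used such
  smoothing may not be exactly recoverable without knowing the abscissa and
  span.
* **p-values** are classical two-sided forms via `stats::cor.test()`; for
  fewer than 10 paired observations the exact small-sample distributions of
  the rank coefficients are requested where ties permit.
* **FDR family**: all off-diagonal pairs of one reported matrix form a
  single Benjamini–Hochberg family (`stats::p.adjust`, method `"BH"`), and
  the significance stars (`*` < 0.05, `**` < 0.01, `***` < 0.001) are
  computed from the *adjusted* p-values — the conservative reading when the
  starring convention is unstated.

Coefficients are rendered to two decimals rounding half away from zero
(−0.955 → "−0.96"), matching the usual heatmap annotation style;
percentages in the baseline report round the same way to one decimal.

## The synthetic-data generator

No keypoint data are publicly deposited for studies of this kind, so the
generator is a first-class, tested module rather than a fixture. It is the
package's definition of the study conditions.

**Walk model.** Each foot advances along the image x-axis with per-frame
step

$$s_k = \mu + \tau (k-1) + \sigma\, m_k\, z_k, \qquad
m_k = 1 + A \sin\!\left(2\pi\left(\tfrac{k}{P} + \phi\right)\right),
\quad z_k \sim N(0,1),$$

with step mean $\mu$ (`step_mean`, default 8 px/frame), linear stride trend
$\tau$ (`trend`, default 0 — individuals show gradually increasing or
decreasing stride length, so the sign is configurable), noise SD $\sigma$
(`step_sd`, default 2 px), gait-cycle period $P$ (30 frames) and
modulation amplitude $A$ (0.5). The sinusoidal gait phase modulates the
*noise envelope* rather than the mean step: stochastic gait adjustments
wax and wane over the cycle, the two feet are offset by
`foot_phase_offset` (default 0.5, anti-phase), and — crucially — a
zero-noise configuration produces an exactly constant-step walk, so the
pipeline's displacement variance is exactly zero, a property the tests
assert without tolerance. Modulating the mean step instead would break
that degenerate case. The right foot's mean, trend and SD are multiplied
by `lr_asymmetry`. Non-foot keypoints are filled by rigid torso
interpolation above the feet midline; dropout frames receive one foot
keypoint with confidence below 0.3. Units are arbitrary pixels per frame
throughout — the analysis is unit-free, so no frame rate or pixel
calibration is assumed.

**Cohort model.** Subjects draw demographics from configurable ranges
(defaults: ages 60–90, 79% male, heights 145–180 cm, weights 40–90 kg,
emulating a small community-dwelling elderly cohort) and per-subject walk
parameters, chiefly `step_sd` from `step_sd_range` (1–4 px), which is what
spreads var_mean across subjects. The two trial pose sequences are
actually generated and pushed through the real feature pipeline; per-trial
durations then follow the linear link

$$\mathrm{duration}_j = \alpha + \beta\,\mathrm{var\_mean}_{2_j} +
\varepsilon_j, \qquad \varepsilon_j \sim N(0, \sigma_\varepsilon^2),$$

with baseline $\alpha$ = 12 s, coupling $\beta$ = −0.4 s/px² and residual
SD `noise_sd` = 0.5 s by default. Linearity is the minimal assumption
consistent with reporting only signed correlations. Total duration is the
sum of the two trials, which makes the population correlation between
var_mean and total duration

$$\rho = \frac{2\beta\sigma_{vm}}
{\sqrt{4\beta^2\sigma_{vm}^2 + 2\sigma_\varepsilon^2}},$$

available in closed form (`analyticDurationCorrelation()`), with
`calibrateNoiseSD()` as its inverse — the route the tests use to build
cohorts with an analytic $\rho = -0.9$ and check recovery within ±0.05
over replicate seeds. With `noise_sd = 0` the link is exactly linear and
the recovered Pearson coefficient is −1 to machine precision.

**Scores.** Per-trial ordinal scores map duration through SPPB-style 4-m
gait-speed cutpoints (4.82 / 6.21 / 8.70 s → scores 4/3/2/1, configurable);
the overall Test-2 score is the better (maximum) of the two trials, the
SPPB convention, and the defaults make simulated scores span the scale.

**What the generator does not emulate.** Real pose-estimator error is
neither Gaussian nor independent across frames (jitter is autocorrelated,
occlusion errors are structured); real gait has kinematic constraints
between keypoints; real cohorts have demographic–gait dependence (age and
var_mean are independent here). Passing tests therefore demonstrate that
the *pipeline* computes its statistics correctly and recovers known
couplings — not that the statistics capture real fall risk.

## Baseline reporting and the pipeline

`summarizeBaseline()` uses the reporting bins: age 60–80 vs over 80 years
(80 assigned to the lower bin, since the printed bins otherwise overlap at
80), height 145–155/155–165/165–175/≥175 cm, weight 40–50/50–60/60–70/≥85
kg. The weight bins deliberately leave a 70–85 kg gap; any record outside
all bins lands in an explicit `unbinned` row rather than vanishing.
`duration` is defined as `duration1 + duration2`, the only reading under
which the three duration variables coexist coherently.

`runPipeline()` chains simulation (or JSON+CSV loading), features, PCA,
correlations and baseline summaries, writing CSV artifacts, a log and a
`manifest.json` with MD5 checksums. No artifact carries a timestamp, so a
rerun under the same seed is bit-identical — the determinism the test
suite checks byte for byte.

## Numerical choices and problem sizes

Variance uses `stats::var` (checked against an independent two-pass oracle
at 1e-12 relative over a thousand random series); eigendecomposition uses
`eigen(symmetric = TRUE)` (checked against a hand-written power-iteration
oracle); BH uses `stats::p.adjust` (checked against a from-definition
step-up). Default test problem sizes — trials of 150 frames, cohorts of
200 subjects for recovery checks, 20 replicate seeds, a 50-subject ×
500-frame cohort for the determinism check — keep the whole suite under a
minute while leaving Monte-Carlo error far inside the asserted tolerances.

## Known limitations

* Displacement mixes both image axes; camera motion or perspective change
  would inflate variance. The analysis assumes a static camera.
* The variance statistic is sensitive to dropped-frame gap merging when
  dropout is heavy; the `include_gap_spanning` switch exists to quantify
  that sensitivity.
* Component *labels* are a sign-pattern heuristic, not a biomechanical
  identification.
* With 17-point skeletons the "foot" is an ankle-region landmark; true
  heel/toe dynamics are invisible.
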