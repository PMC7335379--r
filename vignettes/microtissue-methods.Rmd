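---
title: "Quantifying micro-tissue remodeling: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying micro-tissue remodeling: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microtissue)
```

## The assay and what this package computes

Tendon-derived cells seeded in a collagen-I gel compact the gel around an
array of constraining micro-posts.  Releasing the outermost posts triggers a
remodeling response; over the following 48 h the tissue compacts further and
occasionally detaches from the remaining posts entirely.  The assay's
read-outs per tendon sample are:

* **relative surface area at 48 h** — the top-view silhouette area at 48 h
  as a percentage of the area at 0 h, measured from hourly brightfield
  frames or from a 0 h / 48 h endpoint pair;
* **intact vs released** — whether the tissue stayed anchored to the
  remaining posts;
* **protein read-outs** from band densitometry: pro-collagen I
  (concentration from ELISA), tenomodulin (37 kDa) and alpha-smooth-muscle
  actin (42 kDa) normalized to tubulin (50-55 kDa) on Western blots, and
  active (62 kDa) vs latent (72 kDa) MMP2 on gelatin zymographs, summarized
  as the *active fraction* active/(active + latent).

Each read-out is then regressed on patient age, gender (male = 1) and tendon
type (semitendinosus = 1): ordinary least squares for continuous read-outs,
a logistic GLM for intact/released.

Because no imaging or cohort data from such studies are publicly deposited,
the package carries a first-class synthetic-data layer that emulates the
cohort structure, the microscopy frames and the gel images, with ground
truth attached, so that every downstream stage is testable end to end.

## Silhouette segmentation

Strategy A thresholds the frame at a grey value, keeps the largest connected
component and fills its interior holes; the pixel count times the pixel area
gives the absolute silhouette area.  Strategy B is the fallback for frames
whose absolute intensities do not isolate the silhouette: a 3x3
gradient-magnitude (Sobel) edge map is binarized, scaled to the frame
maximum and subtracted from the original (clamped at zero), which stamps the
silhouette boundary to zero; binarizing the residual recovers the boundary
ring, and hole filling turns it into the silhouette.

Design choices where the method description leaves room:

* **Threshold selection.** Automatic between-class-variance maximization
  (Otsu's criterion) over a 256-bin histogram built on the frame's own
  range, with a fixed-value override.  Building the histogram on the frame's
  range makes the selected partition invariant under positive affine
  intensity rescaling, which the test suite asserts.
* **Edge operator.** A 3x3 Sobel gradient magnitude, the behaviour of the
  common "find edges" default in image-analysis tools.
* **Strategy B's second binarization.** After subtracting the full-scale
  edge mask and clamping at zero, boundary pixels sit exactly at zero, so
  the residual image is thresholded at a small fraction (2%) of its maximum
  rather than by a histogram criterion: on shaded frames the histogram
  criterion preferentially splits the illumination ramp, not the ring.
* **Connectivity.** 8-connectivity for foreground components,
  4-connectivity for background hole identification; ties between
  equal-sized components resolve to the one containing the smallest
  row-major pixel index.
* **Fallback heuristics.** Strategy A's result is rejected (triggering B)
  when the mask covers less than 0.5% or more than 80% of the frame, misses
  a central region of interest covering half of each dimension, occupies
  more than 5% of the image border, or when auto-thresholding is degenerate.
  These are declared operational substitutes: the original procedure's
  criterion for "insufficient" intensities was a human judgement.

On the synthetic battery (6-10 scenes of 49 frames per condition, 256 x 320
px at 12 um/px), strategy A's median area error on evenly illuminated frames
is about 0.03% and strategy B's on strongly shaded frames (gradient 0.6 of
full scale) about 3.3%; the fallback selects B on every shaded frame and
never on a clean one.  These are the numbers the acceptance script
recomputes.

## Compaction read-outs

The relative area is `100 * A(48 h) / A(0 h)` with endpoint frames matched
within +/- 1 h (hourly sampling makes a tighter match meaningless).  Areas
are compared in mm^2, never in raw pixels, because the 0 h and 48 h frames
may come from different microscopes with different pixel sizes.

Release detection operationalizes what was a human observation: a tissue is
*released* at the first frame whose silhouette overlaps fewer than two
anchored post regions, sustained for two consecutive frames (partial
detachment from a single post can precede full release); for a 2-frame
endpoint series, detachment at the final frame suffices.  Detachment already
present at 0 h is reported as released at time 0 with a `pre-release` flag
rather than a negative time.  On a 50-scene battery with programmed
releases, classification is 100% correct and estimated release times fall
within one frame interval of the programmed times.

## Densitometry

Band quantification uses a two-stage subtractive background correction,
chosen as the standard reading of "normalized to global and local
background": the per-pixel global background (median intensity outside all
lane windows) is subtracted from the oriented image, then the band's summed
window intensity is corrected by the per-pixel local background times the
window pixel count.  The local background is the *smaller* of the two
one-sided medians over rows flanking the window: active and latent MMP2 sit
only ~21 rows apart at the default migration calibration, and a neighbouring
band bleeding into one flank must not inflate the estimate.  Corrected
intensities clamp at zero and carry a `below-detection` flag when they do
not rise above the flanking noise floor (3 x MAD x sqrt(window size)); the
MMP9 window (92 kDa) is computed but expected below detection.

Band windows span the migration positions of the target weight +/- 3
kDa-equivalents; tubulin's 50-55 kDa doublet is treated as a single window
spanning both bounds.  Polarity (bright-on-dark for chemiluminescent blots
and cleared zymograph bands, dark-on-light for stained gels) is always
explicit, never inferred.  The "quantile" in the loading-control outlier
definition is read as *quartile*: Tukey fences at Q1 - 1.5 IQR and
Q3 + 1.5 IQR with type-7 interpolated quartiles, and flagged samples are
annotated, not removed — exclusion is a reporting choice, so the regression
layer reports pro-collagen fits both with and without flagged samples.

Measured on rendered gels, corrected intensity is linear in programmed
amount over three decades (R^2 > 0.999), invariant to an additive global
background to well under 1%, shifted by under 5% by a rendered linear
gradient, and recovers programmed active fractions within 0.005.

## The regression layer

Continuous read-outs: OLS with intercept on age, gender, tendon type;
two-sided t-tests; multiple R^2.  Intact/released: maximum-likelihood logit
(IRLS, coefficient tolerance 1e-8, at most 100 iterations), Wald tests, and
McFadden's pseudo-R^2 (1 - l(model)/l(intercept-only)) — the most common
default among the several pseudo-R^2 flavours; the flavour is recorded in
the output.  Perfect separation is detected (divergence warning plus
standardized coefficient magnitude) and refused with a diagnostic rather
than reported.  Intact is coded 1, so a positive age coefficient means
older patients' tissues stay attached.  Rank-deficient designs are refused
with the collinear columns named.  No multiple-testing correction is
applied; alpha = 0.05 per test is recorded in the result objects.  Patients
contributing two tendons contribute two rows; no patient-level random
effect is fitted, which is a known limitation of the tendon-level analysis.
Normality diagnostics are quantile-comparison pairs (order statistics vs
`qnorm((i - 0.5)/n)`) with the probability-plot correlation as a scalar
summary.

## The synthetic-data layer

**Cohort.** Defaults emulate a 36-patient / 41-tendon census: ages
averaging 27.9 y (sd 12.9) within 12-55 y, 20/36 male, 30/41 semitendinosus
tendons, 5/36 patients contributing both tendon types (the second tendon is
always the other type and shares age and gender).  Ages are drawn from a
truncated normal clipped to the age range, with one deliberate subtlety:
the requested mean/sd are treated as *targets for the truncated
distribution*, and the parent normal's parameters are solved by moment
matching.  Parameterizing the parent directly at (27.9, 12.9) would yield
truncated moments near (30.0, 10.0) — visibly narrower and older than the
target census.  Even with moment matching a truncated normal cannot hit the
target pair exactly (best attainable is about (28.2, 11.7)); the residual
mismatch is accepted and asserted within +/- 1.5 y in the tests.  First-tendon
P(semitendinosus) defaults to 25/31 so that the *tendon-level* census is
30/41 in expectation.

**Effect structure.**  The generative model is the inverse of the inference
layer:

* relative area: `28 + 0.96 * age + noise` (sd 20%).  The intercept is
  invented — the observed mean level is not published — and set so that mean
  relative areas sit near 55% at the cohort's mean age; the noise sd is set
  so the age effect explains roughly a fifth of the variance, matching the
  published fit quality.  Gender/tendon effects default to 0 (none were
  detected) but are configurable.
* pro-collagen: a smoothed 5-fold step (logistic in age, width 2 y) centred
  at 25 y, plus additive assay noise (sd 100 ng/ml), clamped at zero.  The
  plateau scale is solved numerically so that the *expected linear age
  slope, fitted over intact tendons only* (intact-probability-weighted age
  distribution, clamping accounted for in closed form), equals -15 ng/ml
  per year; with the 5-fold ratio fixed this pins both plateaus (about
  122 / 610 ng/ml).  A Gaussian with the scatter implied by the published
  standard error would put a third of concentrations below zero, so the
  noise sd is chosen for physical plausibility and the slope — the reported
  quantity — is what the calibration pins.
* intact/released: Bernoulli with log-odds
  `b0 + 0.19 age + 1.6 male - 2.7 semitendinosus` (intact = 1).  The
  intercept is not published; `b0` is solved by numerical integration over
  the cohort's age density and covariate class probabilities so the
  expected release rate equals 10/41 (about -1.92 at defaults).  Released
  tendons draw a release time uniform on 2-37 h (the observed span) and
  carry missing biochemical read-outs, mirroring the exclusion of released
  micro-tissues from further processing.
* blot ratios: age-independent lognormals (alpha-SMA sdlog 0.8, spanning
  the observed ~20-fold range; tenomodulin centred at a deliberately low
  0.03); active MMP2 intensity `30 - 0.17 age + noise` (sd 9.7, chosen to
  match the published uncertainty and fit quality); MMP2 active fraction
  Gaussian (0.35, 0.05) clipped to the unit interval.
* loading control: lognormal tubulin intensities with a 10% chance of a
  0.35x degraded lysate — the low-side outliers the Tukey rule is meant to
  flag (only below-average outliers were observed in practice).

With these defaults and n = 500 tendons, the fitted age coefficients'
95% confidence intervals cover the generating values (0.96, -15, 0.19) in
well over 90 of 100 seeded replicates, and at the study's census (about 41
tendons) the age effect on relative area reaches p < 0.05 in a majority of
replicates.

**Scenes.**  Frames are 256 x 320 px at 12 um/px (a 3.1 x 3.8 mm field).
The silhouette is a smooth star-convex blob (ellipse base with low-order
harmonic perturbations, seeded per scene) whose area follows the
phenomenological decay `A(t) = plateau + (initial - plateau) exp(-rate t)`
(defaults 4.0 to 1.6 mm^2, rate 0.08/h, 49 hourly frames); its aspect ratio
grows with compaction progress, rendering the anisotropy increase, though
only area is a measured output.  The post count and layout are not published
(the platform schematic is not dimensioned): the default is a 2 x 4 array
whose four corner posts are the "outermost" released at t = 0, with the
tissue anchored to the four inner posts.  After a programmed release the
tissue is drawn as a small detached elongated blob overlapping no post.
Ground truth is emitted per frame as the silhouette mask, the mask-derived
area (pixel count x pixel area, exactly) and the closed-form model area.
Tissue is darker than background (brightfield); illumination shading is an
additive linear ramp, and noise is additive Gaussian.

**Gels.**  Bands are Gaussian bumps along the migration axis (row =
intercept + slope log kDa), flat across the lane with raised-cosine
shoulders, with integrated magnitude exactly proportional to the programmed
amount; one renderer serves blots and zymographs via the polarity flag.

**What the generator does not emulate.**  No mechanistic biophysics (no
force balance or cell-level simulation — the decay law is phenomenological);
no ELISA plate rendering (concentrations are simulated directly); no
texture, debris, vignetting or focus drift in the microscopy frames; no
band smearing, lane curvature or saturation in the gels.  Passing tests
therefore demonstrate correctness of the measurement pipeline on idealized
but controlled inputs, not robustness to every real-world artefact.

## Numerical choices and problem sizes

Segmentation batteries use 6-10 scenes x 49 frames per condition; release
batteries 20-50 scenes; recovery studies 100 replicates of ~500 tendons;
the demonstration pipeline runs the full census with 2-frame endpoint
imaging per tendon.  These sizes give stable medians and coverage counts
while keeping a complete run in the minutes range on a single core.  All
generators are pure functions of their parameters and an explicit integer
seed; stage seeds are derived deterministically from one master seed, and
the demonstration pipeline's tabular outputs are byte-identical across
reruns.

## Known limitations

* The fallback heuristics and the release rule are declared
  operationalizations, not reconstructions of the original (manual)
  judgements.
* The truncated-normal age model cannot reproduce the target census moments
  exactly (see above); a skewed or bimodal model could, but would replace a
  stated modelling choice rather than refine it.
* The endpoint (2-frame) imaging path cannot time releases better than "by
  48 h", and extreme compaction can be indistinguishable from detachment in
  a single final frame.
* Tendon-level regressions ignore the correlation between two tendons of
  the same patient.
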