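---
title: "Detecting and lateralizing hippocampal sclerosis from surface morphometry: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and lateralizing hippocampal sclerosis from surface morphometry: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the statistical
pipeline, the assumptions behind each stage, the choices we made where the
design was genuinely open, and what the synthetic-cohort tests do and do not
demonstrate about real data.

## Inputs and data model

The pipeline consumes what a hippocampal surface segmentation tool produces:
per-vertex thickness (mm), gyrification (unitless ratio of native to
unfolded surface area), mean curvature (mm⁻¹) and intrinsic curvature
(mm⁻²) on a fixed-topology mid-thickness mesh with an anterior–posterior
coordinate in [0, 1]; a total volume (mm³) per hemisphere; and a Dice
overlap score per segmentation. Demographics carry subject id, site, group
(HS patient / disease control / healthy control), lateralization, age
(decimal years, > 3 by inclusion rule), sex, and optional clinical flags.
Metric files are accepted as GIFTI (ASCII, Base64 or gzipped Base64
encodings) or as a single wide CSV; both map to the same internal
representation.

Subjects whose worse-hemisphere Dice falls strictly below 0.7 are excluded
automatically, with an `override` argument standing in for the manual visual
review a human pipeline would apply. A score of exactly 0.7 is retained: the
rule is "below threshold", and we treat the boundary as passing.

## Vertex preprocessing

**Outlier replacement.** Vertices outside 5 SD of the field's mean are
replaced by the mean of their non-outlier 1-ring neighbours; if the whole
1-ring is flagged, the nearest non-outlier vertices by breadth-first search
are used. Mean and SD are recomputed after each sweep, and the loop stops
when nothing is flagged or after 10 sweeps (then with a warning). The
1-ring/BFS definition is ours: "neighbours" is otherwise underdetermined on
a mesh, and the bounded loop guarantees termination. A constant field has
zero SD and is returned unchanged. Note that with n vertices a single
spike can raise the sample SD enough to hide itself when n is small
(max attainable z is (n−1)/√n), which is why the replacement operates on
whole surfaces, not tiny patches.

**Smoothing.** The 1 mm FWHM Gaussian smoothing is implemented as iterated
1-ring neighbour-weighted averaging: one sweep applies row-normalized
weights `exp(−d²/2σ_step²)` over mesh edges (self-distance 0). Rows sum to
1, so constant fields are preserved exactly and the operator is linear.
Calibration has two steps: the sweep count is chosen with the per-sweep
bandwidth pinned near 0.55× the mean edge length, then the bandwidth is
fine-solved (uniroot) so the composite kernel's radial second moment equals
`2σ²` with `σ = FWHM/2.3548`. The pin matters: a heavily truncated 1-ring
step composes toward a compound-Poisson kernel rather than a Gaussian, so
matching the second moment alone is not enough. On a uniform 0.5 mm grid the
impulse response matches a dense Gaussian on mesh distances to within 10%
out to 2σ for FWHM around the pipeline's 1 mm setting; substantially larger
FWHM on coarse, anisotropically triangulated meshes accumulates
direction-dependent error and is a known limitation (the pipeline never uses
such settings).

**Averaging.** Each feature is averaged over vertices whose
anterior–posterior coordinate lies in the central [0.01, 0.99] quantile
band, dropping the highly variable head and tail extremes. Trimming is by
coordinate quantile, not vertex rank, so it is mesh-resolution independent.
The whole surface contributes (no subfield masks: subfield labels are not
part of the inputs). Volume passes through untouched. The fixed order is
outliers → smoothing → trimmed mean.

## Harmonization

Per-hemisphere features from multiple scanners are harmonized with
parametric empirical-Bayes location/scale adjustment (ComBat): per feature
column, a linear model with site indicators plus protected covariates (age,
sex, and two disease-status dummies — patient and disease-control against a
healthy reference) is fit; data are standardized by the covariate-adjusted
mean and pooled residual SD; per-site locations and scales are shrunk with
normal / inverse-gamma priors via the standard iterative moment-matched
solution; and covariate effects are added back. We implement this
in-package, rather than delegating, because downstream cross-validation
needs a *stored* model applicable to new rows; the implementation is
cross-checked against `sva::ComBat` in the test suite. Hemispheres enter as
separate columns (5 features × 2 hemispheres), preserving within-subject
pairing. Constant covariate columns (e.g. the patient dummy in an
all-control cohort) are dropped before fitting.

Applying a stored model to rows from a *training* site is deterministic and
reproduces the training output exactly. Rows from an unseen site are
handled by policy: error (default), `"passthrough"` (warn, leave
unadjusted — the documented fall-back, since the pipeline is validated with
and without harmonization), or `"estimate"` — estimate that site's
location/scale from its own rows under the stored standardization model,
with the same empirical-Bayes shrinkage. Estimation needs at least
`min_site_n` rows (default 20, matching the practical minimum for stable
per-scanner estimates). Cross-validation uses `"estimate"`: the fold model
contains nothing from the held-out site; the held-out site's own data are,
unavoidably and legitimately, used to place it on the common scale.

Harmonization requires ≥ 2 sites and ≥ `min_site_n` subjects per site;
single-site runs use the identity (`skip_combat()`), and a fold whose
training data collapse to one site does the same.

## Asymmetry and normalization

Each feature is summarized by the left-referenced asymmetry index
`AI = 2(l − r)/(l + r)`: zero under symmetry, antisymmetric under
hemisphere exchange, bounded in (−2, 2) for positive features. One vector
per subject suffices; the right hippocampus is characterized by the
negation. Asymmetries are z-scored by the mean and SD of *healthy* controls
only (disease controls excluded), so typical anatomical asymmetry maps to
z ≈ 0 and the reference sample self-normalizes to mean 0 / SD 1 exactly.
The statistics are serialized with the model; within cross-validation they
are re-estimated per training fold, after harmonization — the natural order,
since the normalization should describe harmonized features.

## Normative growth charts

Per feature and sex, a penalized cubic-spline GAM (`mgcv`, basis dimension
5, REML smoothing selection) of the harmonized feature against age is fit on
healthy controls, with both hemispheres contributing observations. Centiles
follow a Gaussian location model: `curve_p(age) = μ̂(age) + z_p·σ̂` with a
constant per-chart residual SD, and an individual's percentile is
`100·Φ((value − μ̂)/σ̂)`, clipped to (0.1, 99.9) for display. We chose the
Gaussian location model over quantile regression as the minimal model
consistent with "a GAM accounting for age and sex": it is parsimonious for
the small control cohorts this tool sees, and every centile statement it
makes is testable (ordering, the 2·1.645·σ̂ gap between the 5th and 95th
curves, calibration of held-out exceedance fractions). Separate smooths per
sex (rather than an additive sex offset) match the visibly different male
and female trajectories. Hemispheres are pooled because the charts describe
a hippocampus, not a side; the small hemisphere offsets that exist are
absorbed into σ̂. An intracranial-volume covariate is deliberately not
included (it showed no systematic improvement in the source analyses);
basis dimension 5 reflects the monotone rise-and-plateau shape of
hippocampal maturation. Evaluation outside the fitted age range is flagged
as extrapolation. Serialization stores the mean curve sampled on a fine age
grid plus σ̂ — everything centile evaluation needs — instead of spline
bases; a reloaded model reproduces percentiles to interpolation accuracy
(~10⁻⁶ here).

## Classifier

The classifier is multinomial logistic regression from the five normalized
asymmetries to {left HS, right HS, no HS}, with balanced class weights
`w = n/(K·n_class)` and weak L2 regularization (strength 1.0, disableable)
on the non-intercept coefficients. We minimize the convex objective with
L-BFGS from a zero start and analytic gradients, making the fit bit-for-bit
deterministic given the data — a property the leakage audit tests rely on,
and the reason we did not call `nnet::multinom` (random initial weights);
`nnet` instead serves as the independent cross-check. Disease controls train
as "no HS": the tool's job is to distinguish HS from both healthy anatomy
and other pathology. Bilateral HS patients never train; they pass through
prediction and reporting only.

Decisions: detection is `noHS` iff `S_noHS ≥ max(S_LHS, S_RHS)` (ties go
conservatively to no-HS); lateralization is `left` iff `S_LHS ≥ S_RHS`
(ties to left, with a warning) and is defined for every subject regardless
of detection, since a lateralization opinion is clinically useful even for
borderline detections.

Cross-validation is leave-one-site-out: per fold, harmonization, control
statistics and classifier are refit on the training sites only, and every
subject receives exactly one out-of-fold prediction. The fold models are
ensembled by averaging probability vectors (renormalized); averaging is the
minimal convention among the unstated alternatives (voting, coefficient
averaging) and is invariance-tested (identical folds ≡ one fold). Each fold
carries its own harmonization and normalization state and applies it to new
data before scoring.

Per-feature abnormality thresholds are the probability-0.5 boundaries
(−intercept/slope) of univariate logistic fits separating each side's
patients from all controls. Under complete separation the boundary is still
reported but flagged; a zero slope leaves the threshold undefined and
flagged. A volume-only baseline (raw left/right volumes, or the normalized
volume asymmetry) reuses the same classifier configuration and fold
partition for comparison runs.

## Evaluation

Detection sensitivity is the fraction of unilateral HS patients decided HS;
lateralization sensitivity the fraction with the correct side (all
patients); specificity the fraction of controls decided no-HS. Stratified
breakdowns (age at an 18-year adult cut, sex, MRI status, histology,
outcome, scan isotropy) come with multivariable logistic regressions of
correctness on the factors; complete separation is reported as fitted and
flagged rather than suppressed. Group comparisons of ipsilateral-referenced
normalized asymmetries (controls contribute a seeded random hemisphere,
i.e. a random sign) use a Shapiro–Wilk gate at p < 0.05 per group pair to
choose Welch t or Mann–Whitney, with Holm correction across all feature ×
pair tests. Contingency statistics use Pearson chi-square without continuity
correction.

## Synthetic cohorts: what they emulate, and what passing tests show

The generator produces, per subject and hemisphere, a feature scalar
`trajectory(age) + sex offset + hemisphere offset + site shift + subject
effect + hemisphere noise`, scaled by a per-site factor; vertex fields add a
fixed anterior–posterior pattern, spatially smoothed noise and sparse
outlier spikes; Dice scores are high-valued with injected failures. Age
trajectories use a monotone saturating form `a + b(1 − e^{−age/τ})`
mimicking childhood rise and adult plateau. Sex offsets sit on volume,
thickness and mean curvature; hemisphere offsets on gyrification and
intrinsic curvature — the features that show such effects in healthy
cohorts. Magnitudes are plausible adult scales (volume ≈ 3000 mm³,
thickness ≈ 1.6 mm, gyrification ≈ 3) and are otherwise arbitrary.

Defaults define the reference study conditions: 4 sites × (50 left HS, 50
right HS, 50 healthy, 50 disease controls), ages uniform on 4–60 years,
55% female, site shifts of 0/+5/−4/+2% of each feature's adult scale with
scales 1/1.08/0.95/1.02, a 24×12 surface grid at 0.5 mm spacing. The
ipsilateral HS multipliers (volume 0.82, thickness 0.90, gyrification 0.86,
mean curvature 1.16, intrinsic curvature 1.17) were derived once,
analytically, so that the fraction of ipsilateral hippocampi breaching the
healthy 5th/95th centiles matches the prevalences reported in surgical HS
cohorts (≈ 90% volume, 63% thickness, 88% gyrification, 67% and 70% for the
curvatures): with a multiplier m, a control coefficient of variation c and
the 5th-centile cut at z₀ = 1.645, the breach probability is approximately
`Φ(((1 − z₀·c) − m) / (m·c))`, which we inverted per feature to hit the
target rate. The test suite verifies the realized rates.

Passing the end-to-end tests shows the pipeline's plumbing, contracts and
statistical calibration are right under a generating model it was *not*
fitted to — fold models never see their test site; normative charts are
checked on held-out controls. It does not show clinical performance: real
hippocampi have spatially structured pathology, heavier-tailed asymmetry
distributions, correlated features, scanner effects that are not purely
location/scale, and label noise. On the synthetic cohort the normalized
asymmetries separate the classes almost completely (the classifier scores
near 100% in cross-validation); the reported clinical numbers of the method
this package implements are lower, and the synthetic result should be read
as "the machinery is lossless", not "the problem is easy". Conversely the
null-cohort test (all effects off) verifies the pipeline invents nothing:
detection in patients tracks the false-positive rate in controls and
left/right decisions are binomially balanced.

## Numerical choices and degenerate inputs

* Classifier: L-BFGS, `factr = 1e7` (≈ 2×10⁻⁹ relative tolerance), max
  1000 iterations, zero initialization; softmax computed with row-max
  subtraction; log-probabilities floored at 1e−300.
* ComBat EB iteration: relative-change convergence at 1e−4 (the reference
  implementation's default), max 500 iterations.
* Exact ties in the decision rules are resolved as documented above and
  exercised in tests.
* Degenerate inputs error early with typed conditions: all-outlier fields,
  empty trimmed sets, non-positive asymmetry denominators, zero
  healthy-control SD, zero-variance feature columns, missing classes,
  unseen sites, rank-deficient regression designs, zero contingency
  marginals.
* Problem sizes in the checks: the end-to-end and null experiments use the
  full 800-subject reference cohort on the default 24×12 grid; the
  normative-calibration experiment uses 500 training and 1000 held-out
  controls on a 10×5 grid (chart calibration is a feature-level property,
  so mesh resolution is immaterial there); unit tests use smaller meshes
  and cohorts.

## Known limitations

* Bilateral HS is not classified (no training class); reports still
  characterize both hemispheres.
* The Gaussian centile model cannot express age-varying spread or skew; a
  GAMLSS-style model would, at the cost of much larger control cohorts.
* Harmonizing a new site needs ~20 subjects from that scanner; smaller
  sites run unharmonized (supported, but centile placement is then less
  comparable).
* The smoothing kernel is calibrated for FWHM near the mesh edge length;
  very large FWHM on coarse meshes is inaccurate (and unused).
* Synthetic cohorts are a calibration instrument, not a validation cohort;
  see above.
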