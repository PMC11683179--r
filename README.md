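# aidhs

Automated and interpretable detection and lateralization of hippocampal
sclerosis (HS) from hippocampal surface-based morphometry.

## The problem

HS is the commonest pathology in temporal lobe epilepsy and is surgically
treatable, but its MRI signature — atrophy and morphological change of one
hippocampus — can be subtle enough that a substantial fraction of
histologically confirmed cases are reported as MRI-negative. Surface
segmentation tools (such as HippUnfold) fit a mesh to each hippocampus and
measure, at every vertex, cortical thickness, gyrification (the ratio of
native to unfolded surface area), and mean and intrinsic curvature, plus a
total volume per hemisphere and a Dice quality score per segmentation. This
package takes those outputs — not the MRI itself — and turns them into a
detection/lateralization decision and a clinician-readable report.

## The method

For each subject and hemisphere the per-vertex features are cleaned
(vertices beyond 5 SD iteratively replaced by neighbour means), smoothed
(1 mm FWHM geodesic Gaussian), and averaged over the surface excluding 1% of
vertices at each anterior–posterior extreme, giving five scalars per
hippocampus: volume, thickness, gyrification, mean curvature, intrinsic
curvature. Multi-site batch effects are removed by empirical-Bayes
location/scale harmonization (ComBat) that preserves age, sex and
disease-status covariates. Each feature is then summarized within-subject by
a left-referenced asymmetry index

    AI = 2 (left − right) / (left + right)

which is z-scored against the healthy-control asymmetry distribution. A
multinomial logistic classifier with balanced class weights maps the five
normalized asymmetries to scores `[S_LHS, S_RHS, S_noHS]` (summing to 1);
detection is `HS` when `max(S_LHS, S_RHS) > S_noHS` and lateralization is
`argmax(S_LHS, S_RHS)`. Training uses leave-one-site-out cross-validation —
harmonization, normalization and classifier are refit per fold — and the
fold models are ensembled (averaged probabilities) for new data. Normative
growth charts (penalized-spline GAM of each feature against age, per sex,
fit on healthy controls, Gaussian centiles) place each hippocampus on a
percentile; univariate logistic thresholds on each asymmetry axis mark
left/right abnormality. All of this feeds an individual HTML/JSON report.

Because no imaging cohort ships with the package, a seeded synthetic
generator (`simulate_cohort()`) emulates segmentation-tool outputs — age/sex
trajectories, hemispheric offsets, site batch effects, spatially smooth
vertex noise, and ipsilateral HS effects (volume, thickness, gyrification
reduced; curvatures increased) — so the entire pipeline is testable
end-to-end.

## Worked example

```r
library(aidhs)

cfg    <- sim_config(n_left_hs = 8, n_right_hs = 8, n_healthy = 12,
                     n_disease = 8, grid_n_ap = 12, grid_n_pd = 6, seed = 42)
cohort <- simulate_cohort(cfg)
cohort
#> <aidhs_cohort> 144 subjects across 4 sites (disease_control: 32,
#>   healthy_control: 48, patient_HS: 64); 72-vertex surface

model <- aidhs_train(cohort, min_site_n = 10)
model
#> <aidhs_model> 4 fold models (site1, site2, site3, site4)
#>   out-of-fold: detection 100.0%, lateralization 100.0%, specificity 100.0%
```

Out-of-fold performance is the leave-one-site-out estimate: every subject is
scored by the fold that never saw their site. On this small, well-separated
synthetic cohort the classifier is perfect; the abnormality thresholds land
symmetrically around zero on the normalized-asymmetry axis (about −3.2 for
left HS and +3.3 for right HS for volume; `flagged = TRUE` marks complete
separation of the groups, so the boundary location, not its significance, is
the useful output):

```r
preds  <- aidhs_predict(model, cohort, apply_qc = FALSE)
sid    <- cohort$demographics$subject_id[cohort$demographics$lateralization == "right"][1]
report <- build_report(model, cohort, sid, predictions = preds)
report
#> <aidhs_report> site1_s009: HS (lateralization right);
#>   scores L 0.0% / R 99.8% / none 0.2%
round(report$normative$volume$right$percentile, 1)  # 1.5  — atrophic side
round(report$normative$volume$left$percentile, 1)   # 63.1 — healthy side
render_report(report, "html", "site1_s009_aidhs_report.html")
```

The right (ipsilateral) hippocampal volume sits at the 1.5th centile of the
healthy growth chart while the left is unremarkable, the asymmetries breach
the right-HS thresholds, and the ensemble gives right HS a 99.8% score — the
three panels of the report agree on the same lesion.

A command-line front end covering `simulate`, `preprocess`, `harmonize`,
`train`, `predict`, `report` and `evaluate` lives at `inst/cli/aidhs.R`:

```sh
Rscript inst/cli/aidhs.R simulate --seed 5 --output-dir cohort
Rscript inst/cli/aidhs.R train --data-dir cohort --output-dir model
Rscript inst/cli/aidhs.R report --data-dir cohort --model model/aidhs_model.json --output-dir reports
```

## Scope

The package starts from segmentation-tool outputs: it does not segment MRI,
recompute features from mesh geometry, classify bilateral HS (bilateral
patients pass through prediction and reporting only), or subtype HS.
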