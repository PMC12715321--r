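---
title: "Quantifying and recognising micrographia from scanned handwriting sheets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying and recognising micrographia from scanned handwriting sheets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(micrographr)
```

## The measurement problem

Micrographia — abnormally small handwriting — is a motor sign of
Parkinson's disease (PD). Two facets are distinguished clinically:

* **consistent micrographia**, an overall reduction in stroke size, and
* **progressive micrographia**, a gradual shrinkage of letters as writing
  proceeds (a *sequence effect*).

A cheap, ecologically valid protocol asks a participant to write the same
short sentence ten times down a single A4 (210 × 297 mm) sheet, photograph
it with a smartphone, and submit the scan. `micrographr` implements the
full analysis chain for such sheets:

1. **synthesis** — a generator of artificial handwriting sheets with known
   per-row ink areas, so every downstream stage is testable without any
   patient data;
2. **preprocessing** — deskewing and projection-profile segmentation of a
   page into its ten written rows, and crop normalisation for
   classification;
3. **metrics** — calibrated pen-stroke area per row; consistent
   micrographia is the first-row area in mm², progressive micrographia is
   the sequence effect, the ratio of mean ink areas of the last five to
   the first five rows (values < 1 mean shrinkage);
4. **classification** — a patient-disjoint 5-fold cross-validated image
   classifier over row crops, aggregated into one likelihood-ratio (LR)
   score per patient in [0, 1];
5. **diagnostics** — ROC analysis of the patient LR scores: AUC, the
   Youden index J = sensitivity + specificity − 1 with its associated
   criterion, and prevalence-aware predictive values and accuracy;
6. **reporting** — the classical group tests (equal-variance t,
   Mann–Whitney, Wilcoxon signed-rank, chi-square) and Spearman
   correlations between LR scores and the stroke metrics.

The orchestration module (`run_pipeline()`) chains the stages into one
reproducible run directory with a provenance record; the package's
functions are the interface, there is no separate shell tool.

## What the generator emulates, and what it does not

The generator's defaults encode the study conditions the package targets:
an A4 page at 300 dpi, ten rows, two tasks (sentence first, name second),
and per-group parameter distributions for healthy subjects (HS) and
patients (PD, OFF state):

| group | base pen-stroke area (mm²) | sequence effect |
|-------|---------------------------|-----------------|
| HS    | 126.72 ± 44.85            | 1.05 ± 0.16     |
| PD    | 89.78 ± 26.37             | 0.92 ± 0.23     |

Draws are normal, truncated below at 10% of the group mean: the SDs are
large relative to the means and untruncated draws could go non-physical.
The ON-state contrast is a configurable mean shift with default 0 (no
L-Dopa effect on stroke size); a nonzero shift exists for power
exploration only.

Each subject's rows follow a geometric decay profile `g(r) = a·qʳ⁻¹`
normalised so that the first five rows average to 1 and the last-five to
first-five ratio equals the subject's sequence effect (`q = s^(1/5)` for
ten rows). Row *r*'s target ink area is `base_area_mm2 · g(r)`. Note that
with this normalisation the *first-row* area is `base · g(1)`, about 2%
below the base for a growing profile and 3% above for a shrinking one —
a deliberate, documented property of the parameterisation.

**Rendering.** Pseudo-handwriting is a parametric curve (two superimposed
oscillations with seeded phase/frequency jitter), not font-rendered text:
only ink geometry matters downstream, and a parametric curve gives exact
analytic control. The stroke thickness that hits the row's target area is
not iterated: the curve is rasterised as a one-pixel polyline, the
Euclidean distance transform to the polyline is computed
(`EBImage::distmap`), and the stroke is the set of pixels whose distance
is at most the k-th smallest distance, `k = round(target / c²)` with
`c = 25.4/dpi` mm per pixel. Because grid distances are heavily tied
(0, 1, √2, …), the tie shell at the threshold is topped up
deterministically so the stroke has *exactly* k ink pixels; the realised
binarised area is exact to one pixel, and the generator errors (naming
the row) rather than miss its target by more than 2%. Very small targets
shrink the trajectory itself — fewer oscillations, lower amplitude, then
a shorter written line, the way micrographic writing actually shrinks —
and below the thinnest drawable stroke the generator refuses.

**Scan artifacts** are applied in a fixed order — rotation (≤ 3°),
a linear illumination fall-off (≤ 20% of the dynamic range), additive
Gaussian noise (SD ≤ 5%) — all seeded. Rotations use nearest-neighbour
resampling deliberately: bilinear interpolation convolves the bilevel
stroke with the sampling kernel, and a global threshold then inflates
thin-stroke areas by ~15%; nearest-neighbour keeps the page bilevel so
binarised areas survive a rotate–deskew round trip to within the 5%
robustness contract.

**What passing tests do not show.** The generator varies ink *quantity*
(area, thickness, row height, span) but not letterforms, tremor,
hesitation marks, pressure or language content. A classifier that
separates synthetic cohorts is therefore evidence that the pipeline is
leakage-free and learns ink-geometry differences — not that the specific
architecture would reach any particular accuracy on clinical scans.

## Preprocessing choices

Manual row cropping is replaced by a projection profile: binarise, sum
ink per scanline, bridge blank runs shorter than 2 mm, drop bands shorter
than 2 mm, and require exactly the expected number of bands — anything
else is an explicit segmentation error carrying the count found. A page
failing segmentation is skipped and counted, mirroring a small perceptual
quality discard; it is never imputed. Skew is estimated by maximising the
variance of the projection profile over candidate angles (±3° in 0.25°
steps) on a downsampled page, then undone with a single nearest-neighbour
rotation.

Classifier crops are normalised to ink *intensity* — background 0, ink
towards 1, min-max scaled — padded symmetrically with background to the
target aspect ratio and resized to 32 × 128. A constant (blank) crop maps
to all zeros. Because crops are tight boxes, absolute scale is conveyed
by stroke thickness, ink density and the aspect-driven padding rather
than by raw crop size.

## The classifier

The default backbone (`small_conv`) is a deliberately small scorer
trainable on a laptop CPU in seconds to minutes: one 5 × 5 convolution
(8 filters, stride 2) → ReLU → average pooling onto a 4 × 8 grid →
linear logit → sigmoid, trained from scratch by minibatch SGD
(momentum 0.9) on a class-weighted binary cross-entropy
(inverse-frequency weights by default; the motivating cohorts are 57
patients vs 25 controls). An optional hidden layer (`head_width`) and an
optional `pretrained_plugin` backbone — any user function mapping a crop
to a frozen feature vector, with only the linear head trained — cover the
fine-tuning scheme used with large pretrained networks, which this
package intentionally does not ship or require: the scientific claims
exercised here concern the pipeline, not a specific backbone.

**Cross-validation is patient-disjoint**: all instances of a subject
share the subject's fold, so no writer identity leaks between training
and validation. Subjects are stratified by class and dealt round-robin
after a seeded shuffle (continuing the deal across strata keeps total
fold sizes balanced; 82 subjects in 5 folds yields 17/17/16/16/16).
Setting `folds` equal to the number of subjects degenerates cleanly to
leave-one-subject-out. Each instance is scored exactly once, by the model
whose validation fold contains its subject, and the patient LR is the
mean of the patient's *held-out* instance probabilities — the
leakage-free reading of "mean predicted probability across all folds";
averaging models trained on a patient's own rows would leak and is
rejected. For the within-patient OFF-vs-ON design, labels attach to
pages, folds remain patient-disjoint, and LR is computed per patient and
state. Both handwriting tasks are pooled into one model by default; a
`tasks` filter supports task-separate runs.

All randomness — weight initialisation, batch order, fold shuffle —
derives from named seeds, and identical seeds reproduce identical
predictions exactly.

## Diagnostics

ROC thresholds are the midpoints between adjacent distinct scores plus
∓∞ sentinels; the trapezoidal AUC then equals the Mann–Whitney rank
statistic `P(score_pos > score_neg) + ½ P(tie)`, which the tests verify
against an exhaustive pairwise count and against an independent ROC
implementation. The Youden-optimal criterion breaks ties towards the
lower threshold (higher sensitivity). Predictive values and accuracy are
computed at the class prevalence implied by the cohort sizes, so
`operating_metrics(0.93, 0.88, 57, 25)` reproduces 91% accuracy, 95%
PPV, 85% NPV — printed-figure arithmetic that the acceptance tests check
exactly. Patient-level (not instance-level) ROC is the primary analysis,
because the LR is patient-specific. Confidence intervals are not
computed by default.

## Reporting

`compare_groups()` and `correlate()` wrap the classical tests (all
two-sided, α = 0.05 convention; rank tests use the normal approximation;
the equal-variance t is used where the variance assumption was left
unstated) and return tidy one-row tibbles; `build_report()` assembles the
group summary (mean ± SD), pairwise comparisons and LR-vs-metric Spearman
correlations. No multiple-testing correction is applied, matching the
reporting convention of the motivating study. The perceptual
visual-analogue handwriting rating is *not* reimplemented — it is a human
judgement; automated row-geometry proxies (bounding-box height/length)
stand in and are labelled as such.

## Numerical choices and degenerate inputs

* Binarisation: global Otsu threshold; components under 0.05 mm² removed
  as scan specks (a configurable default, not a measured fact). A
  constant image yields an empty mask, not an error. An adaptive local
  threshold is available behind `method = "adaptive"`.
* Area is ink-pixel count × c²; "pen-stroke area" could also be read as
  bounding-box or convex-hull area, and the ink-pixel reading is the one
  implemented and documented.
* `sequence_effect()` is oriented last/first so values < 1 encode
  shrinkage (patients ≈ 0.92 < controls ≈ 1.05); "size effect" and
  "sequence effect" are treated as synonyms. Zero first-half mean area is
  an explicit undefined-ratio error.
* Ties in the Youden search resolve to the lower criterion; zero rank
  variance makes Spearman's rho undefined (`NA` + warning); undefined
  predictive values (no positive or no negative calls) are `NA`, never an
  error.

## Problem sizes used by the checks

The packaged checks run at deliberately modest sizes, chosen as the
package's own test conditions: round-trip and robustness fixtures render
at 80–150 dpi; the parameter-recovery checks use 19 HS and 15 PD
subjects (the subset size of the motivating pen-stroke-area analysis)
with acceptance within three standard errors of the configured group
mean; the end-to-end classification check uses 20 + 20 subjects at
100 dpi with well-separated group distributions (base areas 130 ± 12 vs
70 ± 10 mm²) and requires patient-level AUC ≥ 0.95; the
`scripts/acceptance.R` recovery runs use the full 300 dpi default. Null
calibration of the report tests uses 1000 Monte-Carlo replicates.

## Known limitations

* Synthetic strokes carry no letterforms, tremor or pressure information;
  absolute classification accuracy on synthetic cohorts does not transfer
  to clinical scans.
* The artifact model (rotation, linear illumination, Gaussian noise) is a
  simplification of smartphone capture; perspective distortion, shadows
  and JPEG blocking are out of scope.
* Kinematic features of dysgraphia (velocity, acceleration, pressure,
  fluency) are outside the static, image-based scope of this package.
* With heavily overlapping group distributions (the realistic defaults),
  an area-driven classifier cannot exceed the separability those
  distributions admit; the well-separated configuration exists precisely
  to test the machinery rather than to claim clinical performance.
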