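# micrographr

Quantification and automated recognition of **micrographia** — the
abnormally small handwriting of Parkinson's disease (PD) — from scanned
pen-and-paper handwriting sheets.

The package is aimed at movement-disorder researchers and methodologists
who want a fully testable, end-to-end implementation of the
pen-and-paper protocol in which a participant writes a short sentence 10
times down an A4 sheet and submits a smartphone scan. It provides:

* a **synthetic sheet generator** with exact per-row ink-area ground
  truth (so every stage is testable without patient data),
* **row segmentation** of a page by its horizontal ink-projection
  profile, with deskewing,
* calibrated **pen-stroke metrics**: consistent micrographia is the
  first-row ink area `A₁` (mm²); progressive micrographia is the
  *sequence effect*

  `S = mean(A₆…A₁₀) / mean(A₁…A₅)`,

  with `S < 1` indicating progressive shrinkage (PD ≈ 0.92 vs healthy
  ≈ 1.05),
* a **patient-disjoint 5-fold cross-validated** image classifier over
  row crops, aggregated into one likelihood-ratio score per patient,
  `LR ∈ [0, 1]` (mean held-out instance probability; higher = more
  impaired),
* **ROC/Youden diagnostics**: trapezoidal AUC (equal to the rank
  statistic `P(s⁺ > s⁻) + ½P(tie)`), the Youden index
  `J = max(sens + spec − 1)` with its associated criterion, and
  prevalence-aware PPV/NPV/accuracy,
* a **reporting layer** (equal-variance t, Mann–Whitney, Wilcoxon
  signed-rank, chi-square, Spearman) over tidy tibbles.

All user-facing functions take and return tibbles and chain with the
pipe; fitted objects have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

A small end-to-end run (6 + 6 subjects, well-separated synthetic groups,
100 dpi, 4 training epochs; ~30 s on one CPU):

```r
library(micrographr)

cfg <- run_config(
  out_dir = "demo_run",
  n_per_group = c(HS = 6, PD = 6),
  generator = generator_config(
    dpi = 100, tasks_per_subject = 1,
    group_area_params = list(HS = c(mean = 130, sd = 12),
                             PD = c(mean = 70, sd = 10)),
    group_seqeffect_params = list(HS = c(mean = 1.05, sd = 0.05),
                                  PD = c(mean = 0.85, sd = 0.05))),
  classifier = classifier_config(epochs = 4, seed = 3),
  seeds = list(generate = 1L, folds_train = 2L))

run <- run_pipeline(cfg)
run$roc
#> <hw_roc> positive = PD (6 vs 6)
#>   AUC 0.806 | Youden J 0.667 at criterion 0.477 | sens 1.000 spec 0.667
#>   acc 0.833 ppv 0.750 npv 1.000
run$report
#> -- group summary --
#>   variable            group     n    mean     sd
#> 1 consistent_area_mm2 HS        6 125.    8.55
#> 2 consistent_area_mm2 PD        6  82.1   7.59
#> 3 sequence_effect     HS        6   1.05  0.0566
#> 4 sequence_effect     PD        6   0.855 0.0558
#> -- comparisons --
#>   variable            test       group1 group2 statistic    p_value
#> 1 consistent_area_mm2 unpaired_t HS     PD          9.21 0.00000337
#> 2 sequence_effect     unpaired_t HS     PD          6.15 0.000108
#> -- correlations (LR vs metrics) --
#>   var_x var_y                   n spearman_rho p_value
#> 1 lr    consistent_area_mm2    12       -0.622  0.0307
#> 2 lr    sequence_effect        12       -0.105  0.746
```

Reading the output: the generated patients write smaller (82 vs
125 mm² first-row area) and shrink as they write (sequence effect 0.86
vs 1.05); both group differences are detected by the unpaired t-test.
The cross-validated classifier separates patients from controls at
patient level with AUC 0.81 at this miniature scale, and the
Youden-optimal LR criterion 0.477 operates at sensitivity 1.00 /
specificity 0.67. Patients with higher LR scores tend to have smaller
stroke areas (negative Spearman correlation). Every artifact of the run
(pages, manifest, per-row metrics, LR scores, ROC points, report tables,
provenance) is written under `demo_run/`.

Individual stages are ordinary functions — e.g.

```r
cfg  <- generator_config()                           # A4, 300 dpi, 10 rows
prof <- sample_subject_profiles(cfg, c(HS = 19))
sheet <- render_sheet(prof[1, ], "sentence", cfg)
rows  <- measure_page(sheet$page, expected_rows = 10)
consistent_micrographia(rows); sequence_effect(rows)
```

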