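# texturestager

Texture-based discrimination of lymph-node invasion status (N0 vs N1-2)
from 2D MRI tumor regions of interest, for imaging researchers who want the
classical radiomics screening-and-modelling workflow as tested, reusable R
functions rather than one-off scripts.

Node-positive rectal tumors tend to be more heterogeneous on T2-weighted
MRI than node-negative ones. The package measures that heterogeneity on a
single tumor slice per imaging sequence and carries it through the full
classical analysis chain:

- **Preprocessing** — ROI intensities normalized to μ ± 3σ (μ, σ from the
  inside-mask pixels) and quantized to `Ng` gray levels, making every
  feature invariant to positive affine intensity transforms.
- **Ten texture features** per ROI, written from first principles and
  verified against brute-force enumeration oracles:
  histogram skewness `SKE = m₃/m₂^{3/2}` and kurtosis `KUR = m₄/m₂²`;
  GLCM contrast `Σ(i−j)²p(i,j)`, energy `Σp²`, entropy `−Σp log₂ p` and
  information measure of correlation `(HXY−HXY1)/max(HX,HY)`;
  GRLM long run emphasis `Σj²r(i,j)/Nr`, run length non-uniformity
  `Σⱼ(Σᵢr)²/Nr`, low gray-level run emphasis `Σr/i²/Nr` and short run low
  gray-level emphasis `Σr/(i²j²)/Nr`. Second-order families use distance-1
  symmetric matrices in four directions (0°, 45°, 90°, 135°), averaged.
- **Interobserver agreement** — ICC(2,1), two-way random effects, absolute
  agreement, with the usual 0.4 / 0.6 / 0.8 bands.
- **Univariate screening** — Lilliefors-gated Student t or Mann-Whitney U,
  plus Spearman correlation with the class.
- **Modelling** — forward-stepwise logistic regression (likelihood-ratio
  entry p < 0.05, removal p > 0.10) per feature scope (sagittal / axial /
  combined), Hosmer-Lemeshow calibration, and in-sample ROC with DeLong
  95% CI and the Youden-optimal cutoff.
- **Synthetic cohorts** — a seeded Gaussian-random-field generator with a
  class-dependent correlation length (the positive class more
  heterogeneous), two coupled sequences per subject and two simulated
  readers, so the whole pipeline is testable without patient data.
  Cohorts round-trip to disk as 16-bit PNGs with CSV manifests; PNG and
  single-slice NIfTI are accepted on load.

## Worked example

```r
library(texturestager)

spec    <- cohort_spec_effect("large", n_per_class = 30, seed = 11)
cohort  <- generate_cohort(spec)
features <- extract_cohort_features(cohort, n_levels = 32, reader = 1)

dplyr::select(features[1:3, ], subject_id, class_label,
              sagittal_ENE, sagittal_ENT, axial_SRLGLE)
#> # A tibble: 3 × 5
#>   subject_id class_label sagittal_ENE sagittal_ENT axial_SRLGLE
#>   <chr>            <int>        <dbl>        <dbl>        <dbl>
#> 1 S001                 0       0.0164         6.33      0.00371
#> 2 S002                 0       0.0217         5.96      0.00355
#> 3 S003                 0       0.0126         6.78      0.00588
```

`class_label` 1 is the node-positive analogue, generated with a shorter
texture correlation length: its GLCM energy runs lower and its entropy
higher than in class 0. Screening and modelling:

```r
screen <- univariate_screen(features)           # 20 features, no MTC
suite  <- run_model_suite(features, screen, scopes = "combined")
glance(suite)
#>   scope        n n_selected deviance null_deviance   aic hl_statistic  hl_p   auc ...
#> 1 combined    60          1     3.74          83.2  7.74         1.33 0.995 0.999
```

Read: on this strongly separated synthetic cohort, one texture feature
suffices; the stepwise model separates the classes almost perfectly
in-sample (AUC 0.999) and shows no calibration failure (Hosmer-Lemeshow
p = 0.995). `tidy(suite)` lists the selected features with odds ratios and
Wald confidence intervals; `autoplot()` on any `roc_analysis()` result
draws the ROC curve.

Interobserver agreement across the two simulated readers:

```r
icc <- agreement_table(
  extract_cohort_features(cohort, n_levels = 32, reader = 1),
  extract_cohort_features(cohort, n_levels = 32, reader = 2)
)
range(icc$icc)     # 0.939 0.998 — all 20 features in the "excellent" band
```

A command-line front end (`exec/texturestager`) wraps the same functions:
`simulate`, `extract`, `analyze univariate | agreement | model`, and
`full-run` (which writes `features.csv`, `icc.csv`, `univariate.csv`,
`roc.csv`, `model_report.json`, `config.json`, `run.log` into one
directory; identical configurations reproduce the report byte for byte).

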