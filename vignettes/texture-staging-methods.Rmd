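---
title: "Methods: texture-based discrimination of nodal status from 2D MRI ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: texture-based discrimination of nodal status from 2D MRI ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the pipeline

Regional lymph-node invasion (N stage) drives the decision between upfront
surgery and neoadjuvant chemoradiotherapy in rectal cancer, but preoperative
nodal assessment on MRI is unreliable when it relies on node size alone.
Tumor *texture* offers an indirect route: node-positive tumors tend to be
more heterogeneous, and heterogeneity is measurable on the primary tumor's
T2-weighted image without ever segmenting a node.

`texturestager` implements that route as a reusable pipeline over 2D tumor
regions of interest (ROIs), one slice per subject per imaging sequence
(sagittal fat-suppression T2WI and oblique axial T2WI in the motivating
design):

1. **Normalization and quantization** — ROI intensities are clipped to
   $\mu \pm 3\sigma$ and linearly quantized to $N_g$ gray levels.
2. **Feature extraction** — ten features per ROI: histogram skewness (SKE)
   and kurtosis (KUR); GLCM contrast (CON), energy (ENE), entropy (ENT) and
   information measure of correlation (INC); GRLM long run emphasis (LRE),
   run length non-uniformity (RLN), low gray-level run emphasis (LGLRE) and
   short run low gray-level emphasis (SRLGLE). Second-order families are
   averaged over the four distance-1 directions (0°, 45°, 90°, 135°).
3. **Interobserver agreement** — ICC(2,1) between two readers' feature
   values; analysis proceeds with reader 1 (or the reader mean, by policy).
4. **Univariate screening** — per-group Kolmogorov–Smirnov normality gate,
   then Student's t-test or Mann–Whitney U; Spearman correlation with the
   class; no multiple-testing correction (flagged in the report).
5. **Modelling** — forward-stepwise logistic regression (likelihood-ratio
   entry at $p < 0.05$, removal at $p > 0.10$) per feature scope
   (sagittal-only, axial-only, combined), Hosmer–Lemeshow calibration, and
   in-sample ROC with the Youden-optimal cutoff.

Because clinical MRI cohorts of this kind are rarely shareable, the package
ships a first-class synthetic cohort generator so that every stage is
testable end to end.

# Preprocessing

Let $x$ be the raw intensities inside the mask, $\mu$ their mean and
$\sigma$ their **population** standard deviation (the convention is not
universal; the population form is chosen and documented here). Intensities
are clipped to $[\mu - 3\sigma,\, \mu + 3\sigma]$ and mapped by

$$q = \left\lfloor \frac{x - (\mu - 3\sigma)}{6\sigma} \, N_g \right\rfloor,$$

with the upper bound closed into bin $N_g - 1$. A constant ROI
($\sigma = 0$) maps to the middle level $\lfloor N_g / 2 \rfloor$. Because
$\mu$ and $\sigma$ are taken from the ROI itself, the map — and therefore
every downstream feature — is invariant to positive affine transforms of
the intensities, which is what makes features comparable across scanners
with different intensity scales (up to nonlinear effects, which are out of
scope).

`normalize_quantize()` defaults to $N_g = 256$ ("8 bits per pixel", the
classical description). For ROIs of a few hundred pixels, 256 levels make
the co-occurrence matrix almost empty off the diagonal and push energy and
entropy into degenerate corners, which is why radiomics practice usually
bins to 32–64 levels; the pipeline and CLI therefore default to
$N_g = 32$, and the level count is exposed everywhere
(`--n-levels`). Feature *magnitudes* depend on $N_g$; class *ordering*
(who is more heterogeneous) does not, and only the ordering is treated as
meaningful here.

Histogram skewness and kurtosis are computed on the quantized levels (the
pipeline normalizes before all feature extraction), with population
moments and non-excess kurtosis — a normal sample gives KUR ≈ 3.

# Texture features

**GLCM.** Pairs of quantized levels at distance 1 are counted in four
directions; a pair counts only when both pixels are inside the mask, and
each pair is accumulated in both orders (symmetric matrix, so 0° ≡ 180°).
With $p(i,j)$ the normalized counts:

- $\mathrm{CON} = \sum (i-j)^2 p(i,j)$
- $\mathrm{ENE} = \sum p(i,j)^2$ (angular second moment; the "energy =
  uniformity" reading, not its square root)
- $\mathrm{ENT} = -\sum p \log_2 p$ (base 2 by default; the base is a
  configuration option and only rescales ENT)
- $\mathrm{INC} = (HXY - HXY1)/\max(HX, HY)$, the information measure of
  correlation 1, defined as 0 when both marginal entropies vanish. IMC1 is
  non-positive for essentially all images; the IMC2 variant
  $\sqrt{1 - e^{-2(HXY2 - HXY)}}$ is available via `inc_variant = "imc2"`.

**GRLM.** Maximal constant-level runs along each traversal line, outside
pixels breaking runs. With $r(i,j)$ the count of runs of 1-based gray
index $i$ and length $j$, and $N_r$ the total run count:
$\mathrm{LRE} = \sum j^2 r / N_r$,
$\mathrm{RLN} = \sum_j (\sum_i r)^2 / N_r$,
$\mathrm{LGLRE} = \sum r / i^2 / N_r$,
$\mathrm{SRLGLE} = \sum r/(i^2 j^2) / N_r$ (Galloway conventions; the
1-based index keeps level 0 from dividing by zero).

Per-direction features are averaged over the directions that contain at
least one pair (GLCM) or run (GRLM); a one-pixel-thin mask has no valid
45°/135° pair, and such directions are dropped from the mean rather than
zero-filled. Averaging over the four directions makes the feature vector
invariant to 90° rotations of image and mask, a property the test suite
checks directly. On a constant ROI the histogram moments are undefined;
`extract_features()` returns `NA` for SKE/KUR with a warning while the
second-order features remain defined (CON 0, ENE 1, ENT 0, INC 0).

All counting code is written from first principles in R and is verified,
for hundreds of random small images with random masks, against brute-force
pair/run enumeration oracles that share no code with the implementation.

# The synthetic cohort generator

The generator emulates the *design* of a two-class single-slice MRI study,
not MRI physics. Its model is a Gaussian random field: per subject, white
noise smoothed with a Gaussian kernel whose standard deviation — the
**correlation length** — is the class's heterogeneity dial. A long
correlation length gives smooth, homogeneous texture (high ENE, low ENT);
a short one gives fine-grained heterogeneous texture. The positive class
(N1-2 analogue) gets the shorter length, reproducing the reported
direction of nodal disease (lower energy, higher entropy) without copying
any particular magnitude.

Per subject: a shared latent field is mixed into the two sequences with
weight `sequence_coupling` (default 0.7, giving correlated but distinct
sagittal/axial textures), i.i.d. pixel noise is added (default sd 0.1 in
units of the unit-variance smoothed field), and each image is affinely
rescaled to positive 16-bit integers — harmless, since the features are
affine-invariant. The ROI is the largest 4-connected component of a
thresholded, separately smoothed field with a central bump (≥ 64 px;
degenerate draws are retried from a derived sub-seed, at most 100 times).
Reader 2's mask flips boundary-band pixels (within `reader_perturb_radius`,
default 2 px) where a smooth standardized perturbation field exceeds
±1 sd — locally coherent over/under-drawing, which keeps Dice overlap
above 0.8 and ICCs in the "excellent" band, as reported for trained
radiologists.

Effect presets fix the class contrast once: `none` (3 / 3 px — a null
cohort for calibration checks), `small` (3.5 / 2.5), `large` (6 / 1.5).
Default cohort size is 60 subjects per class at 64 × 64 px.

Every draw is a pure function of `(master seed, subject index, purpose
tag)` through a multiplicative hash, so identical specs are bit-identical
and enlarging a cohort never reshuffles existing subjects.

What the generator does **not** emulate: Rician noise, bias fields,
anatomy, partial-volume effects, 3D volumes, or any dependence of the
class on covariates. Passing tests on synthetic cohorts therefore
establish the *pipeline's* correctness and calibration, not clinical
performance on real MRI.

# Statistical stages: choices in the open

- **Normality gate.** "Kolmogorov–Smirnov" with estimated mean and sd is
  the Lilliefors test; `nortest::lillie.test()` provides it (a plain KS
  gate is available via `normality = "ks"`). Lilliefors needs n ≥ 5, so
  groups of 2–4 are routed to the Mann–Whitney path. Normality is
  assessed per group by default (`pooled_normality` switches to pooled,
  since the source design does not say which was used).
- **t-test form.** Equal-variance Student by default, mirroring the
  default labeled output of the classical SPSS workflow; Welch via
  `var_equal = FALSE`.
- **Mann–Whitney.** `wilcox.test()` semantics: exact permutation p for
  small untied samples (verified against exhaustive enumeration up to
  n = 8 per group), normal approximation with tie and continuity
  correction otherwise.
- **Categorical tests.** Fisher's exact for 2 × 2 tables with any
  expected count < 5, Pearson chi-square without continuity correction
  otherwise; larger sparse tables fall back to chi-square with a warning.
- **ICC.** ICC(2,1) — two-way random effects, absolute agreement, single
  measures — from the ANOVA decomposition, written out here because no
  installed package provides it. Absolute agreement penalizes systematic
  reader shifts. Zero total variance is defined as ICC 1 and flagged
  `trivial`. Bands: ≤ 0.4 poor, ≤ 0.6 moderate, ≤ 0.8 good, else
  excellent.
- **Stepwise selection.** Forward by likelihood-ratio p (entry 0.05),
  backward elimination after each entry (removal 0.10) — the "Forward:
  LR" convention. `glm(binomial)` is the ML fitter (IRLS is Newton's
  method for the canonical logit link; tolerance 1e-10, ≤ 100
  iterations); the selection loop is this package's own code because base
  `step()` selects by AIC, not p-values. Separation is flagged per
  feature (|coefficient| > 15 or fitted probabilities numerically 0/1).
- **Hosmer–Lemeshow.** Deciles of risk with ties never split (groups by
  maximal rank), zero-expected cells merged into the neighbor with a df
  reduction, statistic on $g - 2$ df. Under a correctly specified fitted
  model its p-values are approximately uniform, which the test suite
  checks by simulation.
- **ROC.** pROC supplies the AUC (Mann–Whitney identity, ties ½) and the
  DeLong 95% CI; this package adds the direction rule (chosen so
  AUC ≥ 0.5, reported as "> c" / "< c"), the Youden-maximal cutoff with
  ties broken toward higher sensitivity, and accuracy = correctly
  classified fraction at the cutoff. Evaluation is deliberately
  **in-sample** — fit and ROC on the same cohort, as in the motivating
  single-cohort design — and the report carries that caveat; no
  cross-validation is added.

# Numerical and degenerate-input conventions

- Pixel coordinates are (row, col), 0-based levels; masks are inclusion
  maps. 16-bit PNG intensities are read as stored integers, with no
  rescaling at load.
- Quantization bins are half-open with the top bin closed; values beyond
  ±3σ saturate at 0 / $N_g - 1$.
- Empty GLCM directions are flagged and excluded from means; an ROI with
  no valid pair in any direction is an error.
- Constant scores in ROC, constant features in Spearman, zero-variance
  groups in screening, and empty candidate scopes in modelling each have
  explicit, tested behaviors (degenerate flag, error, forced
  Mann–Whitney, skipped scope with warning, respectively).
- All simulation sizes in the test suite (500 oracle images, 1,000 null
  replicates for the screening gate, 500 calibration replicates, 50
  discrimination cohorts at 60/60 subjects) were chosen as the smallest
  sizes at which the Monte-Carlo error is comfortably below the asserted
  tolerances.

# Known limitations

- Synthetic cohorts are Gaussian random fields; conclusions about real
  MRI require real images.
- Single-slice 2D analysis; volumetric (3D) texture is out of scope.
- In-sample evaluation only; reported AUCs are optimistic by design and
  labeled as such.
- No multiple-testing correction in the screen (by design, flagged in
  every report).
- IMC1 is reported on its conventional non-positive scale; published
  positive "information correlation" values of unclear provenance cannot
  be compared directly.
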