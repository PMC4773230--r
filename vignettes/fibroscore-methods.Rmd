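---
title: "Quantifying interstitial lung disease on HRCT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying interstitial lung disease on HRCT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibroscore)
```

## The problem

Interstitial lung disease (ILD) is a major cause of morbidity and mortality
in systemic sclerosis (SSc). On high-resolution CT (HRCT), fibrotic change
raises the attenuation of lung parenchyma: normal aerated lung sits around
-800 to -900 Hounsfield units (HU), ground-glass and reticular change
occupies roughly -700 to -500 HU, and consolidation is denser still. Two
complementary ways of turning an HRCT study into a number are implemented
here:

* a **computer-aided densitometric score** — the percentage of the
  segmented lung volume whose attenuation exceeds the normal-parenchyma
  range; and
* the **Warrick visual score** — a reader assigns severity points per
  abnormality type and extent points per number of bronchopulmonary
  segments involved, total 0–30.

The package also implements the cohort statistics with which such scores
are related to pulmonary function (FVC %, DLco %) and patient-centred
measures (Borg dyspnea index, VAS for breathing, HAQ-DI), and synthetic
data generators so the whole pipeline is testable without patient data.

## The densitometric (CaM) score

The lungs are isolated by thresholding: every voxel with attenuation in
the closed window $[-1024, -200]$ HU is a lung candidate. With the voxel
classes

$$
\text{normal} = [-1024, -700], \quad
\text{ILD} = (-700, -500], \quad
\text{consolidation} = (-500, -200],
$$

the percent pulmonary fibrosis over a lung mask $L$ is

$$
\mathrm{PF\%} \;=\; 100 \times
  \frac{N_{[-1024,-200]}(L) - N_{[-1024,-700]}(L)}{N_{[-1024,-200]}(L)},
$$

i.e. the lung-window voxel count minus the normal-attenuation count,
divided by the lung-window count. By construction this equals
$100\,(N_{\mathrm{ILD}} + N_{\mathrm{consolidation}})/N_{\mathrm{total}}$;
the test suite asserts both forms agree to $10^{-12}$.

**Boundary membership.** The thresholds $-700$ and $-500$ HU are
conventional; which class owns the boundary value is not. We fix a
half-open partition (each cut belongs to the class below it) so that the
class counts always sum exactly to the lung-window count. The cuts are
configurable through `cam_thresholds()`, but the default is fixed and used
everywhere, including the synthetic ground truth.

**Volumetric, not per-slice.** The fraction is computed over the full 3-D
voxel set; a per-slice profile (`slice_profile()`) is provided only as a
diagnostic. Volumes are voxel counts times the voxel volume taken from the
native grid — nothing is resampled on read.

Because the score is a deterministic function of (volume, mask), repeat
scoring of the same study is in total concordance: ICC $= 1$ and
Bland–Altman limits of agreement $0$ to $0$. This is a property of the
method, and the acceptance script demonstrates it by actually running the
pipeline twice over 20 phantoms.

## Segmentation without a human in the loop

Interactive threshold segmentation involves minimal manual exclusion of
vessels and large bronchi near the hilum. A reproducible pipeline cannot
include a human, so `refine_lung_mask()` replaces the manual step with a
deterministic rule:

1. delete 26-connected components that touch the grid boundary (exterior
   air is always border-connected; the lungs are enclosed by the body);
2. delete components smaller than `min_component_voxels` (default: the
   voxel count of 1 cm³ at the volume's spacing), suppressing airway and
   vessel fragments;
3. morphological opening with a ball of radius `opening_radius_mm`
   (default 1 mm) to cut thin bridges;
4. optionally delete residual air-like components — mean HU below
   $-950$ with an in-plane centroid in the central third of the grid —
   as a trachea/main-bronchus surrogate. A lone surviving component is
   never deleted, so the rule is inert on anatomies without a separate
   airway component.

This is a documented design choice, not a claim about how any interactive
workflow behaves. The refined mask is provably a subset of the candidate
mask, and segmentation is deterministic given (volume, parameters). On
synthetic phantoms the refined mask overlaps the generator's ground truth
with Dice $\ge 0.98$ (measured $\approx 0.999$).

## The Warrick score

Severity points per abnormality: ground-glass 1, irregular pleural margins
2, septal/subpleural lines 3, honeycombing 4, subpleural cysts 5. Extent
points per abnormality from the number of bronchopulmonary segments
involved: 0 segments → 0, 1–3 → 1, 4–9 → 2, more than 9 → 3. Severity is
the sum over abnormality types present (max 15), extent the sum of extent
points (max 15), total 0–30. The scoring space is enumerated exhaustively
in the tests.

The segment universe is fixed at the conventional 18-segment atlas (10
right; 8 left with the apicoposterior and anteromedial-basal segments
fused). Published descriptions of the score do not pin down the atlas;
fixing it makes "more than nine segments" well defined and caps the extent
input at 18.

Two readers are combined either by component-wise arithmetic mean (the
value used in analyses) or by deferring to an adjudicated consensus read.
Consensus is data, not computation: the package will not invent a
tie-break, it requires the third assessment.

## Cohort statistics

* **Descriptives**: mean with sample SD ($n-1$), median with 25th/75th
  percentiles (type-7 quantiles).
* **Group comparisons**: two-sample pooled-variance t test for continuous
  variables; chi-squared without continuity correction for 2×2 tables
  (correction available by flag). The choice of the classical pooled test
  mirrors standard practice in clinical baseline tables.
* **Correlation**: Pearson product-moment r, p from the t transform with
  $n-2$ df.
* **Multivariate regression**: OLS with intercept. Per-covariate partial
  correlation is derived from the t statistic,
  $r_\mathrm{partial} = t/\sqrt{t^2 + df}$ with $df = n - k - 1$, signed
  by $t$; adjusted $R^2 = 1 - (1-R^2)(n-1)/(n-k-1)$. Rank-deficient
  designs are refused with an error naming the collinear columns — a
  collinear covariate (e.g. a VAS dyspnea scale duplicating the Borg
  score) must be excluded deliberately, never dropped silently.
* **Agreement**: ICC is the two-way random-effects, absolute-agreement,
  single-measure variant, computed from the ANOVA mean squares. Reports of
  inter-reader agreement rarely name the ICC variant; this is the standard
  choice for two interchangeable readers and is stated prominently so the
  number is interpretable. Bland–Altman limits are
  mean difference $\pm\, 1.96$ SD of the paired differences.
* **Missing data**: complete cases per analysis, with n reported alongside
  every statistic. Two-sided p-values throughout; the conventional 0.05
  threshold is reported, never used to drop covariates automatically.

## Synthetic data: what it does and does not emulate

### Phantoms

`generate_phantom()` builds an elliptical-cylinder body (soft tissue,
40 HU) in exterior air ($-1000$ HU) and carves two ellipsoidal lungs.
Lung voxels are drawn fibrotic with the design probability — uniformly, or
weighted toward the pleural surface (`subpleural`) or the lung base
(`basal`) — with HU sampled from $N(-850, 40)$ for normal parenchyma
(centre of the conventional $-800$ to $-900$ HU range) and $N(-600, 50)$
for fibrotic tissue (centre of the ILD band), clamped to the CT range
$[-1024, 3071]$.

The ground truth is measured back from the emitted volume by direct voxel
counting, so it includes tail leakage: a normal draw can land above
$-700$ HU (probability $\Phi(-3.75) \approx 9\times10^{-5}$) and a
fibrotic draw below it (probability $\Phi(-2) \approx 0.023$). The
realized fraction is therefore slightly below the design fraction, by
about $0.023f$; at design 0.41 the pipeline recovers the design value
within about one percentage point, and the tests require ±2 points.

What the phantom does **not** model: airway and vessel trees, honeycomb
texture, scanner noise and reconstruction kernels, inspiration-level HU
shifts (a global HU shift can be emulated by moving the distribution
means). The threshold method only sees the attenuation histogram and
coarse spatial arrangement, so HU-distribution fidelity is the relevant
axis; passing phantom tests shows the arithmetic and the segmentation
logic are right, not that the score is clinically valid on real scans.

### Cohorts

`generate_cohort()` uses a Gaussian copula: a latent multivariate normal
with a target correlation matrix, mapped through monotone transforms to
the marginal means/SDs (clamped to each scale's bounds; the skin score is
rounded to integers) and thresholded at the specified prevalences for
binary variables. The default marginals are calibrated to a 126-patient
SSc cohort's baseline table; only means, SDs and pairwise correlations
are claimed, not distributional shape.

The default correlation preset carries the reported univariate
associations (densitometric vs visual score 0.718, vs FVC $-0.556$, vs
DLco $-0.670$, vs HAQ-DI 0.597; Borg–VAS 0.627; HAQ-DI–Borg 0.546) with
all other pairs 0. That sparse matrix is **indefinite** (smallest
eigenvalue $\approx -0.32$), so it is repaired to the nearest positive
semidefinite correlation matrix before sampling; the repair moves the
named entries appreciably (0.718 → 0.60, for example). The repaired
matrix is the generating truth and is attached to every cohort as
`attr(, "effective_correlation")`; recovery checks compare against it.
The preset is a demonstration of structure, not an estimate of the joint
distribution of any real cohort.

Two further consequences of the design are worth knowing. Clamping at the
scale bounds attenuates both means (by at most 5 % of an SD at the default
bounds — tested at $n = 10^5$) and correlations (by $\le 0.01$ on the
Fisher-z scale at the defaults). And the visual-score components
(`covr_extent`, `covr_severity`, `covr_total`) are drawn as separate
marginals per the preset, so extent + severity only approximately equals
total in generated cohorts; the scoring module, not the cohort generator,
owns that identity.

## Numerical and scale choices

* HU values are clamped to $[-1024, 3071]$ on construction; padding
  values below the floor become pure air and cannot escape the thresholds.
* Canonical array order is slice–row–column with the slice index
  increasing toward the head; DICOM slices are sorted by spatial position
  on read, NIfTI axes are mapped x = column, y = row, z = slice.
* Connectivity is 26-neighbour for component labelling; the test oracles
  use the same convention.
* Problem sizes in the test suite: routine tests use 32×48×48 phantoms
  (≈11 000 lung voxels); fraction-recovery runs use 120×240×230 grids
  (≈10⁶ lung voxels); cohort recovery uses n = 5000 and marginal-bias
  checks n = 10⁵. These sizes keep every statistical tolerance
  comfortably powered.
* All generation is seeded and bit-reproducible; the pipeline itself is
  fully deterministic.

## Worked example

```{r example, eval = FALSE}
ph <- generate_phantom(phantom_spec(seed = 7, design_fibrotic_fraction = 0.13))
mask <- segment_lungs(ph$volume)
dice_overlap(mask, ph$truth$lung_mask)
cam_score(ph$volume, mask)

co <- generate_cohort(cohort_spec(n = 126, seed = 7))
fit <- fit_multivariate(co, "cam_fibrosis_pct",
                        c("age", "sex", "disease_duration", "anti_topo_I",
                          "mrss", "haq_di", "borg", "fvc_pct", "dlco_pct"))
print(fit)
render_table1(co)
```

## Known limitations

* The deterministic airway/vessel exclusion is a surrogate; on real scans
  with lungs touching the scan boundary, border-component deletion would
  need relaxing.
* Only uncompressed little-endian single-frame DICOM is read; enhanced
  multi-frame CT and compressed transfer syntaxes are out of scope.
* The visual-score module encodes the arithmetic of the score, not the
  perceptual task of detecting abnormalities on images.
* Left/right lung separation, lobe segmentation, and texture-based ILD
  classification are deliberately not implemented.
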