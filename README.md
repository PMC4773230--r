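# fibroscore

Quantitative CT densitometry and visual scoring of interstitial lung
disease (ILD), written for researchers who study lung involvement in
systemic sclerosis (SSc) and want a reproducible, fully tested pipeline
from CT voxels to cohort-level statistics.

## What it computes

**Densitometric fibrosis score.** Lung parenchyma is isolated by
thresholding the attenuation window [−1024, −200] HU and cleaning the
mask deterministically (border-connected air removal, small-component
filtering, morphological opening, optional airway exclusion). Over the
lung mask *L*, voxels are classified as normal [−1024, −700] HU, ILD
(−700, −500] HU, or consolidation (−500, −200] HU, and the percent
pulmonary fibrosis is

```
PF% = 100 × (N[-1024,-200](L) − N[-1024,-700](L)) / N[-1024,-200](L)
```

— the lung-window volume minus the normal-attenuation volume, over the
lung-window volume. Being a deterministic function of (volume, mask), a
repeat measurement reproduces the score exactly: ICC = 1, Bland–Altman
limits of agreement 0 to 0.

**Warrick visual score.** Severity points per abnormality (ground glass
1, irregular pleural margins 2, septal/subpleural lines 3, honeycombing
4, subpleural cysts 5) plus extent points per abnormality from the number
of bronchopulmonary segments involved (0 → 0, 1–3 → 1, 4–9 → 2, >9 → 3),
totalled over an 18-segment atlas; range 0–30. Dual readers are combined
by component-wise mean or by an adjudicated consensus read.

**Cohort statistics.** Descriptives (mean ± SD, median, IQR), pooled
t / chi-squared group comparisons, Pearson correlation, multivariate OLS
with per-covariate partial correlations (r = t/√(t²+df)) and adjusted R²,
ICC(2,1) agreement, and Bland–Altman limits.

**Synthetic data.** Chest phantoms (two ellipsoidal lungs in a
soft-tissue body, normal parenchyma ~ N(−850, 40) HU, fibrotic tissue ~
N(−600, 50) HU, known ground truth measured back from the emitted voxels)
and Gaussian-copula patient cohorts calibrated to a 126-patient SSc
baseline table, so every stage is testable without patient data.

I/O covers uncompressed little-endian single-frame DICOM series (with
rescale-slope/intercept HU calibration and spatial slice sorting) and
NIfTI volumes/masks.

## Worked example

```r
library(fibroscore)

ph   <- generate_phantom(phantom_spec(seed = 7, design_fibrotic_fraction = 0.13))
mask <- segment_lungs(ph$volume)
dice_overlap(mask, ph$truth$lung_mask)
#> [1] 0.9996005
cam_score(ph$volume, mask)
#> <cam_result> pulmonary fibrosis 12.9 % of 30.0 ml lung
#>   voxels: 30024 lung-window = 26157 normal + 3768 ILD + 99 consolidation
```

The segmentation recovers the generator's ground-truth lungs almost
voxel-for-voxel (Dice 0.9996), and the measured fibrosis (12.9 %) sits at
the design fraction (13 %) minus the expected distribution-tail exchange
across the −700 HU cut.

```r
co <- generate_cohort(cohort_spec(n = 126, seed = 7))
cohort_pearson(co, "cam_fibrosis_pct", "dlco_pct")
#> r = -0.465, n = 126, p = 4.2e-08
fit_multivariate(co, "cam_fibrosis_pct",
                 c("age", "sex", "disease_duration", "anti_topo_I", "mrss",
                   "haq_di", "borg", "fvc_pct", "dlco_pct"))
#> <fibro_regression> n = 126, k = 9, multiple R = 0.772, adjusted R2 = 0.564
#>              name coefficient std_error       t r_partial         p
#>               age     0.00499   0.04337  0.1151   0.01068 9.086e-01
#>               ...
#>            haq_di     9.42771   1.40129  6.7279   0.52980 6.870e-10
#>           fvc_pct    -0.18019   0.02441 -7.3821  -0.56536 2.559e-11
#>          dlco_pct    -0.25387   0.03403 -7.4593  -0.56936 1.724e-11
```

In this synthetic cohort the fibrosis score is driven by DLco, FVC and
HAQ-DI — the structure the generator's correlation preset encodes — while
age, sex, disease duration, antibody status and skin score carry no
signal. `render_table1()` / `render_table2()` / `render_table3()` lay the
same numbers out as publication-style tables, and `plot_association()`
draws the score-vs-measure scatter plots.

See the methods vignette (`vignettes/fibroscore-methods.Rmd`) for the
model, the endpoint conventions, the deterministic segmentation rule, and
what the synthetic generators do and do not emulate.

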