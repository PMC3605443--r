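# hepafat

Quantifying hepatic steatosis from rapid in-phase/opposed-phase MRI and
from computer-assisted histology morphometry — with the calibration and
diagnostic statistics that connect the two — as a fully synthetic,
reproducible R pipeline.

## Who this is for

Researchers developing or validating non-invasive liver-fat measurements:
the package provides the complete measurement chain (signal model →
estimator → histology reference → calibration → ROC / agreement
statistics), each stage testable offline against generators with exact
ground truth.

## The methods

**MRI.** A triple gradient-echo acquisition (opposed / in / opposed phase;
TE 2.38, 4.76, 7.14 ms at 1.5 T; TR 88 ms; flip 70°) yields per-slice ROI
intensities OP1, IP, OP2. T2\* is estimated from the two opposed-phase
echoes,

    T2* = (TE3 - TE1) / ln(OP1 / OP2),

and the fat-sensitive parameter alpha is the two-point Dixon fraction with
OP1 decay-corrected to the in-phase echo time:

    alpha = (IP - OP1 * exp(-(TE2 - TE1)/T2*)) / (2 * IP),

averaged over three slices. The acquisition is deliberately T1-weighted,
over-weighting fat to amplify low-fat contrast, so alpha relates to the
fat volume fraction f through the one-parameter calibration

    alpha = k f / (k f + (1 - f)),     d(alpha)/df at f=0  =  k.

**Histology.** The areal fat fraction of a trichrome-stained section is
measured by thresholding the green band at 220 (8-bit), labelling bright
particles, keeping those with area 100–10000 px and circularity
4πA/P² in [0.5, 1] (vacuoles), and dividing the kept area by the
hole-filled tissue area. Circularity uses a chain-code perimeter with
Vossepoel–Smeulders weights so digitised circles are not falsely rejected.

**Statistics.** ROC/AUC (Mann–Whitney form) of alpha against the 5/33/66%
visual steatosis boundaries and against regression-derived morphometric
cutoffs, optimal cutoffs by maximal sensitivity + specificity, exact
binomial CIs, log-scale Bland–Altman limits of agreement with ratio
back-transformation, and the controls' log-scale 95% prediction interval.

## Worked example

```r
library(hepafat)

# one slice of simulated signals at 10% fat, T2* = 22 ms
tr <- simulate_roi_signals(0.10, mri_signal_params(t2star = 22, noise_sd = 0))
sprintf("OP1 %.2f  IP %.2f  OP2 %.2f", tr$op1, tr$ip, tr$op2)
#> "OP1 12.40  IP 15.79  OP2 9.99"
c(estimate_t2star(tr), compute_alpha(tr, estimate_t2star(tr)))
#> 22.000  0.148     # T2* recovered; alpha > f because of T1 weighting

# histology phantom with exact ground truth, measured morphometrically
ph <- generate_histology_phantom(histology_phantom_spec(
  target_fat_fraction = 0.10, seed = 7))
areal_fat_fraction(ph$image)
#> areal fat fraction = 0.1008 (34826 / 345329 px; 18 of 22 particles accepted)
ph$true_areal_fat_fraction   # 0.1008 -- vessels and tears correctly rejected

# a full synthetic cohort (59 patients, 10 controls) and its report
coh <- generate_cohort(n_patients = 59, n_controls = 10, seed = 42)
diagnostic_report(coh)
#> ROC vs visual fat estimate:
#>  threshold cutoff    auc ... sensitivity ... specificity
#>       >=5% 0.0874 0.9195 ...       83.33 ...      100.00
#>       >33% 0.0874 1.0000 ...      100.00 ...      100.00
#>       >66% 0.1430 0.9851 ...      100.00 ...       95.12
#> Calibration: alpha ~ k f / (k f + 1 - f): k = 2.5085, r^2 = 0.847, n = 59
#> log-scale limits of agreement (n = 59):
#>   mean diff -0.006 (sd 0.505)
#>   limits -0.995 (95% CI -1.223 to -0.767) and 0.983 (95% CI 0.755 to 1.211)
#>   ratio bounds 0.370 to 2.672
#> Controls: 95% prediction interval (log scale, n = 10): 0.008 to 0.088
```

Reading the report: alpha separates steatosis grades with AUCs above 0.9
at every boundary; the fitted k ≈ 2.5 means the acquisition amplifies
low-fat contrast 2.5-fold; the ratio bounds say 95% of paired
morphometry/MRI fat measurements fall within a factor ≈ 2.7 of each
other; and the control interval is the healthy reference range of alpha.

## The analysis workflow

Numbered drivers under `analysis/` run the study end to end, writing
tables to `results/`:

| script | stage |
|---|---|
| `01_simulate_cohort.R` | cohort simulation + group comparisons |
| `02_histology_morphometry.R` | phantom generation + morphometric measurement |
| `03_mri_alpha.R` | signal simulation + alpha re-estimation per subject |
| `04_calibration.R` | nonlinear k fit + morphometric cutoff derivation |
| `05_diagnostics.R` | ROC tables, agreement limits, control interval |

`run_pipeline(pipeline_config(out_dir = "..."))` performs the same chain
programmatically and writes a manifest with per-file checksums.

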