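---
title: "Quantifying hepatic steatosis from rapid dual-echo MRI and histology morphometry"
author: "hepafat authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying hepatic steatosis from rapid dual-echo MRI and histology morphometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hepafat)
```

## The measurement problem

Hepatic steatosis — fat accumulating as triglyceride vacuoles inside
hepatocytes — is graded clinically from biopsy sections at the 5%, 33% and
66% thresholds of the fraction of hepatocytes containing fat. The visual
grade is subjective and requires an invasive biopsy, so a rapid MRI
surrogate is attractive. `hepafat` implements, as a tested pipeline driven
entirely by synthetic data, the three measurement layers such a study
needs:

1. a **fat-sensitive MRI parameter** $\alpha$ computed from a triple-echo
   opposed-phase / in-phase / opposed-phase gradient-echo acquisition with
   T2\* correction;
2. a **morphometric reference** — the areal fat fraction of a colour
   histology section measured by threshold / particle / shape-filter
   analysis;
3. the **diagnostic statistics** connecting them: a nonlinear calibration,
   ROC analyses with optimal cutoffs and exact binomial confidence
   intervals, log-scale Bland–Altman limits of agreement, and a log-scale
   prediction interval for healthy controls.

## The MRI signal model and the $\alpha$ estimator

At 1.5 T, water and fat protons precess at slightly different frequencies,
so their transverse magnetizations are **opposed** at echo times 2.38 ms
and 7.14 ms and **in phase** at 4.76 ms. For a water-dominant voxel with
weighted water and fat signals $W$ and $F$, the magnitude signals are

$$\mathrm{OP} = (W - F)\,e^{-TE/T_2^*}, \qquad
  \mathrm{IP} = (W + F)\,e^{-TE/T_2^*}.$$

The two opposed-phase echoes carry identical contrast and differ only by
decay, giving the T2\* estimate

$$T_2^* = \frac{TE_3 - TE_1}{\ln(\mathrm{OP1}/\mathrm{OP2})},$$

and after correcting OP1 to the in-phase echo time the two-point Dixon
fraction is

$$\alpha = \frac{\mathrm{IP} - \mathrm{OP1}\,
  e^{-(TE_2 - TE_1)/T_2^*}}{2\,\mathrm{IP}} \;=\; \frac{F}{W+F}.$$

$\alpha$ is computed per slice and averaged over the (up to three) slices,
exactly in that order: T2\* varies between slices, so the correction must
precede the averaging.

Numerical choices, all of which matter for noisy clinical data:

* **Non-physical decay** (OP1 $\le$ OP2, possible under noise at low fat)
  returns an `Inf` sentinel meaning "no correction" (decay factor exactly
  1); the slice is flagged in `correction_applied` rather than failing the
  subject.
* **Raw $\alpha$ outside $[0,1]$** is clamped to the range; at low fat,
  noise routinely drives the numerator slightly negative.
* With neither T1 weighting nor noise, the estimator inverts the simulator
  exactly (error at machine precision); the test suite asserts
  $|\hat\alpha - f| < 10^{-6}$ over a grid of fat fractions 0.01–0.45 and
  T2\* 5–40 ms, and that $\hat\alpha$ is independent of the simulated T2\*.

### Deliberate T1 weighting

The acquisition (TR 88 ms, flip angle 70°) does **not** try to make
$\alpha$ equal the proton-density fat fraction. Each compartment enters
with the spoiled-gradient-echo steady-state weight
$w = \rho \sin\theta\,(1-E_1)/(1-\cos\theta\,E_1)$, $E_1 = e^{-TR/T_1}$.
Because fat's T1 (default 343 ms) is shorter than water's (default
586 ms), fat is over-weighted, which *increases* the slope of $\alpha$
versus fat fraction at low fat — exactly where the clinically important
5% boundary lives — and keeps image SNR high. The T1 defaults are
literature-typical 1.5 T values chosen by this package, configurable in
`mri_signal_params()`.

One regime caveat the tests exercise: the amplification
$\alpha > f$ holds while fat's *weighted* signal stays below water's,
i.e. $f < 1/(1+k)$ (about 0.39 for the default T1 pair). Beyond that the
opposed-phase magnitude $|W-F|$ folds and the estimator returns $1-\alpha$
territory; the simulator therefore refuses $f > 0.5$ outright, mirroring
the water-dominance assumption under which the method is valid.

## The calibration model

With fat over-weighted by a lumped factor $k$ (T1 weighting times
proton-density ratio), the signal fat fraction becomes

$$\alpha(f) = \frac{k f}{k f + (1 - f)},$$

a bijection of $[0,1]$ onto itself, concave for $k>1$, with initial slope
$d\alpha/df|_{f=0} = k$ — the low-fat contrast gain. Its exact inverse
$f = \alpha / (k - \alpha(k-1))$ converts measured $\alpha$ into an
MRI-derived fat fraction for agreement analysis. `fit_k()` estimates $k$
by deterministic Brent search on $(10^{-3}, 100]$ with tolerance
$10^{-9}$; there is no random initialisation, so fits are reproducible
bit-for-bit. Noiseless data recover $k$ to $10^{-6}$; on noisy cohorts of
59 the tests verify recovery within 10% across 200 seeds against a
brute-force grid refit.

## Histology morphometry

A trichrome-stained section shows fat vacuoles, vessels, ducts and tears
as near-white voids on darkly stained tissue. The measurement proceeds in
four stages:

1. **Threshold**: a pixel is bright iff its green-band value is $\ge 220$
   (8-bit). The comparison is inclusive — the published description does
   not state strictness, so this choice is explicit and configurable.
2. **Particles**: connected bright components (8-connected by default,
   configurable to 4) are labelled deterministically in row-major
   first-pixel order; holes inside a candidate are filled before
   measurement, since a vacuole is a void and should be solid after
   thresholding.
3. **Filter**: keep particles with area in $[100, 10000]$ px and
   circularity $4\pi A / P^2$ in $[0.5, 1]$, all bounds inclusive
   ("between ... and" read inclusively). At 0.5 µm/px the size window is
   equivalent-circle diameters 5.6–56 µm. Oversize blobs (vessels, ducts)
   and elongated streaks (tears) fail one bound each. Border-touching
   particles are kept by default (configurable).
4. **Tissue area**: invert the binary image and fill every hole not
   connected to the border. This re-includes the vacuole and vessel voids
   in the tissue footprint — the denominator is the whole biopsy area, and
   fat is deliberately *not* subtracted from it.

The areal fat fraction `fat_area / tissue_area` equals the fat *volume*
fraction for sections thin relative to vacuole size, which is the
quantity the calibration consumes.

### The perimeter estimator

Circularity is the one quantity where discretisation can silently destroy
the filter: counting exposed pixel edges overestimates a smooth perimeter
by up to $4/\pi$, pushing small digitised circles *below* the 0.5
circularity bound and wrongly rejecting legitimate vacuoles. The default
estimator therefore walks the 8-connected boundary chain and applies the
Vossepoel–Smeulders weights (0.980 per straight step, 1.406 per diagonal
step, −0.091 per corner), which is nearly unbiased on digitised circles;
the tests pin circularity of rasterised circles with diameters 12–120 px
into $[0.88, 1]$. The naive edge-count estimator remains available as
`perimeter = "edges"` (under it a square's circularity is exactly
$\pi/4$). Reported circularity is clipped at 1.

## The synthetic-data generators

### Histology phantoms

`generate_histology_phantom()` composites, on a white slide, a wavy-edged
tissue blob (green channel kept below the threshold), non-overlapping
bright vacuole disks with diameters drawn from a configurable range
(default 8–40 µm at 0.5 µm/px, safely inside the filter window), plus
large roundish "vessels" (area > 10000 px) and thin elongated "tears"
(circularity < 0.5) that a correct filter must reject. Because shapes
never overlap and never touch the tissue boundary, the ground-truth
fraction `fat pixels / tissue pixels` is exact by construction, and the
thresholded binary equals the union of the bright ground-truth masks
pixel-for-pixel — the tests assert both. Vacuole placement resamples until
the achieved fraction is within 10% relative of the target and fails
explicitly when the target is unreachable (small image, coarse vacuole
quantum), rather than under-filling silently.

What the phantom does **not** emulate: staining-intensity variation and
colour gradients of real trichrome sections, partial-volume grey rims
around vacuoles, overlapping or clustered vacuoles, and micro- versus
macrovesicular morphology. Passing the phantom tests therefore
demonstrates correctness of the segmentation *arithmetic*, not robustness
to real-world stain variability. Phantom colour parameters are aesthetic
defaults only.

### Cohorts

`generate_cohort()` emulates a mixed-aetiology hepatology cohort of 59
patients plus 10 lean controls. The visual fat percentage is a stratified
two-component mixture — 58% low-fat subjects (log-normal, median ≈ 2%)
and 42% steatotic subjects (35–98%) — giving a stable sample median near
5% with the heavy right tail such cohorts show. A **latent true fat
fraction** is tied to the visual estimate through a linear link (slope
0.00103 fraction per percent, intercept 0.0088, chosen so the 5/33/66%
boundaries map to morphometric cutoffs near 0.014/0.043/0.077) with
between-subject log-scale sd 0.20. Both tissue measurements then observe
this latent value with their own errors: morphometry with log-normal
scatter (sdlog 0.28, biopsy sampling and sectioning variability) and MRI
as $\alpha = \alpha(f; k=2.6) + \mathcal N(0, 0.02)$, floored at 0.008
(magnitude images have a noise floor, and log-scale agreement analysis
needs positive values).

The latent structure is the deliberate design choice here: if $\alpha$
were generated directly from the *measured* morphometric value, any noise
level small enough to give realistic ROC performance would make the
calibration fit almost perfect ($r^2 \approx 0.96$), which no real
between-method comparison shows. With the latent structure the default
parameters yield calibration $r^2 \approx 0.83$, $\alpha$-versus-visual
$r^2 \approx 0.89$, and log-agreement sd ≈ 0.5–0.6 — jointly plausible
for a 59-patient biopsy-vs-MRI comparison. The default $k = 2.6$ is the
value consistent with median $\alpha \approx 0.07$ at median fraction
$\approx 0.03$ in such a cohort. Controls draw $\alpha$ from a low-fat
log-normal (median ≈ 0.024). All randomness flows from one explicit seed;
equal seeds give bit-identical cohorts.

## Diagnostic statistics

* **AUC** uses the Mann–Whitney pairwise formulation with ties counting
  ½ — identical to trapezoidal integration of the empirical ROC — and is
  verified against an exhaustive pair-counting oracle and against `pROC`.
* **Optimal cutoff** scans all achievable cutoffs (midpoints of sorted
  unique scores plus the two degenerate ends) with positivity
  `score > cutoff`, maximising sensitivity + specificity; ties break
  toward the lowest cutoff, favouring sensitivity. The reference side uses
  ≥ at the first (5%) boundary and > at the upper two.
* **Sensitivity/specificity CIs** are exact Clopper–Pearson, reported in
  percent.
* **Agreement** between morphometry and the MRI-derived fraction is
  assessed on natural logs (the disagreement of fat measurements grows
  with magnitude): limits $\bar d \pm 1.96\,s_d$, limit CIs via
  $SE = s_d\sqrt{3/n}$ with a $t_{n-1}$ quantile, and ratio bounds
  $e^{\text{limit}}$.
* **The healthy reference range** of $\alpha$ is the log-scale 95%
  prediction interval $\bar x \pm t_{0.975}(n-1)\,s\sqrt{1+1/n}$,
  exponentiated. Natural logs are used throughout for consistency with
  the agreement analysis.
* The AUC p-value uses the normal approximation to the Mann–Whitney null;
  group-comparison wrappers (`compare_groups()`) call base R tests and
  claim nothing beyond them.

## Problem sizes and runtime

The shipped analysis scripts and tests use cohorts of 59 + 10, phantoms of
512–768 px square, 100-seed median checks, 200-seed calibration-recovery
checks and 500-draw permutation/simulation checks — sizes chosen so the
full suite completes in well under a minute while keeping Monte-Carlo
tolerances meaningful.

## Known limitations

* The pipeline consumes ROI-mean intensities; it does not simulate 2-D
  k-space, phase maps, field inhomogeneity, or multi-peak fat spectra, and
  it does not parse DICOM.
* Iron-induced T2\* shortening is not modelled as a function of liver iron
  concentration; LIC is carried as metadata only.
* The morphometry does no stain normalisation or colour deconvolution and
  does not distinguish micro- from macrovesicular steatosis beyond the
  size filter.
* $\alpha$ is only interpretable under water dominance ($f < 0.5$, and
  strictly $f < 1/(1+k)$ for the amplification property); fat-dominant
  livers would alias.
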