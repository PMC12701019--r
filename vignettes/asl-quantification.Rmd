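---
title: "Quantifying airway surface layer height from confocal reflection XZ scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying airway surface layer height from confocal reflection XZ scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aslheight)
library(dplyr)
```

## The measurement problem

The conducting airways are covered by a thin (~7 µm) airway surface layer
(ASL) whose height is tightly regulated by epithelial ion transport (CFTR-
mediated Cl⁻ secretion, ENaC-mediated Na⁺ absorption). In cystic fibrosis the
ASL is depleted, and restoring it is the point of CFTR-modulator therapy, so
measuring ASL height on air–liquid interface (ALI) cultures is a core
preclinical readout. The conventional assay labels the ASL with a
rhodamine-dextran bolus — which itself adds volume and perturbs the very
quantity being measured.

Confocal *reflection* microscopy avoids the label entirely. In an XZ scan, a
fraction of the incident laser light is reflected wherever the refractive
index changes along the optical axis:

1. medium → transwell membrane,
2. transwell → cell layer,
3. ASL → air.

An axial line profile through such a scan therefore shows three reflection
peaks. The ASL height is the distance between peaks 2 and 3 minus the
thickness of the cell layer, which is delineated separately by basolaterally
loaded calcein-AM (leaving the ASL untouched):

$$ h_\mathrm{ASL} = (z_3 - z_2) - h_\mathrm{cell}, \qquad
   h_\mathrm{cell} = b - a $$

where $a, b$ are the half-maximum boundaries of the calcein band. The
dye-based method is implemented alongside: there the ASL height is simply the
width $y - x$ between the half-maximum boundaries of the rhodamine band. Both
methods are exposed so that the equivalence of the two can be demonstrated on
the same scans.

## Processing model

Per lateral position the chain is:

1. **Profile extraction** — mean over `width` adjacent columns (default 5:
   noise reduction without blurring lateral tilt).
2. **Peak detection** — local maxima of the reflection profile with
   topographic prominence above `min_prominence` (default 0.1) of the profile
   maximum. Flat-topped maxima caused by detector quantization collapse to
   their midpoint.
3. **Gaussian refinement** — each candidate is refined by a
   Levenberg–Marquardt least-squares fit of a Gaussian plus constant baseline
   in a ±2 µm window, giving sub-pixel peak centres. Fits with $R^2 < 0.9$
   flag the position.
4. **Interface classification** — of the detected peaks, the three most
   prominent (ties broken toward smaller depth) are assigned by ascending
   depth to $z_1, z_2, z_3$. Spurious noise bumps are thereby dropped without
   a tuned exclusion rule.
5. **Half-maximum boundaries** — the baseline is the 5th percentile of the
   fluorescence profile; the plateau reference is the median of the
   baseline-subtracted samples lying in the top decile of the intensity
   range (robust to a bright rim at the air interface); the band edges are
   the outermost crossings of half the reference, linearly interpolated. A
   step edge convolved with the axial point spread crosses half level at the
   true edge, so no deconvolution is needed.
6. **Height and QC** — negative computed heights (possible under noise when
   the ASL is near zero) are clamped to 0 and flagged rather than dropped, so
   well means are not biased upward. Positions failing any stage carry an
   explicit flag and are excluded from summaries; nothing becomes a silent
   `NaN`. The offset between $z_2$ and the calcein lower bound is reported as
   a QC metric (`z2_offset_um`) because the reflection formula couples the
   reflection peaks with the calcein width.

Wells are sampled at 15 pre-defined positions in serpentine order within the
central 60% of the culture (meniscus avoidance); the well value is the mean
over usable positions, reported with SD, SEM, and the coefficient of
variation CV = 100·SD/mean. `subsample_stability()` quantifies how these
summaries change at 10/15/20 positions, the analysis used to justify a
15-position plan.

## The phantom generator

Real cultures cannot ship with a package, so `render_scan()` produces
synthetic XZ scans with exactly known geometry — the oracle for every
recovery test:

* **Reflection amplitudes** follow normal-incidence Fresnel reflectance
  $R = ((n_1-n_2)/(n_1+n_2))^2$ with default indices medium 1.33, transwell
  1.58, cell 1.37, ASL 1.34, air 1.00. This predicts the observed amplitude
  ordering (ASL→air brightest, transwell→cell weakest) from physics rather
  than from tuned constants.
* **Axial blur**: Gaussian point spread with σ = 0.7 µm (the axial
  resolution scale of an NA 0.75 water-immersion objective at 488 nm);
  fluorescence bands are ideal plateaus convolved with the same kernel,
  rendered in closed form via the Gaussian CDF.
* **Noise**: additive Gaussian with SD expressed as a fraction of the
  brightest peak (default 0.05). A single noise knob keeps recovery
  tolerances interpretable; Poisson shot noise is deliberately omitted.
* **Tilt**: a linear interface-depth drift across the lateral field (µm per
  field) emulating a non-level insert; per-column offsets are recorded in
  the ground truth.
* **Quantization**: intensities are clamped to [0, 1] and quantized to 16
  bits, as a detector would; this also makes TIFF round trips bit-exact.
* **Geometry**: depth 0 at the first stack plane, z increasing toward air;
  default z-step 0.2 µm/pixel (configurable — voxel size is an acquisition
  choice, not a constant of the method).

`volume_challenge_series()` renders a time series in which the true ASL
height relaxes as a single exponential
$h(t) = h_\infty + (h_0 - h_\infty)\,e^{-t/\tau}$ toward steady state after an
apical volume challenge. The exponential is a simulation convention — the
functional form of reabsorption is not asserted as biology — chosen as the
simplest monotone relaxation with one time constant.

What the phantom does **not** emulate: lateral point spread, refraction and
spherical aberration through tilted interfaces, mucus versus periciliary
sublayers (reflection cannot distinguish them on real cultures either),
meniscus curvature, and photobleaching. Passing recovery tests therefore
demonstrates correctness of the *analysis*, not of the optics of any
particular microscope.

## Worked example

```{r phantom}
cfg <- phantom_config(asl_height = 8.8, noise_gaussian_sd = 0.05, tilt = 1)
scan <- render_scan(cfg, seed = 42)
scan

meas <- measure_scan(scan, method = "reflection", well_id = "wt_1")
summarize_well(meas)
```

The recovered well mean sits within a fraction of a z-step of the configured
8.8 µm truth. Method equivalence on the same scan:

```{r equivalence}
flu <- measure_scan(scan, method = "fluorescence", well_id = "wt_1")
compare_groups(meas$asl_um, flu$asl_um, "paired_t")
```

Group statistics use two-tailed t or Wilcoxon signed-rank tests with the
two-stage linear step-up FDR adjustment (Benjamini–Krieger–Yekutieli):

```{r stats}
bky_adjust(c(0.001, 0.02, 0.9))
percent_of_control(8.4, 13.5)
```

## Numerical and design choices

* **1-based indices.** All lateral/axial indices are 1-based, following R
  convention; depths reported to users are always in µm.
* **Plateau reference.** The half-max reference uses samples in the top
  decile of the intensity *range* rather than the top 10% by count; on a
  plateau band the two coincide, but the range definition also behaves
  correctly for sharply peaked bands and keeps the triangle profile's
  half-max at exactly half its apex.
* **Prominence, not height.** Peak candidacy uses topographic prominence so
  a shoulder on a bright peak does not register as an interface.
* **Clamping, not dropping.** Negative heights are evidence about noise near
  zero ASL; dropping them would bias well means upward.
* **Degenerate statistics.** A paired comparison with all differences zero
  reports statistic 0, p = 1 (no effect) instead of erroring.
* **Sampling plans.** Default 3×5 serpentine grid over the central 0.6 of
  the field; the exact grid geometry of a physical stage plan is an
  acquisition choice, so rows, columns and central fraction are parameters.
* **Mixed models are out of scope.** Repeated-measure designs (sequential
  drug additions within a well) should be exported — the per-position CSV is
  tidy for exactly this — and analysed with `lme4`/`emmeans`; the package
  implements only the tests it owns end-to-end.
* **Problem sizes.** The bundled tests run phantoms of 300×160 pixels with
  15–20 positions and Monte-Carlo loops of 200–1000 replicates; these sizes
  give stable statistics while keeping the suite interactive.

## Limitations

Reflection imaging reports a single air-facing interface: mucus accumulation
and periciliary-layer change are indistinguishable without supplemental
labels. The phantom's Fresnel amplitudes assume normal incidence and ignore
multiple reflections; both are second-order for the thin, nearly
index-matched layers simulated. Proprietary microscope containers are not
read — convert to TIFF first.
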