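# aslheight

Label-free quantification of airway surface layer (ASL) height from confocal
reflection XZ scans.

## The problem

The airways are lined by a thin (~7 µm) liquid film — the airway surface
layer — whose height reflects the balance of CFTR-mediated Cl⁻/fluid
secretion and ENaC-mediated Na⁺/fluid absorption. ASL depletion drives
muco-obstructive disease (cystic fibrosis foremost), and ASL height on
air–liquid interface cultures is a standard preclinical readout for ion
channel modulators. The conventional assay adds a fluorescent dextran bolus
to the apical surface — a volume perturbation of the very layer under study.
Confocal *reflection* microscopy measures the layer without any label: light
reflects wherever the refractive index changes along the optical axis, so an
axial line profile shows peaks at (1) medium→transwell, (2) transwell→cell
and (3) ASL→air, and

```
ASL height = (z3 − z2) − cell height
```

with the cell-layer thickness taken between the half-maximum boundaries of a
basolaterally loaded calcein-AM band. This package implements that analysis
for anyone running the assay: Gaussian sub-pixel peak fitting, half-maximum
edge detection, serpentine multi-position sampling, per-well summaries with
CV, subsampling stability, group statistics with two-stage step-up FDR
adjustment — plus a physics-based phantom generator (Fresnel interface
amplitudes, axial PSF blur, detector noise, lateral tilt) that provides
exact ground truth for every step.

## Worked example

```r
library(aslheight)

cfg  <- phantom_config(asl_height = 8.8, noise_gaussian_sd = 0.05, tilt = 1)
scan <- render_scan(cfg, seed = 42)
scan
#> <asl_scan> 300 z x 160 x pixels, z-step 0.2 um, channels: reflection, calcein, rhodamine
#>   truth: z1=4.00 z2=14.00 z3=37.80, cell 15.00 um, ASL 8.80 um

meas <- measure_scan(scan, method = "reflection", well_id = "wt_1")
summarize_well(meas)
#> # A tibble: 1 x 9
#>   well_id time_min method     n_positions n_flagged mean_um  sd_um sem_um cv_pct
#> 1 wt_1           0 reflection          15         0    8.80 0.0510 0.0132  0.580
```

The phantom was rendered with a true ASL of 8.8 µm under 5% detector noise
and 1 µm of lateral tilt; the 15-position reflection pipeline recovers a
well mean of 8.80 µm with a CV of 0.6%. The dye-based method on the same
scan agrees:

```r
flu <- measure_scan(scan, method = "fluorescence", well_id = "wt_1")
compare_groups(meas$asl_um, flu$asl_um, "paired_t")
#> # A tibble: 1 x 6
#>   test       n_a   n_b estimate statistic p_value
#> 1 paired_t    15    15 -0.00157    -0.128   0.900
```

i.e. a mean method difference of 0.002 µm, not significant — the in-silico
counterpart of the label-free method's validation against the conventional
protocol.

A thin command-line surface wraps the same functions
(`inst/cli/asl.R`, subcommands `simulate`, `measure`, `aggregate`,
`compare`); stacks are plain multi-file TIFF directories with a YAML
sidecar, outputs are tidy CSVs plus a JSON run manifest, and identical seeds
reproduce every output byte for byte.

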