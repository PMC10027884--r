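# arcdose

Simulation and evaluation pipeline for studying how **linear interpolation
reconstructs volumetric radiotherapy doses** from planar ion-chamber-array
measurements acquired during rotational (VMAT) delivery, and how detector
spacing, spatial sampling density, structure volume, and tissue mass-density
heterogeneity govern the accuracy of the reconstructed dose-volume-histogram
(DVH) metrics.

It is written for medical physicists and methodologists who want a fully
synthetic, reproducible testbed for patient-specific QA dose reconstruction:
no clinical measurements or DICOM data are needed — every input (phantom,
beams, detectors, structures) is generated by code under a seed.

## What it models

During a VMAT arc, a 2D ion-chamber array held perpendicular to the beam
records a planar dose at each gantry control point. Commercial QA systems
turn those sparse planes into a volumetric dose by linear interpolation and
percent-depth-dose (PDD) scaling, then compare reconstructed DVH metrics with
the planned ones. The package implements that chain end to end:

* **Detector arrays** — the three commercial lattices: a 27 x 27 square grid
  at 10 mm pitch (729 chambers), an interleaved 27 x 27 + 26 x 26
  checkerboard at 7.07 mm (1405 chambers), and a 32 x 32 grid at 7.62 mm
  with corner chambers removed (1020), plus custom lattices.
* **Geometry** — cartesian/cylindrical transforms (`r = sqrt(x^2+y^2)`, the
  three-branch azimuth rule, reduced to `[0, 2*pi)`) and gantry rotation
  about the phantom axis.
* **Synthetic ground truth** — an analytic parallel-beam arc model: flat
  in-field profiles with logistic penumbra, depth factors from a
  buildup-then-exponential PDD family evaluated at the radiological depth
  `int rho dl` through water phantoms with optional lung-like inserts.
* **Measurement** — per-control-point chamber sampling (point or
  volume-averaged), multiplicative noise, and low-dose-rate dropout
  (readings below 5 cGy/min become explicit no-response markers).
* **Reconstruction** — two-point linear interpolation
  `phi(x) = (x-x1)/(x0-x1) y0 + (x-x0)/(x1-x0) y1`, bilinear interpolation
  (equal to the weighted average of the four diagonal rectangle areas),
  checkerboard gap filling, angular re-interpolation along the rotation,
  PDD depth extension, and per-beam accumulation onto a 2.5 mm (or 2.0 mm)
  voxel lattice.
* **DVH metrics** — cumulative DVHs and the ICRU-83 family
  (D98/D95/D50/D2/D1, Dmean, Dmax, V5...V50), with `D_p` defined as the dose
  exceeded by exactly p% of the volume.
* **Evaluation** — absolute percent deviations
  `Pdd% = |(D_recon - D_truth)/D_truth| x 100`, bootstrap confidence
  intervals, and a Shapiro–Wilk-gated paired t / Wilcoxon comparison,
  driving five scripted experiments (spacing, heterogeneity, Nyquist,
  small-volume, dropout).

## Worked example

```r
library(arcdose)

grid    <- grid_spec(c(109, 109, 109), 2.5)        # 2.5 mm over 27 cm
pdd     <- make_pdd_table()                        # 4/10/26 cm PDD curves
phantom <- make_density_phantom("cylindrical", "homogeneous", grid)
plan    <- make_plan(24, arc = c(0.4, 0.4 + 220 * pi / 180),
                     field_range_cm = c(4, 12), seed = 2024)

truth <- ground_truth_dose(plan, phantom, pdd, grid)
arr   <- detector_array("octavius729")
ms    <- measure_plan(plan, phantom, pdd, arr)     # 24 planes x 729 chambers
recon <- reconstruct_volume(ms, arr, pdd, plan, target = grid)

rois <- make_roi_set(grid, list(
  list(name = "ptv", role = "PTV", shape = "sphere",
       centre_mm = c(0, 0, 0), radius_mm = 25)))
d_t <- truth$values[rois$ptv$mask]
d_r <- recon$values[rois$ptv$mask]
pdd_percent(dvh_metric(d_r, "Dmean"), dvh_metric(d_t, "Dmean"))
#> [1] 0.7343731
```

The 0.73% is the absolute percent deviation of the PTV mean dose introduced
by 10-mm-pitch sampling plus linear interpolation for this plan. Running the
same plan through the 7.07 mm checkerboard array (`"octavius1500"`) gives
0.58%, the spacing effect the experiments quantify systematically. The
numbered drivers under `analysis/` reproduce the full study:
`01_simulate.R` (scene and ground truth), `02_reconstruct.R` (measurement
export and reconstruction accuracy), `03_dvh_deviation.R` (per-metric Pdd%
tables), `04_experiments.R` (the five 20-plan experiments with paired
tests), writing their tables under `results/`. For example, experiment
output at master seed 42:

```
<experiment_report> scenario 'spacing' (seed 42)
  octavius1500   mean Pdd% = 0.423 (SD 0.178, 95% CI 0.348-0.500, n = 20)
  octavius729    mean Pdd% = 0.622 (SD 0.242, 95% CI 0.517-0.726, n = 20)
<paired_comparison> paired t-test on 20 pairs: statistic -9.189, p = 2.02e-08 (significant at alpha = 0.05)
```

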