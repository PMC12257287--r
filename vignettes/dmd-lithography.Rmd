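---
title: "Planning, simulating and checking DMD maskless photolithography jobs"
author: "dmdlitho"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning, simulating and checking DMD maskless photolithography jobs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dmdlitho)
```

## The workflow this package models

A standard fluorescence microscope fitted with a digital micromirror device
(DMD) and a UV LED can pattern light-curable resin spin-coated on a glass
slide: wherever the projected pattern exposes the film past a dose
threshold, the resin hardens; the rest washes away. Structures larger than
one field of view (FOV) are built by stepping the motorised stage and
projecting successive DMD frames. `dmdlitho` implements the computational
side of that workflow — optical and dosimetric arithmetic, spin-coat
thickness calibration, decomposition of a physical-units design into an
ordered exposure sequence, a virtual printer, and quantitative quality
control of printed line grids — and runs it end to end against a simulated
microscope driver, so every part is testable without hardware.

## Optics and dosimetry

The projected pixel size of a DMD through an objective is measured, not
calculated: the projection width divided by the DMD column count
(`dmd_pixel_size()`). Two independent measurements of the same 20x setup
give 0.7 um/px (560 um over 800 columns) and 0.702 um/px (421.2 um over
600 rows); both are honoured through each objective's
`measured_pixel_size_um` field, and the package does not pick a winner.
The bundled reference objective uses 0.702 um because scaling that value by
the magnification ratio (`scale_pixel_size()`) reproduces the full
reference pixel-size column (3.51 / 0.70 / 0.35 / 0.14 um at 4x / 20x /
40x / 100x) at two-decimal rounding, which 0.700 does not.

Depth of focus uses the standard scalar approximation
$\Delta z = n\lambda/\mathrm{NA}^2$ (`depth_of_focus()`), with $n$ the
immersion index (1.0 air, 1.515 oil) and $\lambda$ the exposure wavelength
in micrometres. It is an order-of-magnitude guide, not a wave-optics
computation: in practice layers far thicker than $\Delta z$ still print
accurately, so the number informs objective choice rather than gating any
computation.

Two linear power models are provided. LED output is assumed proportional to
the percent setting (`led_power()`); linearity below roughly 10% output is
an extrapolation the calibration did not probe. Delivered power versus the
fraction of ON DMD mirrors is affine (`dmd_power()`, slope 2.71 mW per unit
fraction, intercept -0.02 mW by default); because the tiny negative
intercept is a fit artifact, predicted power is clamped at zero.

Energy is `power x time / 1000` (mJ) and dose is energy per illuminated
area (mJ/mm^2). No intermediate rounding is applied anywhere in the chain —
rounding the 1.3616 mW power to 1.36 before multiplying would shift the
0.478 mJ/mm^2 dose to 0.477. `exposure_time_for_dose()` inverts the chain
exactly, which is how a job config expressed as a target dose (around
0.5 mJ/mm^2 works well across layer heights) becomes an exposure time.

## Spin-coat calibration

Film thickness follows $h(\mathrm{RPM}) = a/\sqrt{\mathrm{RPM}} + h_0$.
The offset term matters over a wide spin range (roughly 200–3200 RPM):
without it the reference calibration drops from $R^2 = 0.96$ to $0.90$
(documentation values; the raw points behind them are not available, so the
package treats them as context, not targets). After substituting
$x = \mathrm{RPM}^{-1/2}$ the model is linear in $(a, h_0)$, so
`fit_spin_curve()` is closed-form ordinary least squares — no optimiser, no
convergence tolerance. $R^2$ is defined as $1 - SS_{res}/SS_{tot}$ with
$SS_{tot}$ about the sample mean, also in the forced-zero-offset case,
so the two variants are comparable on one scale.

Stacking accuracy is checked through the layer constant
$c = h\sqrt{\mathrm{RPM}}$, which the model predicts is invariant across
spin speeds. Comparing a single-layer print against a stacked dual print,
the package reports the symmetric relative difference
$100\,|c_1 - c_2| / \bar c$ (`multilayer_error()`). The mean denominator is
a deliberate choice: it is symmetric in the two prints (neither is the
"reference") and it reproduces the reported 4.93% check from the measured
depths (43.93 um at 120 RPM; 69.77 um total, 34.885 um per layer, at
210 RPM), where a $c_1$ or $c_2$ denominator gives 5.05% or 4.81%.
Fluid-dynamic effects (viscosity drift, evaporation) are outside the model;
the calibration absorbs them empirically.

## Tiling and registration

One coordinate convention holds everywhere: x grows rightward with raster
columns, y grows downward with raster rows, the design origin is its
top-left corner, and pixels are half-open intervals. This eliminates the
usual flip bugs between camera, DMD and stage frames.

`plan_tiles()` covers the design with abutting FOV-sized tiles
(`ceil(extent / FOV)` per axis), visited in serpentine order so consecutive
exposures always differ by one stage step — the minimal axis-aligned
traversal. Frames are resampled nearest-neighbour: a DMD mirror is ON iff
its centre falls inside an ON design pixel. The DMD is binary, so
anti-aliasing has no meaning here. Tiles whose frame contains no ON pixel
are skipped (recorded in the plan's `skipped` attribute) to save stage
moves. The scan order and overlap used on the real instrument are not
constrained by the workflow itself; serpentine order and zero overlap are this
package's choices, with an `overlap_um` option whose overlapping ON pixels
simply expose twice.

Multilayer jobs are registered on a printed fiducial marker.
`align_to_fiducial()` computes FFT-based normalized cross-correlation over
all integer translations and reports the offset of the best match in
micrometres, flagging peak correlations below a configurable threshold
(default 0.5) so a failed match is visible rather than silently wrong. A
flat (zero-variance) template is an error, not a zero offset.

## The virtual printer

`simulate_print()` deposits, per exposure,
`power x time / 1000 / FOV-area` uniformly on every substrate cell whose
centre lies under an ON mirror, then convolves the accumulated map with a
Gaussian point-spread approximation. Defaults, and why:

* **Substrate pitch** — half the projected DMD pixel (Nyquist with respect
  to the frame raster), so frame geometry survives resampling.
* **PSF sigma** — 0 by default; `psf_sigma_default()` offers
  $0.21\,\lambda/\mathrm{NA}$, a Gaussian approximation of the
  diffraction-limited spot. It is configurable because real printed
  resolution (about 5 um at 20x) is well above the diffraction limit, due
  to DMD mirror-edge artifacts the simulator does not model.
* **Stage jitter** — independent Gaussian offsets per exposure, default SD
  1 um when enabled, motivated by the sub-2-um pitch scatter observed on
  real stitched prints. Jitter is seeded; with the same seed the map is
  bit-identical.
* **Borders** — the blur uses zero padding with a kernel normalized to unit
  sum, so total dose is conserved for structures away from the edges;
  conservation checks exclude a margin of a few sigma.

`cure()` thresholds the dose map (cured iff dose >= threshold; the boundary
cell cures, a tie-break that keeps the noiseless round trip exact). No
per-resin cure threshold is documented by resin vendors; 0.5 mJ/mm^2 is adopted as the
default from the dose range that prints well, and every function takes an
explicit threshold. Resist kinetics, oxygen inhibition and z-profiles
(sidewall shape) are out of scope.

`synth_grid_image()` renders the fixture the QC tests run on: dark
horizontal and vertical lines on a bright background with per-line Gaussian
positional jitter, optional global rotation and additive pixel noise, and
returns the exact post-jitter line positions. It emulates the geometry and
noise of a stitched-grid micrograph but not shading, blur, uneven
illumination or stitching seams — so green QC tests demonstrate correctness
of the measurement pipeline on known geometry, not robustness to every
real-world imaging artifact.

## Grid quality control

`qc_grid()` runs the standard quantitative analysis of stitched line prints:
upscale (bicubic, default 4x), binarize (Otsu; line polarity configurable),
skeletonize (Zhang–Suen thinning to 1-px curves), detect segments with the
progressive probabilistic Hough transform, classify as horizontal
(|angle| <= 45 deg) or vertical, group by midpoint coordinate along the
dominant axis (1-D single linkage; a gap beyond the tolerance starts a new
bar), and represent each group by the maximally distant pair among its
pooled endpoints — one merged line per physical bar. Orientations are
reported as deviation from the assigned axis so both axes share one
misalignment scale; pitch is the spacing of adjacent merged-line midpoints
converted with the known pixel size and upscale factor.

The detection parameters are not fixed by the analysis itself, so they are
exposed in the API with these defaults: Otsu binarization, upscale 4,
Hough threshold 10 votes, minimum segment length 25% of the shorter image
side, maximum gap 5 px (all post-upscale), grouping tolerance half the
expected pitch when one is supplied, else 10 px. Detection randomness is
seeded, so reports are reproducible.

Known limitation: with a 1-degree Hough angular grid on a thinned
staircase skeleton, walks lock onto axis-aligned runs once the grid is
rotated by about a degree or more. Orientation estimates are therefore
trustworthy in the sub-degree misalignment regime — which is the QC use
case, stitching misalignment — and the pipeline is not intended for
deliberately rotated or non-orthogonal patterns.

## Problem sizes and determinism in the shipped tests

The test suite builds all fixtures in code: grids of 8–20 lines at 50 um
pitch and 0.7 um pixels analysed at upscale 2, tiling designs of about
100 x 120 design pixels on a 40 x 50 mirror DMD, and ten-point calibration
tables. These sizes were chosen so each property is exercised on
non-trivial geometry while the whole suite stays quick to run. The noisy
calibration tolerance (10% on $a$ at $n = 10$, $\sigma = 2$ um) was fixed
in advance by a 1000-replicate Monte-Carlo run at those exact conditions
(observed maximum relative error 8.8%). Every stochastic step — jitter,
noise, probabilistic detection — takes an explicit seed, and all seeded
paths are bit-reproducible.

## Running a job

```{r, eval = FALSE}
cfg <- read_job_config("job.yml")   # objectives, dmd, light_source, job
res <- run_job(cfg)                 # plans, exposes, simulates, writes
res$cure                            # simulated cured structure
```

A job config names an objective, a design mask (PNG/TIFF plus its pixel
pitch in um) and either a fixed exposure time or a target dose with an LED
fraction; `run_job()` validates everything before the first driver call,
executes move-then-project per exposure against the (by default simulated)
driver, and writes the plan JSON, stage CSV, dose and cure TIFFs and a
structured log. With a fixed seed the plan JSON and stage CSV are
byte-identical across runs. The `inst/cli/litho.R` script exposes the same
operations as shell subcommands (`litho plan`, `litho simulate`,
`litho qc grid`, `litho spincoat fit|rpm`, `litho optics`, `litho run`).
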