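---
title: "Methods: ratiometric optode imaging of cellular oxygen consumption and acidification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ratiometric optode imaging of cellular oxygen consumption and acidification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optomet)
```

## Overview

`optomet` turns two-channel sensor-foil (planar optode) image stacks into
calibrated pO₂ / pH maps, per-cell oxygen consumption (OCR) and
extracellular acidification rates (ECAR), spatial maps of metabolically
active regions, and group comparisons. Because real instrument data are
large and instrument-specific, the package carries its own physics: a
micro-respirator simulator whose ground truth every analysis stage is
tested against. This vignette records the models, their assumptions, the
parameters that matter, and the design decisions taken where the
measurement conventions of the field leave the algorithm open.

## The micro-respirator model

When a sensor-foil-covered plunger is lowered onto an adherent cell layer,
a thin medium film of height $h$ is trapped between cells and foil.
Within it we model each analyte field $F(x, t)$ (pO₂ in % air saturation,
or pH) as an effective two-dimensional reaction–diffusion system:

$$\frac{\partial F}{\partial t} = D_{\mathrm{eff}} \nabla^2 F
  \;-\; k\,\rho(x)\,\frac{h_{\mathrm{ref}}}{h},$$

with zero-flux (Neumann) boundaries at the edge of the imaged field.

* $\rho(x)$ is the areal cell density (cells/cm²), piecewise constant over
  the scene's patches.
* $k$ is an effective per-cell sink coefficient — (% air-sat/s) per
  (cells/cm²) for oxygen, (pH/s) per (cells/cm²) for acidification — *at
  the reference chamber height*. It lumps cellular uptake/extrusion,
  medium capacity and (for pH) buffering into one identifiable number:
  only the product $k\rho$ is observable in a depletion curve.
* The chamber height enters **only** through $h_{\mathrm{ref}}/h$: halving
  the trapped volume doubles the apparent depletion rate. This is the
  minimal model reproducing the micro-respirator rationale (a thinner film
  makes metabolism visible faster); the real film height under a lowered
  plunger is an unknown of such instruments, so heights here are free
  simulator parameters, not estimates.
* Oxygen is clipped at 0 (full local depletion); pH is an unclipped
  deviation field — no CO₂/bicarbonate chemistry is modelled, because only
  pH trajectories are observable and proton/buffer speciation would not be
  identifiable from them.

Integration is forward Euler with automatic sub-stepping to the explicit
stability bound $\Delta t \le \Delta x^2 / 4 D_{\mathrm{eff}}$; exceeding a
sub-step budget is a configuration error rather than a silent slowdown.
Forward Euler is adequate because the grids are small (tens of pixels) and
the fields smooth; the test suite pins conservation under pure diffusion to
$10^{-9}$ relative and the sink mass balance to $10^{-6}$.

The default *study condition* used across the validation experiments is a
confluent monolayer at 66,000 cells/cm² — the detection-limit density for
tumour-cell patches in small silicone inserts (2000 cells on 0.03 cm²) —
with $k_{O_2} = 7.6\times10^{-7}$ so that the patch depletes at
$\approx 0.05$ %O₂/s at reference height, a rate that makes dense tumour
patches visible in minutes, consistent with the qualitative behaviour the
instrument class is built for.

## Forward optical model and camera noise

The foil is read out ratiometrically: an analyte-sensitive channel divided
by a reference channel cancels common-mode illumination and dye loading.
The renderer writes, per pixel,

$$I_{\mathrm{ref}} = s\,G_0, \qquad
  I_{\mathrm{sens}} = R(F(x))\, M(x)\, s\, G_0,$$

where $R(\cdot)$ is the calibration's forward model, $s$ an exposure
scale, $G_0$ a baseline intensity (1000 camera units), and $M(x)$ a
strictly positive *illumination mismatch* field — the spatial bias that a
one-point adjustment later has to remove; it is applied to one channel
only, since bias common to both channels cancels in the ratio and would be
invisible. Noise is the standard CMOS approximation: a shot-like
multiplicative term with SD $\propto \sqrt{I}$ plus additive Gaussian read
noise, both per channel and per pixel, floored at zero. All stochastic
rendering is a pure function of (scene, acquisition, seed).

Typical short-term protocols drive the defaults: 20-s frame intervals over
10–60 min for oxygen, 10-s intervals over 30 min for pH.

## Calibration models

The instrument class delegates calibration to closed vendor software; this
package fixes the two standard optode forms explicitly and records them in
the serialised calibration files:

* **Oxygen — Stern–Volmer collisional quenching**:
  $R(C) = R_0/(1 + K_{sv} C)$, $C$ in % air saturation. Two points — a 0%
  point from sulfite-saturated solution and a 100% point from
  air-saturated medium — give the closed form $R_0 = R_{0,\mathrm{obs}}$,
  $K_{sv} = (R_{0,\mathrm{obs}}/R_{100,\mathrm{obs}} - 1)/100$; with more
  points the model is linear in $C$ on the $1/R$ scale and fitted by least
  squares. Equal or inverted ratios (no quenching) are calibration errors.
* **pH — 4-parameter log-sigmoid**:
  $R(\mathrm{pH}) = R_{\mathrm{acid}} + (R_{\mathrm{base}} -
  R_{\mathrm{acid}})/(1 + 10^{s(\mathrm{p}K_a - \mathrm{pH})})$, fitted by
  Levenberg–Marquardt nonlinear least squares to ≥ 4 buffer points
  (typically six between pH 5 and 8.5 at 40 mM buffer capacity), started
  from the extreme points (asymptotes), the mid-ratio crossing (pKa) and
  $s = 1$. A non-convergent or non-monotone fit on [5, 8.5] errors with
  diagnostics.

Inversion clamps rather than errors: ratios above $R_0$ (transient
super-saturation or noise excursions at frame level) clamp to 0% with a
flag; pH ratios outside the open asymptote interval clamp to the nearest
*calibrated* endpoint pH. One calibration object serves a whole foil batch
(each batch is calibrated separately); spatial bias is the OPA's job, not
the calibration's.

## Image pipeline and its fixed order

The conversion order is fixed as **ratio → OPA → smooth → calibrate**:

* the division guard defaults to 1% of the reference channel's dynamic
  range; ratios at weaker reference pixels are NaN with an `invalid` flag;
* the OPA is a multiplicative correction *in ratio space*, fitted as
  expected/observed from an image of a plate holding one known analyte
  value everywhere (per pixel, or per well on a plate layout); its median
  factor must sit in a [0.5, 2] sanity band;
* the noise filter is a Gaussian blur of $\sigma$ = `smoothing_factor`
  pixels (the instrument convention "smoothing factor 2" reads as
  $\sigma = 2$ px; whether the vendor filter is Gaussian, median or
  bilateral is not documented — Gaussian was chosen and its semantics are
  exposed). It is a *normalised convolution*: invalid pixels carry zero
  weight, so means near gaps stay unbiased. Smoothing runs on ratio maps
  because that is where the noise is generated; the nonlinear calibration
  inversion does not commute with blurring, and the suite asserts the
  difference;
* calibration inversion is per-pixel with flag propagation.

ROI means use valid pixels only; a timepoint whose valid fraction falls
below 50% becomes a flagged gap rather than a silently dropped row. Well
extraction averages circular discs (radius 80% of half the well pitch) in
row-major A1…H12 order.

## Kinetics: linear range, slopes, normalisation

OCR and ECAR are slopes of the linear range of the ROI trajectory. The
measurement convention only says "a linear regression was calculated for
the linear range"; the selection rule is this package's definition, stated
so it can be overridden: among all contiguous windows of length
$\ge \max(\texttt{min\_points}, \texttt{min\_fraction}\cdot T)$ (defaults
10 and 0.3) whose OLS $r^2 \ge 0.99$, take the longest, ties to the
earliest start; if none qualifies, report the best minimum-length window
flagged `sub_threshold` so manual override remains possible. The slope
itself is closed-form OLS from prefix sums (validated against `lm()` to
$10^{-10}$), with $r^2 := 0$ on zero-variance windows.

Normalisation follows the field's factors, with signs chosen so that
consumption and acidification are positive:

$$\mathrm{OCR} = \frac{-\text{slope}\,[\%\mathrm{O}_2/\mathrm{s}]}{\text{cells}}\times 10^7,
\qquad
\mathrm{ECAR} = \frac{-\text{slope}\,[\mathrm{mpH/min}]}{\text{cells}}\times 10^4,$$

where the fitted pH/s slope converts to mpH/min by ×60,000. The unit chain
is explicit in the result row because mixing per-second acquisition with
per-minute reporting is the classic source of silent 60× errors.

## Nuclei counting

Cell numbers for normalisation come from Hoechst-stained nucleus counts:
median background subtraction, Otsu threshold (floored at 5× the image MAD
so that pure-noise images segment nothing), 8-connected components,
area gates, optional border exclusion, and declumping. Two declump modes
are provided: `intensity` (watershed on the smoothed fluorescence
landscape — the usual and default choice for nuclei, and the most accurate
on the generator's fixtures) and `watershed` (watershed on the Euclidean
distance transform, shape-based, tolerance 0.2 px because nuclear-scale
distance saddles are sub-pixel). Tile scans sum per-tile counts; border
exclusion applies only to outer borders, while interior tile edges assign
each object to the tile owning its centroid, with the ownership boundary
in the middle of the overlap strip.

The nuclei renderer draws Gaussian spots (default $\sigma = 1.2$ px at the
default 5 µm/px tile scale, i.e. a ≈ 6 µm nucleus radius) with an optional
hard-core minimum separation. The counting benchmark uses a sub-confluent
monolayer (20,000 cells/cm²) with a 4-px (≈ 20 µm) minimum separation —
real nuclei cannot interpenetrate, while an unconstrained Poisson process
places arbitrarily close pairs that no 5-µm-pixel counter could resolve;
the unconstrained mode remains available and is used for the renderer's
additivity tests.

## Spatial detection

Active regions are detected as depressions below a robust background —
median (optionally of pixels outside a provided cell mask) minus the pixel
value — thresholded at $k\cdot\mathrm{MAD}$ (default $k = 5$) or an
absolute value, filtered to components of at least 0.1 mm². A robust
*relative* statistic is used because baseline pO₂/pH drifts between wells
and the experimental readout identifies regions visually against their
surroundings, not on an absolute scale. Region labels are deterministic
(reading order of each component's first pixel). Time-to-detection is the
first timestamp at which a detected region overlaps the ground-truth mask
with IoU ≥ 0.3; a single region "matches" at IoU ≥ 0.5. Both IoU levels
are operational definitions introduced here — the experimental literature
reports visual detectability only — and the specific detectable colony
sizes reported for real cell lines (0.5–1.3 mm²) depend on biology and
optics that a simulator cannot claim; the suite therefore tests
*qualitative* detection behaviour (detectability of the 66,000 cells/cm²
condition within 10 minutes, monotonicity in density, threshold and
measurement duration), not those literal sizes.

## Statistics

Group comparisons of normalised rates use classical equal-variance one-way
ANOVA with post hoc Tukey HSD (Tukey–Kramer for unbalanced groups), exactly
the stated experimental procedure — no Welch correction. Each replicate
value is treated as one observation ("n" in the field's figures means
independent experiments). Degenerate all-identical data define $F = 0$.
Stars follow the convention: `*` < 0.05, `**` < 0.01, `***` < 0.001,
`****` < 0.0001. The suite calibrates the type-I error on 10,000 null
simulations, checks the two-group Tukey p against the pooled t-test
($q = \sqrt{2}\,|t|$), and compares ANOVA p to the exact permutation
distribution of F at tiny n.

## Pipeline, formats, determinism

`run_pipeline()` executes the stages in fixed order from a schema-validated
YAML configuration (unknown keys are rejected by name) and writes: the raw
stack as 16-bit multi-page TIFF with a JSON sidecar (page pairs per
timepoint, intensity scale, timestamps, channel roles, batch), nuclei
images as 16-bit TIFF, ground truth and all tables as RFC-4180 CSV with
the documented headers, heat maps as PNG with a pinned value→colour
mapping, and a manifest with MD5 checksums of every product. All
randomness flows from the single config seed through fixed per-stage
substreams, so identical configurations yield identical checksums — the
suite asserts this on the shipped demo configuration. The demo uses
sub-confluent densities (20,000 / 6,000 cells/cm²) so that its nuclei
counts sit in the counter's accurate regime; problem sizes throughout the
validation experiments (30–40 px grids, 31-frame stacks, 20-seed
replications) were chosen as the smallest scenes that still exhibit each
effect clearly.

## What passing tests do and do not show

The simulator reproduces the *mechanisms* the analysis relies on —
ratiometric readout, illumination bias, camera noise, diffusion-limited
depletion, nucleus-scale image statistics — under a known ground truth.
It does not reproduce real cell biology: no growth or motility during a
measurement, no photobleaching, no CO₂ equilibria, no 3-D diffusion
through the medium column, and sink coefficients are invented stand-ins
for per-cell metabolism. Green tests therefore certify the pipeline's
correctness and calibration behaviour, not quantitative agreement with any
particular cell line's OCR/ECAR.

## Known limitations

* The effective-2-D chamber model cannot estimate absolute OCR/ECAR in
  mol/s — only rates in analyte units per second, normalised per cell —
  because the trapped medium volume is a free parameter.
* The linear-range rule is a reasonable automation of a manual practice;
  curves with two genuinely linear regimes will return the longer one.
* Distance-transform declumping degrades for nuclei under ~3 px radius;
  the intensity mode is preferred at such scales.
* No image registration or drift correction is attempted; frames are
  assumed aligned.
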