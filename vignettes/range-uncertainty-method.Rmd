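---
title: "Quantifying inter-fraction proton range uncertainty from serial CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying inter-fraction proton range uncertainty from serial CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangewepl)
```

## The problem

Proton dose distributions stop. Where they stop depends on the
water-equivalent path length (WEPL) from the patient surface to the target,
so any day-to-day anatomical change — setup residuals after image guidance,
organs moving relative to bone, weight loss, cavity filling — translates
directly into a range error. Treatment-planning systems that optimise
robustly need a probability distribution for this inter-fraction range
error, separated into a *systematic* component $\Sigma$ (reproducible shifts
of the mean) and a *random* component $\sigma$ (day-to-day spread).
`rangewepl` estimates these distributions from serial volumetric CT imaging
acquired during image-guided radiotherapy courses, per beam angle and per
treatment site.

## The pipeline

For each patient course, one fraction (by convention the first usable one)
is the reference. Every other usable fraction is processed as follows.

1. **Calibration.** CT numbers are converted to relative proton stopping
   power through a piecewise-linear curve whose knots come from a density
   phantom: each insert's HU is paired with its stopping power relative to
   water, computed from the Bethe–Bloch ratio
   $$S_\mathrm{rel} = \frac{\rho_e}{\rho_{e,w}}\cdot
     \frac{\ln\!\big(2 m_e c^2 \beta^2 / (I(1-\beta^2))\big) - \beta^2}
          {\ln\!\big(2 m_e c^2 \beta^2 / (I_w(1-\beta^2))\big) - \beta^2},$$
   with $\beta^2 = 1-(m_pc^2/(m_pc^2+E))^2$ and $I_w = 75$ eV. The ratio is
   treated as energy independent: for the cortical-bone insert
   ($\rho_e = 1.69$, $I = 87$ eV) it changes by only
   `r round(energy_independence_check(), 3)` % between 90 and 310 MeV, the
   worst-case therapeutic energies, so a single curve suffices.
2. **Registration.** The daily image is resampled into the reference frame
   using the rigid couch shift recorded by the guidance system (bilinear
   interpolation on stopping-power values, so the calibration's clamping
   semantics are preserved; optional in-plane rotation about the
   isocenter).
3. **Truncation correction.** Megavoltage CT has a 386 mm scanning circle;
   large patients can extend beyond it. Pixels outside the circle but
   inside the (shifted) planning body contour are filled with a uniform
   stopping power (default 1.0, water, since the truncated periphery is
   fairly homogeneous soft tissue); pixels outside both are air.
4. **WEPL ray tracing.** For each pixel of the clinical target volume
   (CTV) a ray is traced in the CT plane toward the beam focus, and the
   effective depth $\sum_i s_i\,\ell_i$ is accumulated, with $s_i$ the
   stopping power of traversed pixel $i$ and $\ell_i$ the geometric length
   of the ray's intersection with it. The traversal is an exact incremental
   grid-crossing walk, not fixed-step sampling; a fine-step sampling
   routine exists in the test suite purely as an independent oracle.
5. **Range error.** The per-pixel difference
   $\Delta\mathrm{WEPL} = \mathrm{WEPL}_\mathrm{fraction} -
   \mathrm{WEPL}_\mathrm{reference}$, matched by grid index in the
   registered frame, is the range-error sample of that (patient, fraction,
   angle) triple. Positive values mean the beam would stop short
   (undershoot risk); negative values mean overshoot.

Population statistics then pool these samples: the overall mean and
$\Sigma$ (the standard deviation of per-fraction mean changes) are weighted
by number of analysed images — every usable image contributes one term,
regardless of patient — while $\sigma$ is computed from all non-binned
per-pixel data, i.e. weighted by data points.

## Conventions and tunable parameters

* **Coordinates.** In-plane physical axes: $+y$ anterior, $+x$ patient
  left. Matrix row 1 is the most anterior row; grids are 1-based
  `[row, col, slice]`. Gantry $0^\circ$ places the source anterior (rays
  travel $(0,-1)$), $90^\circ$ at patient left. These conventions are fixed
  by the unit tests.
* **Source distance** (`source_axis_distance`, mm): default 2000 mm;
  `Inf` selects a parallel beam. At 2000 mm the divergence across a pelvis
  is small, but the tracer supports any positive distance.
* **Calibration curve**: piecewise linear between knots, the standard
  practice for stoichiometric-style calibrations and exactly testable.
  Below the lowest knot the conversion clamps to 0 (no negative stopping
  powers); above the highest knot it extrapolates the last segment so
  metal-bright pixels are handled conservatively.
* **Insert I-values.** The shipped insert table pairs each insert's
  relative electron density and measured HU with a mean excitation energy
  chosen, at the 150 MeV reference energy, to reproduce the reference
  stopping-power column to better than 0.001; manufacturer I-values for
  these substitutes are not published to that precision. The
  energy-independence check defaults to the manufacturer-typical 87 eV for
  cortical bone, which is the conservative (largest-contrast) choice for
  that bound. The reference energy of `build_calibration()` is fixed at
  150 MeV — mid-therapeutic — and immaterial at the 0.6 % level by the
  independence bound.
* **Range–energy law**: $R=\alpha E^p$ with $\alpha = 0.0022$ cm,
  $p = 1.77$ (standard water values), configurable.
* **Endpoint convention**: integration stops at the target pixel *centre*,
  the unambiguous choice, and the one the sampling oracle tests. Traversal
  starts at the grid boundary, not the body surface: outside-body pixels
  carry (near-)zero stopping power, and this removes any dependence on
  body segmentation from the kernel.
* **Corner crossings**: a ray passing exactly through a pixel corner
  yields duplicated crossing parameters and hence zero-length segments,
  which contribute nothing — each crossing is processed once.
* **Histogram bin width**: 1 mm by default. Heat-map displays may truncate
  at ±15 mm for legibility; statistics always use the full data.
* **Estimators**: sample ($n-1$) standard deviations throughout. For
  $\sigma$, two definitions are provided: `"pooled"` (default; SD of all
  concatenated pixel values about the grand mean, which includes
  between-fraction mean variation) and `"within"` (pixel-weighted mean of
  within-fraction variances, the day-to-day fluctuation alone). The pooled
  reading is the most literal interpretation of computing $\sigma$ "from
  all the non-binned fraction data", but the distinction matters —
  $\sigma_\mathrm{pooled}^2 \approx \Sigma^2 + \sigma_\mathrm{within}^2$ —
  so both are exposed and labelled rather than silently conflated.

## The synthetic phantom courses

No public serial megavoltage-CT archive exists, so validation uses a
first-class synthetic module. `phantom_spec()` describes an elliptical body
with disc/slab inserts and a circular CTV, rasterised by the pixel-centre
rule; `simulate_course()` perturbs it per fraction with Gaussian setup
displacement, a Gaussian post-correction residual (the recorded shift is
constructed so that applying it leaves exactly that residual), Gaussian
insert motion relative to the CTV, linear body-contour erosion, and
Gaussian insert-density fluctuation. All stochastic elements are Gaussian
with stated SDs — the choice that keeps the variance decomposition of the
resulting range errors analytic. Fraction images are re-rasterised from the
perturbed geometry, never interpolated, so generator output carries no
resampling artefacts.

Closed-form ground truth (`ground_truth_stats()`) exists for the degenerate
models: no motion (all zeros); erosion only (per-fraction mean
$-e\,(f-1)\times$ background stopping power, overshoot, monotone with
fraction); and slab-density fluctuation (mean 0,
$\Sigma^* = t\cdot s$ for thickness $t$ and density SD $s$). Mixed
image-level models have no closed form; for quantitative
parameter-recovery tests the sample-level generator
`simulate_range_error_samples()` draws per-fraction means from
$N(m^*, \Sigma^{*2})$ and pixels from $N(\mu_f, \sigma_w^{*2})$, so its
truth is exact by construction: the pipeline should recover $m^*$,
$\Sigma^*$ and $\sigma_\mathrm{pooled} \approx \sqrt{\Sigma^{*2} +
\sigma_w^{*2}}$.

Two anatomy-flavoured configurations ship as editable JSON: a pelvis-like
ellipse (360 × 260 mm) with two lateral 1.622-sp discs standing in for the
femoral heads, and a smaller head-and-neck-like ellipse with an air cavity.
On the pelvis phantom, random femoral-disc motion perturbs lateral-beam
WEPL (the disc chord seen by a lateral ray changes as the disc moves) but
not anterior-beam WEPL (anterior rays never cross the discs), so
$\Sigma(90^\circ) > \Sigma(0^\circ)$ — the qualitative beam-angle ordering
expected for prostate anatomy, and one of the package's acceptance checks.

What the generator does **not** emulate: CT noise texture and imaging
artefacts of megavoltage imaging, deformable anatomy beyond rigid insert
motion plus contour erosion, through-plane motion, and 3D phantoms.
Passing tests on these phantoms therefore demonstrate correctness of the
calculation chain, not clinical realism of any particular $\Sigma/\sigma$
value.

## Numerical choices and degenerate inputs

* The exact traversal and the fine-step oracle (step = spacing/1000) agree
  to better than 0.05 mm on random 32 × 32 images over parallel and
  divergent (500–3000 mm) geometries; the suite checks 100 such cases.
* Bilinear resampling can ring at sharp edges only in the sense of
  smoothing; values are clamped at 0 so no negative stopping powers ever
  enter a trace.
* A fraction with a single CTV pixel has an undefined SD but still
  contributes its mean; groups too small for $\Sigma$ (or $\sigma$) yield
  `NA` rows with a warning rather than failing the whole table.
* `NA`/`NaN` voxels convert to stopping power 0 with a warning;
  NIfTI files without positive pixel dimensions are rejected rather than
  silently assigned a default spacing.
* Rays that enter the grid exactly at the target centre (target on the
  upstream boundary) have zero effective depth.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so a
full run takes seconds on one CPU: 32 × 32 oracle-equivalence images,
100 × 100 single-slice pipeline phantoms, a 140 × 200 pelvis course of 20
fractions for the beam-angle ordering, and 200-fraction × 500-pixel
sample-level populations for parameter recovery. The code itself is
size-agnostic; clinical grids (512 × 512, 30–40 fractions, several angles)
are minutes-scale.

## Known limitations

Ray tracing is strictly in-plane (coplanar beams only), matching the
effective-depth algorithm it implements; pixel correspondence across
fractions is by grid index after rigid registration, so genuinely
deformable change is attributed to density differences along the ray; the
systematic error contributed by the HU calibration itself is out of scope;
and no margin recipe or correction strategy is applied to the resulting
statistics — they are estimates of the residual inter-fraction error after
image guidance, intended as priors for robust optimisation or robustness
analysis.
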