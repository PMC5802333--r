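# rangewepl

Inter-fraction proton range uncertainty from serial volumetric CT.

## What it is for

Proton treatment plans are only as robust as the uncertainty model behind
them. Between treatment fractions the patient changes — residual setup
error after image guidance, organs moving relative to bone, weight loss,
cavity filling — and every such change alters the water-equivalent path
length (WEPL) from the surface to the target, i.e. where the protons stop.
`rangewepl` turns a course of daily volumetric CT images (e.g. TomoTherapy
megavoltage CT) into site- and centre-specific probability distributions of
this residual range error, summarised per beam angle as

* **mean** — the average WEPL change across the course (mm),
* **Σ (systematic)** — the standard deviation of per-fraction *mean* WEPL
  changes, weighted by number of analysed images,
* **σ (random)** — the spread of the per-pixel WEPL changes, weighted by
  number of data points.

These are the priors that robust/probabilistic plan optimisation and
robustness analysis consume. The intended users are medical physicists and
therapy researchers with serial IGRT archives.

## The method in brief

CT numbers are converted to relative proton stopping power with a
piecewise-linear calibration whose knots are density-phantom inserts; each
insert's stopping power relative to water comes from the Bethe–Bloch ratio

    S_rel = (ρe/ρe,w) · [ln(2·me·c²·β² / (I·(1−β²))) − β²]
                       / [ln(2·me·c²·β² / (Iw·(1−β²))) − β²]

with Iw = 75 eV and β obtained from the proton kinetic energy. The ratio is
energy independent to < 0.6 % between 90 and 310 MeV even for cortical
bone, so a single curve is used. For each clinical-target-volume (CTV)
pixel a ray is traced in the CT plane toward the beam focus, accumulating
stopping power × intersection length per traversed pixel (exact
grid-crossing walk) — the effective depth. Daily images are first resampled
into the reference frame with the recorded rigid couch shifts, and
field-of-view truncation (386 mm scanning circle) is corrected with a
uniform-density fill inside the planning body contour. The per-pixel
difference of each fraction's WEPL map against the reference fraction's is
the range-error sample from which the population statistics are built.

Because no public serial MVCT data exist, the package includes a
ground-truthed synthetic module: elliptical digital phantoms with bone-like
inserts, per-fraction setup error and IGRT correction, relative insert
motion, body-contour erosion and density fluctuation, plus an exact-truth
sample-level generator for statistical validation. See the methods
vignette (`vignettes/range-uncertainty-method.Rmd`) for the full model
description and design choices.

## Worked example

Simulate a 12-fraction head-and-neck-like course with 3 mm setup error,
1.5 mm post-correction residual and 0.2 mm/fraction weight-loss erosion,
then analyse it for an anterior and a lateral beam:

```r
library(rangewepl)

course <- simulate_course(head_neck_like_phantom(),
                          motion_model(setup_sd = 3, residual_after_igrt_sd = 1.5,
                                       erosion_rate = 0.2),
                          n_fractions = 12, seed = 42)
res <- run_course(course$reference, course$fractions, course$ctv_mask,
                  beams = list(beam_geometry(0, Inf), beam_geometry(90, Inf)),
                  patient_id = "hn01")
head(res$summaries, 4)
#>   patient fraction angle n_pixels   mean_mm     sd_mm
#> 1    hn01        2     0      316 1.7647923 1.7806348
#> 2    hn01        2    90      316 0.1016311 0.5253680
#> 3    hn01        3     0      316 0.2152713 4.6068129
#> 4    hn01        3    90      316 1.9215943 0.9387782

population_table(res$samples, res$summaries)
#>   angle mean_mm sigma_mm sd_mm n_fractions n_pixels
#> 1     0   0.209     2.35  4.71          11     3476
#> 2    90  -1.384     2.25  2.27          11     3476
#> 3   All  -0.587     2.39  3.78          22     6952
```

Each summary row is one analysed image at one beam angle: `mean_mm` is that
fraction's mean WEPL change over the 316 CTV pixels (positive = undershoot
risk, negative = overshoot), `sd_mm` its within-fraction spread. The
population table pools the course: per angle and over all angles it reports
the image-weighted mean, the systematic error Σ (`sigma_mm`, SD of the
per-fraction means) and the random error σ (`sd_mm`, SD of all 6952
non-binned pixel values). Heat maps of the per-fraction histograms
(`plot_range_heatmap()`) and per-fraction SD plots (`plot_fraction_sd()`)
visualise the same data.

File-based workflows use `run_analysis()` with a JSON config (paths to
per-fraction NIfTI images, shift CSV, mask NIfTIs, angles, …) and write
summary/histogram/population CSVs plus a replayable run log. A thin CLI
(`inst/cli/rangewepl`) exposes `calibrate`, `wepl`, `simulate`, `analyze`
and `stats` subcommands.

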