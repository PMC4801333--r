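---
title: "Quantitative canalography: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative canalography: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canaloflow)
```

## The measurement problem

Aqueous humor leaves the eye mainly through the conventional outflow
pathway: trabecular meshwork, Schlemm's canal (the angular aqueous plexus
in pigs), collector channels, and episcleral veins. Bulk outflow can be
measured, but it is well established that drainage is *segmental* —
some clock hours of the limbal circumference carry far more flow than
others — and no routine method quantifies that regional structure. A
fluorescein canalogram makes it visible: tracer perfused into the
anterior chamber gradually fills the perilimbal vessels, and a time-lapse
(here one frame every 30 s for 20 min) records where and how fast each
sector fills. `canaloflow` turns such a stack into regionally discrete
kinetics and per-quadrant flow estimates.

## Pipeline and model

1. **Macropixel reduction.** Each frame is partitioned into a 32 × 32
   grid of contiguous blocks (block sizes differ by at most one pixel when
   the image dimension is not divisible; the larger blocks come first, a
   fixed and documented order). A macropixel's value is the arithmetic
   mean of its block, giving 1024 coarse time courses. Intensities are
   then normalized to percent of the single global maximum, so downstream
   flow is in "percent fluorescence per frame" and all results are
   invariant to overall gain.

2. **Analysis annulus.** The cornea (dye-blocked, dark) and — for
   anterior segment cultures — the scleral compression ring are excluded
   using a per-eye geometry config; only macropixels whose centers fall in
   the annulus between the corneal radius and the outer radius, forming a
   complete ring around the eye, are analyzed. Each included macropixel
   gets a clock hour (twelve 30° sectors, hour 12 centered on the superior
   pole, advancing clockwise in the displayed image — the ophthalmic
   charting convention), a perilimbal ring (three equal-radial-width
   bands), and an anatomical quadrant (IN, SN, ST, IT, bounded by the
   vertical and horizontal meridians; nasal is image-left for OD,
   image-right for OS).

3. **Per-macropixel fill curves.** Each included time course is fit with
   a penalized cubic regression spline (`mgcv`), basis dimension
   `k = min(10, n_frames − 1)`, smoothing parameter by GCV — a
   deterministic fit with no random initialization. From the fitted curve
   evaluated on a dense grid (step = frame interval / 10, with linear
   interpolation at the crossing) we take the maximum intensity `I_max`,
   the half-max `I_half = I_max / 2` measured from absolute zero, the
   earliest time `t_half` at which the curve reaches `I_half`, and the
   filling rate `I_half / t_half`. Half-max is deliberately *not*
   baseline-adjusted: the rate is defined as the rise from an initial
   value of zero to the half-max intensity over the time taken, and a
   baseline-adjusted variant would change the meaning of the rate unit.
   A macropixel counts as *filling* when its fitted dynamic range exceeds
   a noise floor (default 5% of the global maximum) and the curve ends
   higher than it starts; non-filling macropixels carry no kinetics and
   contribute zero flow.

4. **The 36-region global model.** Macropixels are grouped by clock hour
   and ring (12 × 3 = 36 regions) and averaged per frame. A *single*
   model is then fit to all regions at once:
   `intensity ~ ring + te(clock_hour, time)`, a tensor-product smooth
   cyclic in clock hour (period 12) and cubic in time, stratified by
   ring, with GCV-selected smoothing. A purely additive formulation —
   separate smooth terms for hour, ring and time — cannot produce
   region-specific half-max *times*: additive terms shift a shared curve
   up and down but never sideways, so every region would cross half-max
   simultaneously. The hour-by-time interaction is therefore the default;
   `formulation = "additive"` keeps the simpler model available for
   comparison. Per-region `t_half` and rate are extracted from the fitted
   surface exactly as in step 3.

5. **Flow attribution.** Each included, filling macropixel contributes a
   flow increment `[F(t_half) − F(t_first)] / n_frame_intervals` in
   percent per frame, where `F` is its region's global-fit curve by
   default (`flow_source = "individual"` substitutes its own fit).
   Quadrant flow is the quadrant's share of the summed increments scaled
   to a configurable total of 3 µl/min — a normalization constant
   representing established total aqueous flow, not a measurement, so the
   four quadrant values always sum to it exactly. Per-quadrant filling
   time is the first frame at which any member macropixel exceeds its own
   first-frame baseline by the onset threshold (default 5% of global max,
   the automated stand-in for a human "first appearance" call); quadrants
   that never cross are censored at stack end. Matched per-eye metrics
   (e.g. nasal vs temporal filling times) are compared with a paired
   two-sided t-test.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `frame_interval_s` | 30 | s | acquisition cadence; frame times are synthesized from it |
| `grid_rows`, `grid_cols` | 32 | – | macropixel grid; 32 × 32 = 1024 macropixels |
| `spline_k` | 10 | basis functions | cap on per-macropixel spline dimension |
| `noise_floor` | 5 | % of global max | filling / non-filling classification |
| `onset_threshold` | 5 | % of global max | first-appearance filling time |
| `total_flow_ul_min` | 3 | µl/min | normalization constant for quadrant flows |
| `eval_step_s` | interval/10 | s | dense grid for half-max extraction |

## Numerical choices and edge cases

- **Tie-breaks.** A radius exactly on a ring boundary belongs to the
  inner ring; an angle exactly on a meridian or hour boundary belongs to
  the clockwise-following sector. Membership is by macropixel center
  point, which is simple, deterministic, and appropriate for a coarse
  grid.
- **Degenerate curves.** A constant series is fit as the constant (the
  zero-roughness optimum) rather than sent to the smoother; a fill that
  crosses half-max at the first instant (`t_half = t_first`) gets a zero
  increment and a degenerate flag rather than an infinite rate; fit
  failures are flagged per macropixel and never abort the run.
- **Earliest crossing wins** when a non-monotone fitted curve reaches
  half-max more than once.
- **Zero-variance paired differences** are reported explicitly (t = 0,
  p = 1 for identical vectors; infinite t, p = 0, flagged, for a constant
  non-zero difference) instead of erroring.

## The synthetic generator

Real canalogram stacks are not redistributable, so the package carries a
first-class generator: sector-wise logistic filling
(`baseline + A / (1 + exp(−(t − t50)/τ))`) of a homogeneous perilimbal
annulus around a dark corneal disk, additive Gaussian noise on counts
clipped at zero and at bit depth, fully determined by a seed. Logistic
kinetics were chosen because the half-max crossing has a closed form,
giving exact analytic oracles for `t_half`, flow fractions and onset
times. Defaults mirror the emulated acquisition: 580 × 610 px, 41 frames
at 30 s. Three presets encode the study conditions: `whole_eye` (all
quadrants active, nasal t50 = 300 s vs temporal 600 s, with distinct
per-quadrant amplitudes 90/110/60/40 counts so the four true flow
fractions are strictly ordered SN > IN > ST > IT), `asc_day1` (focal
filling confined to the nasal quadrants plus a compression-ring
exclusion) and `asc_day3` (all quadrants active, every t50 strictly
smaller than day 1). Presets align their kinetic boundaries with the
quadrant meridians rather than the 12 clock sectors, because clock
sectors straddle the meridians by 15° and would blur the per-quadrant
ground truth the presets exist to define.

What the generator does *not* emulate: vessel-tree branching structure
(available only as a display option), optical blur, photobleaching,
motion, and Poisson photon statistics. Passing the recovery tests
therefore demonstrates that the estimation chain is correct and unbiased
under clean logistic filling with Gaussian noise — not that it is robust
to every artifact of real microscopy.

```{r example, eval = FALSE}
sim <- generate(preset("whole_eye", seed = 17, rows = 192, cols = 192),
                grid_rows = 32, grid_cols = 32)
fit <- canaloflow(sim, grid_rows = 32, grid_cols = 32)
summary(fit)
plot(fit, type = "dots")
plot(fit, type = "rings")
```

## Problem sizes used in the test suite

The suite exercises the full pipeline on scaled-down stacks chosen to
keep the statistical properties intact: recovery tests use 192 × 192 px
whole-eye stacks at the native 41-frame cadence and the full 32 × 32
grid (≈ 570 included macropixels); conservation is checked over 100
random 48 × 48 px, 12-frame stacks at a 12 × 12 grid; the paired
nasal-temporal contrast uses six 128 × 128 px stacks with distinct
seeds. Image width scales only the number of pixels averaged per
macropixel, not the kinetics being estimated, so these sizes probe the
same estimation problem as full-size stacks.

## Known limitations

- Flow is *relative*: quadrant values in µl/min inherit the configured
  total; cross-eye or cross-day comparisons of absolute flow require the
  normalization assumption to hold in both conditions.
- Geometry is manual by design (cornea and compression ring identified
  per eye); there is no automatic limbus segmentation or session
  registration.
- The global model's smooth structure (tensor interaction, cyclic period
  12, ring stratification) is an interpretation; the strictly additive
  alternative is retained for sensitivity analysis.
- `t_half` carries no uncertainty interval; the package reports point
  kinetics only.
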