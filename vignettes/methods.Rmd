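---
title: "Methods: pericyte calcium and single-vessel hemodynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pericyte calcium and single-vessel hemodynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pericyteflow)
```

This vignette is the package's own account of what each stage computes,
the assumptions behind it, the parameters that matter, and the design
decisions taken where the underlying experimental workflow left them
open. Nothing here states a result that the test suite or
`scripts/acceptance.R` does not itself compute.

## What the synthetic generators emulate

Every analysis stage in this package is validated by parameter
recovery: a seeded generator produces data with a known ground truth,
and the stage must recover it. The generators emulate the statistical
structure of two-photon pericyte recordings:

* **Calcium traces/movies** — baseline fluorescence `F0` modulated by
  Poisson-arriving transients with instantaneous rise and
  single-exponential decay (`decay_tau` = 1 s by default, appropriate
  for a slow indicator such as GCaMP6s; ~0.5 s for faster RCaMP-like
  kinetics), an optional slow sinusoid emulating vasomotion-coupled
  calcium, additive Gaussian noise, and — in movies — transients
  rendered as spatial Gaussian blobs confined to the soma or process
  compartment, a plasma channel, and symmetric cross-channel
  bleed-through `M = [[1, b], [b, 1]]`.
* **Diameter kymographs** — per-line bright plateaus of width
  `D(t) = D0 (1 + a sin(2πft))`, edges softened by a Gaussian edge
  model whose half-maximum falls exactly at the programmed radius, so
  the FWHM ground truth is exact by construction.
* **Velocity kymographs** — dark blood-cell streaks (anti-aliased
  bands, default 6 µm wide, multiplicative contrast 0.6, overlaps
  multiply and saturate toward 0) on a bright plasma background, with
  Poisson arrivals and per-line displacement `v · Δt / pixel_size`.
  Stall epochs force zero velocity; streaks then run parallel to the
  time axis.
* **Stimulus trials** — a 5-s pre-stimulus baseline followed by a 5-s
  stimulus during which calcium dips and diameter/velocity rise, each
  following a raised-cosine onset/offset ramp (1 s) that reaches its
  full programmed magnitude within the window.
* **Grouped observations** — `y = µ + δ·[post] + a_animal + b_unit + ε`
  with Gaussian components: the paired pre/post, unit-within-animal
  design of a repeated-measures pharmacology experiment.

What they deliberately do **not** emulate: optics (no PSF, no
photobleaching), motion artifacts, indicator nonlinearity, vessel
curvature, or hematocrit-dependent streak statistics. Passing the
recovery suite therefore shows the algorithms are correct under the
stated statistical model, not that they are robust to every artifact of
in-vivo data.

One generator choice deserves emphasis: for velocimetry validation the
cell arrival rate is tied to the programmed speed (`flux = 40·v`
cells/s, minimum 5), which keeps the linear cell density near one cell
per 25 µm at every speed. A fixed sparse flux at 10 mm/s would imply
centimetre-scale gaps between cells — unphysical, and it would leave
most 80-ms estimation windows without a single streak. Flux-counting
accuracy is validated separately at fixed rates (2–10 cells/s) at
moderate speed.

## Calcium stage

**Unmixing** solves the 2×2 linear system per pixel and clips negative
intensities to zero (photon counts cannot be negative); the number of
clipped values is attached to the result. A mixing matrix with
reciprocal condition number below 1e−12 is rejected.

**ΔF/F₀** uses the mean of the first 5 s of the trial as `F0`; the
basal-fluorescence summary uses the first 2.5 s. Both windows are
arguments. A non-positive `F0` is an error — a flagged, unusable trace,
never a silent `NaN`.

**Transient detection** band-pass filters the ΔF/F trace and reports
peaks by topographic prominence, reading amplitudes from the
*unfiltered* trace (the filter is for detection only; because the
zero-phase filter reshapes the apex, the raw amplitude is read as the
maximum within half a separation window around the detected peak).
Numerical choices:

* The filter is a zero-phase FFT mask rather than a recursive
  (Butterworth) design: at ~12 Hz sampling a 0.01 Hz lower edge makes
  IIR coefficients ill-conditioned, while the frequency-domain mask is
  exact and stable. Default band 0.01–2 Hz, configurable.
* The prominence gate is `k` times the SD of the filtered trace over
  the 5-s baseline window. The default `k = 7` was calibrated on
  band-limited pure noise: in a 2-Hz band, noise-peak prominences
  routinely reach 5–6 baseline SDs (and the 5-s window cannot express
  sub-0.2 Hz noise power, biasing the SD estimate low), so a 2-SD gate
  admits tens of false transients per minute, whereas transients of
  physiological amplitude sit above 10 SDs. The multiplier is exposed
  for recordings with different noise structure.
* Minimum peak separation 1 s; of two qualifying peaks closer than
  that, the taller is kept, and a flat-topped plateau counts once (its
  first sample).

**3-D event detection** estimates per-pixel baseline mean and SD from
the first 5 s, marks voxels above `mean + k·SD` (default `k = 3`),
groups active voxels by 26-connectivity over (x, y, t), and keeps
components with at least 4 voxels, 2 frames, and a footprint
intersecting the vessel structure (the ROI set's vessel mask, or the
union of ROI labels when no mask is supplied). Per-ROI frequency counts
retained components touching that ROI, in events/min. The SD floor
`max(SD, 1e-6·|mean|)` keeps noise-free input well defined; a
consequence worth knowing is that with zero noise *any* positive
excursion is "active", so transients closer in time than the rendered
kernel span merge into one component — the validation suite therefore
spaces noise-free plants beyond the kernel footprint.

**Spectral summary** is the periodogram of the full mean-removed trace
(no Welch averaging, so the lowest resolvable bins are retained), with
the one-sided PSD normalized so `sum(psd)·df` equals the population
variance (a Parseval identity the tests assert to 1%). The peak
frequency is the PSD argmax within the search band, default
0.01–0.5 Hz. A 60-s trace resolves nothing below 1/60 Hz; the
implementation searches the bins that exist inside the band and errors
only when there are none, since demanding strict resolvability of the
0.01 Hz edge would reject the standard 60-s trial that the band is
meant for.

## Line-scan stage

**Diameter (FWHM).** Scan lines are averaged in non-overlapping windows
(default 25 lines, i.e. 50 ms at 2 ms/line — fast enough to sample
0.1 Hz vasomotion 200× per cycle while suppressing per-line noise).
The profile baseline is the mean of the outer 10% of pixels on each
side (robust to a non-centred vessel), the half-maximum is
`baseline + (max − baseline)/2`, and crossings are located with linear
interpolation. Profiles with no crossing (vessel filling the scan) are
flagged invalid, not guessed. The estimator is exactly invariant to
global intensity scale and offset. A sampled rectangular plateau is
measured exactly when its edges fall mid-pixel; a width-10 plateau
centred *on* a pixel is inherently represented by 9 or 11 bright
columns, which is a property of sampling, not of the estimator.

**Velocity (Radon velocimetry).** Each sliding window (default 40
lines, 75% overlap) is mean-subtracted and projected along candidate
streak slopes; the slope maximizing the projection variance gives
`v = slope · pixel_size / line_period`. Design decisions:

* The search grid is uniform in *slope* where slow streaks span the
  window and geometric where fast streaks cross the scan in a few
  lines, because the alignment basin's width is constant in slope in
  the first regime and proportional to slope in the second. A fixed
  fine *angle* grid cannot do both: near 89° a 0.25° step corresponds
  to tens of px/line and can miss the basin of a 10 mm/s streak
  entirely. After the grid scan, the estimate is refined continuously
  (golden-section search between the neighbouring grid slopes), making
  the final value grid-free.
* The per-slope energy is normalized by a *circular-shift null*: each
  null replicate shifts every scan line by an independent random
  offset (fixed internal seed, so the estimator is deterministic),
  which destroys inter-line alignment at every slope — including
  slope 0, i.e. stalls — while preserving each line's spatial
  structure and traffic density. Without this, traffic-count
  fluctuations accumulate like a random walk across the window and
  dominate the raw energy whenever streaks cross the scan in a few
  lines, biasing the argmax. (A line-*permutation* null fails
  specifically on stalled windows, which are permutation-invariant.)
* Projection bins are 1 px (the null normalization keeps fine bins
  well conditioned at steep slopes, and fine bins sharpen the peak for
  slow streaks).
* Sign convention: positive velocity is motion toward increasing scan
  position; flipping the position axis negates the estimate.
* A window whose best slope lies at the grid boundary is outside the
  measurable range (default ±50 mm/s) and is flagged `unresolved`;
  each window also carries a separability score (peak score over the
  median across slopes).

**Flux.** At a reference column (default mid-scan), intensities are
split into cell/plasma classes by Otsu's threshold, with a guard: Otsu
assumes a bimodal histogram, and on sparse traffic it happily splits
the plasma noise mode. If the between-class separation is below 3
pooled SDs the threshold falls back to a robust noise floor
(`median − 5·MAD`), under which cells — dark excursions roughly 8 noise
SDs deep — remain detectable while pure noise yields zero counts. Cell
runs separated by fewer than 2 plasma lines merge, and flux is counted
in 1-s bins.

**Cleaning.** Samples outside the physiological bounds (defaults:
diameter (0.5, 50] µm, velocity [−50, 50] mm/s, flux [0, 500] cells/s)
are replaced by the mean of the two nearest in-bounds neighbours
(one-sided at the ends). For velocity and flux only, Rosner's
generalized ESD test (α = 0.05, up to 15 outliers, critical values from
the t distribution) then removes residual outliers — the kind of
artifact steep-streak misfits produce in fast vessels. A trace more
than half out of bounds is rejected outright. Cleaning never adds
samples and never alters in-bounds, unflagged values.

**Resampling.** Valid samples are linearly interpolated to 10
samples/s and smoothed with a centred 11-point moving average — 11
points at 0.1 s spacing span exactly 1 s — with shrinking windows at
the ends. The tests verify the exact discrete frequency response of
this window on a 0.1 Hz tone.

**Vasomotion.** Frequency is the count of diameter peaks (prominence at
least 5% of the mean diameter, at least 2 s apart) per minute of
observation (`n·dt`); the vasomotor index is the mean peak-to-trough
excursion over detected cycles divided by the mean diameter. ΔD/D is
ambiguous between half-amplitude and peak-to-trough conventions;
peak-to-trough was chosen and is stated here — a pure sinusoid of
amplitude `a` on diameter `D0` yields `2a/D0`. The PSD argmax of the
diameter trace is reported alongside, since both the cycle-count rate
and the spectral peak are used in practice to summarize vasomotion.

## Neurovascular coupling

Percent change is computed against the mean of the 5 s immediately
before stimulus onset (for calcium this re-references the trace: the
trial-start `F0` and the pre-stimulus baseline may differ), and the
response magnitude is the extremum — minimum for the calcium dip,
maximum for hemodynamic rises — strictly within the stimulus window. A
post-stimulus grace period for hemodynamic lag is not included by
default; the window is an argument. Because a window extremum of a
noisy trace is biased outward by roughly the per-sample noise SD,
responses are read from smoothed (`resample_smooth` /
`resample_series`) and, when repeats exist, trial-averaged traces —
matching how stimulus-locked responses are summarized in practice
(mean + SEM across trials).

## Statistics

The normality gate applies Shapiro–Wilk at α = 0.05 and, on failure,
the natural-log transform, shifting by `1 − min(x)` when non-positive
values make the plain log undefined (the shift is recorded). The
treatment comparison is a linear mixed model with a fixed treatment
effect and random intercepts for animal and unit-within-animal — the
minimal structure for repeated measures of the same animals and the
same pericytes/vessels. Models are fit by maximum likelihood so the
likelihood-ratio test of the treatment term (χ², 1 df) is valid across
fixed-effect structures; REML variance components are reported
alongside. Singular fits (a variance component at zero) are flagged,
not failed, and in the degenerate no-hierarchy case the estimate
reduces exactly to the plain mean difference on a balanced design.
Trials within a unit can be averaged before fitting
(`average_trials = TRUE`), default off. Holm's step-down adjustment is
implemented in closed form; note it is *not* idempotent — re-adjusting
an already-adjusted vector multiplies the smallest element by the
family size again — so adjusted values should be computed once from raw
p-values per family.

On the calibration design used in the tests (7 animals × 6 units ×
paired pre/post, 84 observations), the χ²(1) reference for the LRT is
mildly anti-conservative relative to the exact paired comparison; the
test suite measures the rejection rate under the null over 1000
simulated datasets and the effect recovery over 500, at that design
size.

## IO and pipeline

Movies and kymographs are written as multi-page 32-bit TIFF with a JSON
sidecar (frame rate, channel order, line period, pixel size,
orientation). The TIFF writer available to R stores 32-bit unsigned
integer samples, so intensities are mapped to [0, 1] by a power-of-two
scale recorded in the sidecar; one write/read cycle is exact to one
quantization step (~2e-10 of the intensity range), which is the
round-trip guarantee the tests assert. Observation tables are CSV with
a config-hash header comment. `run_pipeline` executes the full chain —
generation, calcium analysis, hemodynamics, cleaning, resampling,
vasomotion, mixed models with Holm correction — per unit and condition,
logging per-unit failures and skipping them rather than aborting; all
randomness derives from the single configuration seed, and two runs
with the same configuration produce byte-identical summary tables. The
package's interface is its exported functions plus this vignette;
`scripts/acceptance.R` is the only shell entry point shipped.

## Problem sizes

The recovery suite uses 60-s trials at 12 frames/s, 128×128 px movies
for the full-scale 3-D detection check and 32–64 px frames elsewhere,
4-s kymographs at 2 ms/line for velocimetry across 0.2–10 mm/s, 10-s
kymographs for flux, 1000/500 simulated datasets for mixed-model
calibration, and an exhaustive sweep of all non-decreasing p-value
triples on a 0.001 grid for the Holm oracle. These sizes were chosen so
each check is statistically meaningful while the whole suite runs in
minutes on one CPU.

## Known limitations

* Velocimetry assumes straight scan paths and reports a single
  dominant velocity per window; windows containing both moving and
  stalled cells yield the dominant population's slope.
* Flux counting undercounts when cell transits overlap at the
  reference column (noticeable above ~10 cells/s at 2 mm/s).
* The 3-D detector's SD floor makes zero-noise data maximally
  sensitive; detection thresholds are meaningful only relative to a
  non-degenerate noise level.
* The mixed-model layer fits random intercepts only; random slopes and
  Bayesian alternatives are out of scope.
* ROIs are inputs (as in manual selection); no segmentation or motion
  correction is provided.
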