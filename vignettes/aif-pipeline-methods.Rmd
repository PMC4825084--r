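---
title: "Automated AIF measurement: models, parameters and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated AIF measurement: models, parameters and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aifx)
```

This vignette is the package's own account of the science behind each
stage: the models and their assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic phantom does and does
not emulate, and the numerical choices made where the design was open.

## The measurement problem

First-pass perfusion CMR acquires one short-axis frame per cardiac cycle
while a gadolinium bolus transits the heart: right ventricle (RV) first,
left ventricle (LV) about a pulmonary transit time later, then the
myocardium at much lower amplitude. Quantitative myocardial blood flow
(MBF) needs the arterial input function (AIF) — the LV blood-pool
time–signal curve — measured from the brightest, artefact-free cavity
pixels. The two systematic troubles are papillary muscles (intracavitary
tissue that stays dark and drags the mean down) and partial-volume pixels
at the cavity boundary. The pipeline automates the ROI choice so the AIF
is reproducible and operator-independent.

## Stage models and parameters

**Motion correction.** A translation (rigid) motion model is estimated
per frame. Consecutive frames are matched by FFT cross-correlation of
mean-removed, Gaussian-smoothed images (`motion_sigma_px = 1` px; the
smoothing stabilises the correlation peak on noisy frames), with a
parabolic sub-pixel fit around the integer peak. Matching *consecutive*
frames keeps the brightness-constancy assumption tenable despite contrast
wash-in — adjacent frames have nearly the same contrast state. Pairwise
shifts are composed to a reference frame (the frame of maximal total
intensity, near the LV peak, the most stable anchor), then refined twice
against the temporal mean of the corrected stack, which contains every
structure and suppresses the single-frame contrast bias. Each output
frame is produced by one bilinear interpolation from its original.
Constant (degenerate) frames are skipped with a warning and an identity
field. In-plane translation covers the dominant respiratory component of
cardiac perfusion motion; elastic deformation is beyond this model and is
listed under limitations.

**Heart detection.** The temporal standard-deviation map (population,
1/T, variance; at T = 60 the sample/population distinction is
negligible) highlights bolus-swept pixels. It is thresholded at
`mean + k·SD` with k = 1 for the dedicated AIF series and k = 2 for the
myocardial series; the statistics are taken over the whole map (taking
them over a foreground subset would need a foreground definition the map
itself is supposed to provide). Components are 8-connected; regions
smaller than 4 px (AIF series) / 16 px (myocardial) are discarded because
curve features on a couple of pixels are meaningless. A candidate's
*baseline* is the mean of its first 3 frames — the series begins
pre-contrast by acquisition design. Candidates whose peak is below twice
that baseline, or whose peak falls in the first or last 3 frames, are
removed. Candidates whose mean curves correlate above 0.75 and whose
minimum inter-pixel distance is below the sum of their average radii
(`r = sqrt(area/π)`) are unioned — a ventricle split by papillary
muscles or artefacts behaves exactly like this. The two ventricles are
then chosen by a linear rank vote: per feature, candidates are scored
1..N (N best — larger area, peak value, upslope and M; smaller
time-to-peak, FWHM and distance to image centre), totals decide. The
distance-to-previously-selected feature only exists in the second round,
so the vote runs twice ("iteratively"): once without it for the first
pick, once with it (and without the first pick) for the second. Ties
break on higher M, then smaller distance to centre — M is the most
ventricle-specific single feature. The bounding box is the union box of
the winners expanded 25 % per side and clipped.

**Intensity correction.** A 2-D polynomial surface (total degree 3;
lower orders underfit typical coil profiles, higher orders chase noise)
is weighted-least-squares fitted to the averaged PD frames, with
foreground pixels (above the Otsu threshold of the PD image) at weight 1
and background at 0.1 — a simplified foreground/background weighting
scheme, ours, not a reproduction of any published one. The surface is
floored at 5 % of its maximum (division guard), normalised to mean 1
over the heart box so heart-region signal levels are preserved, and
divided out of every frame; this multiplies each pixel's curve by a
time-constant scalar, so temporal shape is exactly preserved. Baseline
removal subtracts the per-pixel mean over the pre-contrast frames —
by default the frames before the onset of the whole-image mean curve
(first crossing of baseline + 10 % of range), falling back to the first
3 frames.

**Ventricular classification.** The pixel curves of the two vote winners
are modelled as mixtures of two independent temporal sources — the RV
and LV bolus passages. FastICA (fixed-point iteration, kurtosis
contrast) with a deterministic initial rotation extracts them; the
kurtosis contrast was the most reliable of the standard contrasts on
bolus-shaped sources in our benchmarks. Failures retry with seeded
random rotations (`ica_max_retries = 5`) and finally fall back to the
candidate mean curves with a warning. Sources are canonicalised
(positive peak, unit maximum). Every box pixel is Pearson-correlated at
zero lag with both sources; correlation above 0.7 assigns the pixel to
the better-matching chamber, the rest is background, and zero-variance
pixels get correlation 0 rather than NaN. The earlier-peaking source is
the RV. Whitening constrains ICA outputs to be exactly uncorrelated, so
when the true sources are slightly correlated (overlapping bolus
passages) recovery is near-perfect but not exact; at delays under ~4 s
the separation degrades gracefully.

**AIF extraction.** The per-pixel temporal maximum (MIP) is computed
over the LV label map, and the threshold is set at
`min + q/100 · (max − min)` of the LV MIP values — the *range* reading
of "percentile", chosen deliberately (a `mode = "quantile"` switch
provides the order-statistic reading). q = 75 is the default ROI; 50 and
25 give progressively larger ones. Selected pixels are averaged per
frame and the curve is linearly interpolated onto the 0.5 s grid with no
extrapolation.

**Timing points.** Peak time is the curve argmax. The rising-peak anchor
is the sample of maximal forward difference before the peak; the
baseline sample minimises `|v[i−1]−v[i]| + |v[i+1]−v[i]|` before the
anchor. The start time is the curve sample closest to the intersection
of a least-squares line through the rising segment (samples between
10 % and 90 % of peak enhancement) with the horizontal baseline level.
"Closest" is measured in normalised coordinates — time over curve
duration, intensity over peak enhancement — so the geometry is
scale-free; without normalisation the answer would depend on the units
of the axes. Degenerate curves (flat, peak at either end, no
enhancement) raise a distinguishable timing error.

**Curve metrics.** PV is peak minus baseline value; TTP is peak minus
start time; FWHM is the width between the two baseline-referenced
half-height crossings, linearly interpolated, with the right edge
clipped (and flagged) at the series end if the curve never falls below
half height; upslope is the best least-squares slope over a sliding
3-sample (1 s) window between start and peak; `M = PV / (TTP · FWHM)`.

**MBF.** Tissue curves are modelled as
`tissue(t) = Δt/60 · Σ_s AIF(s) · R(t−s)` with the Fermi residue
`R(t) = F·(1 + e^{−kτ})/(1 + e^{k(t−τ)})`, so `R(0) = F` is the flow in
ml/g/min (the 1/60 converts minutes to seconds and lives inside the
convolution operator, used identically by the phantom forward model and
the estimator). Fermi-constrained deconvolution is this package's
choice of constrained model — the standard parameterisation in
perfusion CMR for this role. Fitting is bounded L-BFGS-B
(F ∈ [0, 10] ml/g/min, k ∈ [0.001, 5] /s, τ ∈ [0, 15] s) from a fixed
3 × 3 grid of (k, τ) starts with a data-derived flow start, hence
deterministic; the window begins at the supplied contrast start time,
and timing points are an explicit input so the same points can be
reused across AIF variants. Convolution uses the rectangle rule on the
0.5 s grid.

## The phantom: what it emulates, what it does not

`phantom_spec()` renders a 48 × 64 (dedicated AIF) or 192 × 256
(myocardial) series of 60 frames at a 1 s R-R interval: gamma-variate
chamber boluses (`A·((t−t0)/(αβ))^α · e^{α−(t−t0)/β}`, peaking at
`t0 + αβ` with value A), RV at t0 = 5 s (A = 100, α = 3, β = 1.5 s), LV
6 s later (A = 110, α = 3, β = 2 s; a physiological pulmonary transit),
Fermi-convolved myocardial enhancement per sector (computed on a 4×
finer grid so the discrete forward model approximates the continuous
convolution), papillary blobs at myocardial base intensity plus 2 % of
the LV bolus (dark by construction), static tissue base intensities
(blood 40, myocardium 30, background 8 a.u.) so pre-contrast frames
contain registerable anatomy, a degree-2 polynomial coil-shading surface
(≈ ±15 %), smooth sinusoidal respiratory-like translation (default
amplitude 1.5 px), and additive Gaussian noise (σ = 2 a.u., switchable
to Rician). There is no canonical SNR for this kind of acquisition, so
the noise and shading levels were chosen once to look like typical
first-pass series and are configurable. The exported truth contains the
noiseless LV bolus (the true AIF), all masks, the motion schedule, the
shading field and the sector flows.

What it does *not* emulate: MR signal physics (saturation recovery, T1,
signal saturation of the blood pool at high contrast doses),
contrast-agent recirculation, elastic deformation, through-plane motion,
and anatomical variability beyond disc/annulus geometry. Passing the
phantom batteries therefore demonstrates that the *algorithmic chain* is
correct and robust to the modelled artefacts — not that it handles every
clinical series; saturation in particular is why dedicated low-resolution
AIF series exist, and the package follows that design rather than
correcting saturation.

Truth masks live in the phantom's base geometry while the corrected
series lives in the geometry of the registration reference frame, so
evaluations shift the truth masks by the reference frame's (rounded) true
displacement before computing overlap — the standard protocol when
scoring registered outputs against simulated truth.

## Numerical and degenerate-input choices

Coordinates are 1-based (row, col) with inclusive bounding boxes,
matrix-style, throughout. Time is always seconds internally; frame
indices exist only at the I/O edge. Flat pixel curves correlate 0 (never
NaN). Empty candidate sets, ICA ambiguity (equal source peak times) and
timing failures raise conditions with distinct classes
(`aifx_empty_candidates`, `aifx_ica_failure`, `aifx_timing_error`) so a
caller — including the CLI wrapper, which maps them to exit codes 2/3/4 —
can tell over-segmentation from separation failure from a degenerate
curve. Rank ties in the vote share averaged scores (preserving the
N(N+1)/2 per-feature sum); selection ties break on M, then
centre-distance. All randomised components (ICA retries, phantom noise,
bootstrap CIs) are seed-controlled; a fixed default rotation makes the
default ICA path fully deterministic.

## Validation batteries and problem sizes

The test suite and `scripts/acceptance.R` use: 50 default phantoms for
AIF fidelity (median Pearson r and NRMSE against truth), 100
randomized-geometry phantoms for robustness (LV Dice > 0.5), 20 for
papillary exclusion, 10 for threshold monotonicity, one noiseless
phantom for timing (peak checked exactly against `t0 + αβ`; start
against the same geometric rule at 1000× oversampling), 20 random 2 × 2
mixtures for ICA recovery, 3 phantoms at 4 px amplitude for motion
recovery, and 100 noise seeds at each of F = 1.1 and 3.2 ml/g/min
(rest/stress-like) for Fermi recovery at 1 % noise. These sizes give
stable medians while keeping the default run lightweight.

## Known limitations

Translation-only motion correction; no saturation correction (AIF should
come from the dedicated series); Fermi deconvolution is one constrained
model among several (B-spline and Tikhonov variants exist); the ICA step
needs the two boluses separated by roughly 4 s or more; DICOM input is
not supported (convert to 4-D NIfTI first); myocardial contours are an
input (no myocardium segmentation), matching the manual-contour practice
the MBF comparison is designed around.
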