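# aifx

Automated arterial input function (AIF) measurement for first-pass
contrast-enhanced myocardial perfusion CMR, with Fermi-constrained
deconvolution for myocardial blood flow (MBF) quantification and a
synthetic dynamic phantom for end-to-end validation.

## The problem

Quantitative myocardial perfusion requires the AIF — the time–signal
intensity curve of the gadolinium bolus in the left-ventricular (LV) blood
pool — as the input to tissue deconvolution. Measuring it by hand means
drawing and adjusting an ROI across 45–90 dynamic frames while dodging
papillary muscles (dark intracavitary structures that depress the curve)
and partial-volume boundary pixels. That is slow and operator-dependent.
`aifx` automates the whole measurement for users doing quantitative
perfusion analysis: imaging scientists, perfusion-software developers, and
anyone who needs reproducible AIFs from dynamic series.

## The method

Given a dynamic series (one frame per cardiac cycle, optional proton
density (PD) reference frames), the pipeline runs fixed stages:

1. **Motion correction** — translation registration of consecutive frames
   by FFT cross-correlation with sub-pixel refinement, composed to a
   maximal-intensity reference frame and refined against the temporal
   mean.
2. **Heart detection** — the temporal standard-deviation map is
   thresholded at mean + 1 SD (dedicated AIF series) or + 2 SD (myocardial
   series); regions with peak < 2 × baseline intensity or peaks in the
   first/last 3 frames are dropped; regions with curve correlation > 0.75
   within a radius-sum distance are merged; a linear rank vote over
   {area, PV, upslope, M, TTP, FWHM, distance-to-centre,
   distance-to-first-pick} selects the two ventricles and sets the heart
   bounding box. The combined curve score is `M = PV / (TTP × FWHM)`.
3. **Intensity correction** — a polynomial surface fitted to the PD images
   removes surface-coil shading; the pre-contrast baseline is subtracted.
4. **Ventricular classification** — FastICA separates the two independent
   temporal sources in the candidate-ventricle pixel curves; every box
   pixel correlating > 0.7 with a source joins that chamber; the
   earlier-peaking source is the RV.
5. **AIF extraction** — LV pixels whose temporal maximum-intensity
   projection (MIP) exceeds the 75th percentile of the LV MIP range are
   averaged per frame (excluding dark papillary and partial-volume
   pixels), and the curve is linearly resampled at 0.5 s.
6. **Timing and metrics** — baseline, contrast-start and peak times are
   detected geometrically; PV, TTP, FWHM, upslope and M quantify the
   curve.
7. **MBF (optional)** — per-sector tissue curves are deconvolved under a
   Fermi impulse-response model `R(t) = F·(1 + e^{-kτ}) / (1 + e^{k(t-τ)})`;
   flow is `F = R(0)` in ml/g/min.

A `phantom_spec()`/`generate_phantom()` pair renders synthetic dual-
sequence series — RV-then-LV gamma-variate bolus, Fermi-convolved
myocardial enhancement, dark papillary blobs, coil shading, rigid motion,
noise — with full ground truth, so every stage is testable without
clinical data.

## Worked example

```r
library(aifx)

ph  <- generate_phantom(phantom_spec(seed = 1))   # synthetic AIF series
res <- run_aif_pipeline(ph$series)
res
#> <aif_pipeline>
#> <aif_timing: baseline 5.5 s, start 11.0 s, peak 17.0 s>
#>   AIF: 120 px selected at the 75% threshold (89.28 a.u.)
#> # A tibble: 1 × 6
#>      pv   ttp  fwhm upslope     m fwhm_clipped
#>   <dbl> <dbl> <dbl>   <dbl> <dbl> <lgl>
#> 1  110.     6  8.11    33.4  2.27 FALSE
```

The phantom's LV bolus arrives at 11 s and peaks at 17 s with amplitude
110 a.u.; the detected start (11.0 s), peak (17.0 s) and peak value
(110 a.u.) recover that construction. 120 bright LV pixels passed the
75 % MIP-range threshold of 89.3 a.u. — none of them papillary. Against
the exported ground-truth AIF:

```r
truth <- resample_half_second(ph$truth$aif$time_s, ph$truth$aif$signal_au)
compare_aifs(truth, res$aif)
#> # A tibble: 1 × 3
#>   pearson_r nrmse_pct     n
#>       <dbl>     <dbl> <int>
#> 1     1.000     0.876   119
```

i.e. the automated curve correlates r = 1.000 with the truth with a
root-mean-square error of 0.9 % of the curve range. `autoplot(res$aif,
timing = res$timing)` draws the curve; `plot_qc(res)` overlays the
selected pixels on the MIP image. `estimate_mbf()` + `tidy()` /
`glance()` fit per-sector flows, and `threshold_sensitivity()` repeats
the extraction at the 75/50/25 % thresholds to show the ROI-size effect
on MBF. A command-line wrapper lives at `inst/cli/aifx.R`.

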