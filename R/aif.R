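new_aif_curve <- function(time_s, signal_au, ...) {
  out <- tibble(time_s = time_s, signal_au = signal_au)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c("aif_curve", class(out))
  out
}

#' Resample a time-signal curve to the half-second grid
#'
#' Linear interpolation of an intensity curve onto `t = 0, 0.5, 1, ...`
#' seconds (starting at the first multiple of 0.5 s covered by the data),
#' converting the time unit from image frames to seconds.  No
#' extrapolation is performed.
#'
#' @param times sample times in seconds, strictly increasing.
#' @param values signal values (a.u.).
#' @return An `aif_curve` tibble with columns `time_s`, `signal_au`.
#' @examples
#' resample_half_second(c(0, 1, 2), c(0, 2, 4))
#' @export
resample_half_second <- function(times, values) {
  if (length(times) < 2)
    aifx_error("aifx_format_error", "need at least 2 samples to resample")
  if (any(diff(times) <= 0))
    aifx_error("aifx_format_error", "times must be strictly increasing")
  grid <- seq(ceiling(times[1] / 0.5) * 0.5, times[length(times)], by = 0.5)
  new_aif_curve(grid, approx(times, values, xout = grid)$y)
}

#' Extract the arterial input function from the LV region
#'
#' Thresholds the temporal maximum-intensity projection (MIP) of the LV
#' pixels at `min + percentile/100 * (max - min)` of the LV MIP range and
#' averages the surviving (brightest) pixels per frame.  This excludes dark
#' papillary-muscle pixels and partial-volume boundary pixels that would
#' depress the AIF peak.  The curve is then resampled at 0.5 s.
#'
#' @param series motion- and intensity-corrected [perfusion_series()].
#' @param lv_mask logical `H x W` LV mask (e.g. [lv_mask()] of a
#'   classification).
#' @param percentile threshold position in the LV MIP range; 75 is the
#'   default ROI, 50 and 25 give progressively larger ROIs.
#' @param mode `"range"` (percentage of the MIP min-max range, default) or
#'   `"quantile"` (order statistic of the MIP values).
#' @param resample resample to the 0.5 s grid (default) or keep frame times.
#' @return An `aif_curve` tibble with attributes `pixels` (logical mask of
#'   the selected pixels), `threshold`, `percentile`, `n_pixels`.
#' @export
extract_aif <- function(series, lv_mask, percentile = 75,
                        mode = c("range", "quantile"), resample = TRUE) {
  mode <- match.arg(mode)
  if (!any(lv_mask))
    aifx_error("aifx_empty_candidates", "LV mask is empty")
  mip <- apply(series$data, c(1, 2), max)
  vals <- mip[lv_mask]
  thr <- if (mode == "range") {
    min(vals) + percentile / 100 * (max(vals) - min(vals))
  } else unname(quantile(vals, percentile / 100))
  sel <- lv_mask & mip >= thr
  if (!any(sel))
    aifx_error("aifx_empty_candidates", "no LV pixels survive the threshold")
  curve <- mask_curve(series, sel)
  if (resample) {
    out <- resample_half_second(series$times, curve)
  } else {
    out <- new_aif_curve(series$times, curve)
  }
  attr(out, "pixels") <- sel
  attr(out, "threshold") <- thr
  attr(out, "percentile") <- percentile
  attr(out, "n_pixels") <- sum(sel)
  out
}

#' Detect bolus timing points on an AIF curve
#'
#' Finds the three contrast-enhancement time points: peak time (curve
#' maximum), baseline time (the sample with minimal intensity variation
#' relative to its neighbours, before the steepest rise), and start time
#' (the curve sample geometrically closest, in normalised time/intensity
#' coordinates, to the intersection of a least-squares line through the
#' rising segment with the horizontal baseline level).
#'
#' @param curve an `aif_curve`, or a numeric vector of values when `times`
#'   is given.
#' @param times optional sample times (s) when `curve` is a plain vector.
#' @return An `aif_timing` list: `baseline_time`, `start_time`,
#'   `peak_time` (s) and `baseline_value` (a.u.).
#' @export
timing_points <- function(curve, times = NULL) {
  if (is.null(times)) { t <- curve$time_s; v <- curve$signal_au }
  else { t <- times; v <- curve }
  n <- length(v)
  if (n < 5 || sd(v) == 0)
    aifx_error("aifx_timing_error", "curve too short or flat for timing detection")
  peak_idx <- which.max(v)
  if (peak_idx == 1 || peak_idx == n)
    aifx_error("aifx_timing_error", "curve peaks at the first or last sample")

  # anchor: steepest single-step rise before the peak
  anchor <- which.max(diff(v[seq_len(peak_idx)]))
  base_idx <- if (anchor >= 3) {
    cand <- 2:(anchor - 1) + 0L
    rough <- abs(v[cand - 1] - v[cand]) + abs(v[cand + 1] - v[cand])
    cand[which.min(rough)]
  } else 1L
  bl <- v[base_idx]
  pv <- v[peak_idx] - bl
  if (pv <= 0)
    aifx_error("aifx_timing_error", "no enhancement above baseline")

  seg <- which(v >= bl + 0.1 * pv & v <= bl + 0.9 * pv)
  seg <- seg[seg >= base_idx & seg <= peak_idx]
  if (length(seg) < 2) seg <- c(anchor, anchor + 1)
  slope <- ls_slope(t[seg], v[seg])
  if (!is.finite(slope) || slope <= 0)
    aifx_error("aifx_timing_error", "rising segment has non-positive slope")
  intercept <- mean(v[seg]) - slope * mean(t[seg])
  t_star <- (bl - intercept) / slope

  span <- t[n] - t[1]
  ii <- seq_len(peak_idx)
  d2 <- ((t[ii] - t_star) / span)^2 + ((v[ii] - bl) / pv)^2
  start_idx <- ii[which.min(d2)]
  if (start_idx < base_idx) start_idx <- base_idx
  if (start_idx == peak_idx) start_idx <- peak_idx - 1L

  structure(list(baseline_time = t[base_idx],
                 start_time = t[start_idx],
                 peak_time = t[peak_idx],
                 baseline_value = bl),
            class = "aif_timing")
}

#' @export
print.aif_timing <- function(x, ...) {
  cat(sprintf("<aif_timing: baseline %.1f s, start %.1f s, peak %.1f s>\n",
              x$baseline_time, x$start_time, x$peak_time))
  invisible(x)
}

# Shared metric computation given resolved timing quantities.
metrics_core <- function(t, v, bl, start_time, peak_time) {
  peak_idx <- which.min(abs(t - peak_time))
  pv <- max(v) - bl
  ttp <- peak_time - start_time
  half <- bl + pv / 2

  # last up-crossing before the peak
  pre <- which(v[seq_len(peak_idx)] < half)
  t_up <- if (length(pre) == 0) t[1] else {
    i <- max(pre)
    t[i] + (half - v[i]) / (v[i + 1] - v[i]) * (t[i + 1] - t[i])
  }
  post <- which(v < half & seq_along(v) > peak_idx)
  clipped <- length(post) == 0
  t_down <- if (clipped) t[length(t)] else {
    j <- min(post)
    t[j - 1] + (v[j - 1] - half) / (v[j - 1] - v[j]) * (t[j] - t[j - 1])
  }
  fwhm <- t_down - t_up

  win <- which(t >= start_time & t <= peak_time)
  upslope <- if (length(win) >= 3) {
    max(vapply(seq_len(length(win) - 2), function(k) {
      idx <- win[k:(k + 2)]
      ls_slope(t[idx], v[idx])
    }, 0))
  } else if (length(win) == 2) {
    (v[win[2]] - v[win[1]]) / (t[win[2]] - t[win[1]])
  } else NA_real_
  m <- pv / (ttp * fwhm)
  list(pv = pv, ttp = ttp, fwhm = fwhm, upslope = upslope, m = m,
       fwhm_clipped = clipped)
}

#' Quality metrics of an AIF curve
#'
#' Computes the contrast-enhancement characteristics used to compare AIF
#' measurements: peak value above baseline (PV), time to peak from contrast
#' start (TTP), baseline-referenced full width at half maximum (FWHM),
#' maximal upslope (best least-squares slope over a sliding 3-sample
#' window between start and peak), and the combined
#' `M = PV / (TTP * FWHM)`.  A good AIF has high PV, upslope and M, and
#' low TTP and FWHM.
#'
#' @param curve an `aif_curve`.
#' @param timing an `aif_timing`; detected from `curve` when omitted.
#' @return One-row tibble: `pv` (a.u.), `ttp` (s), `fwhm` (s), `upslope`
#'   (a.u./s), `m` (a.u./s^2), `fwhm_clipped` (TRUE when the curve never
#'   falls below half height before the series ends).
#' @export
curve_metrics <- function(curve, timing = timing_points(curve)) {
  mc <- metrics_core(curve$time_s, curve$signal_au, timing$baseline_value,
                     timing$start_time, timing$peak_time)
  tibble(pv = mc$pv, ttp = mc$ttp, fwhm = mc$fwhm, upslope = mc$upslope,
         m = mc$m, fwhm_clipped = mc$fwhm_clipped)
}

#' Compare two AIF curves
#'
#' Pearson correlation and normalised root-mean-square error between two
#' curves on their common time grid; the NRMSE is normalised by the
#' min-max range of the reference curve `a` and reported in percent.
#'
#' @param a reference `aif_curve`.
#' @param b comparison `aif_curve`.
#' @return One-row tibble: `pearson_r`, `nrmse_pct`, `n` overlapping
#'   samples.
#' @export
compare_aifs <- function(a, b) {
  ka <- round(a$time_s * 2)
  kb <- round(b$time_s * 2)
  common <- intersect(ka, kb)
  if (length(common) < 3)
    aifx_error("aifx_format_error", "fewer than 3 overlapping samples")
  va <- a$signal_au[match(common, ka)]
  vb <- b$signal_au[match(common, kb)]
  rng <- max(va) - min(va)
  tibble(
    pearson_r = safe_cor(va, vb),
    nrmse_pct = sqrt(mean((vb - va)^2)) / rng * 100,
    n = length(common)
  )
}
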