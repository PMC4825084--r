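#' Surface-coil intensity correction from PD frames
#'
#' Fits a 2-D polynomial intensity surface to the averaged proton-density
#' frames by weighted least squares (foreground pixels above the Otsu
#' threshold of the PD image get weight 1, background 0.1 — a simplified
#' foreground/background weighting) and divides every frame by the
#' surface, normalised to mean 1 over the heart box so that signal levels
#' inside the heart are preserved.  Each pixel's curve is scaled by a
#' time-constant factor, so temporal shape is untouched.
#'
#' @param series a [perfusion_series()] with PD frames; without them the
#'   operation is a no-op with a warning.
#' @param box optional `heart_box` over which the surface is normalised;
#'   whole image when `NULL`.
#' @param poly_order polynomial total degree (default 3); rank-deficient
#'   fits fall back to lower orders with a warning.
#' @return The corrected [perfusion_series()] with the normalised surface
#'   in attribute `"surface"`.
#' @export
coil_correct <- function(series, box = NULL, poly_order = 3) {
  if (is.null(series$pd)) {
    warning("no PD frames present; coil correction skipped")
    return(series)
  }
  pdm <- Reduce(`+`, series$pd) / length(series$pd)
  nr <- nrow(pdm); nc <- ncol(pdm)
  rng <- range(pdm)
  w <- matrix(0.1, nr, nc)
  if (diff(rng) > 0) {
    norm <- (pdm - rng[1]) / diff(rng)
    thr <- EBImage::otsu(norm, range = c(0, 1))
    w[norm > thr] <- 1
  }
  rows <- rep(seq_len(nr), nc)
  cols <- rep(seq_len(nc), each = nr)
  surf <- NULL
  for (deg in poly_order:1) {
    X <- poly2d_design(rows, cols, nr, nc, deg)
    fit <- tryCatch(lm.wfit(X, as.vector(pdm), as.vector(w)),
                    error = function(e) NULL)
    if (!is.null(fit) && fit$rank == ncol(X)) {
      surf <- matrix(X %*% fit$coefficients, nr, nc)
      if (deg < poly_order)
        warning(sprintf("surface fit rank-deficient; fell back to order %d", deg))
      break
    }
  }
  if (is.null(surf))
    aifx_error("aifx_format_error", "polynomial surface fit failed")
  # guard against division blow-up where the fitted surface dips low
  surf <- pmax(surf, 0.05 * max(surf))
  norm_mask <- if (is.null(box)) matrix(TRUE, nr, nc) else box_mask(box, c(nr, nc))
  surf <- surf / mean(surf[norm_mask])
  out <- series
  for (t in seq_len(n_frames(series)))
    out$data[, , t] <- series$data[, , t] / surf
  out$pd <- lapply(series$pd, function(p) p / surf)
  attr(out, "surface") <- surf
  out
}

# First frame index at which the whole-image mean curve rises clearly
# above its early level; used to pick default baseline frames.
detect_onset <- function(series) {
  m <- apply(series$data, 3, mean)
  bl <- mean(m[1:3])
  rng <- max(m) - min(m)
  if (rng <= 0) return(NA_integer_)
  hit <- which(m > bl + 0.1 * rng)
  hit <- hit[hit > 1]
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Remove pre-contrast baseline intensity
#'
#' Subtracts the per-pixel mean over the pre-contrast (baseline) frames
#' from every frame.  By default the baseline frames are those before the
#' automatically detected onset of the whole-image mean curve, falling
#' back to the first 3 frames.
#'
#' @param series a [perfusion_series()].
#' @param baseline_frames integer vector of frame indices; auto-detected
#'   when `NULL`.
#' @return The baseline-removed [perfusion_series()], with the frames used
#'   in attribute `"baseline_frames"`.
#' @export
remove_baseline <- function(series, baseline_frames = NULL) {
  if (is.null(baseline_frames)) {
    onset <- detect_onset(series)
    baseline_frames <- if (!is.na(onset) && onset > 1) seq_len(onset - 1) else 1:3
  }
  if (length(baseline_frames) == 0)
    aifx_error("aifx_parameter_error", "baseline frame set is empty")
  bl <- apply(series$data[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  out <- series
  for (t in seq_len(n_frames(series)))
    out$data[, , t] <- series$data[, , t] - bl
  attr(out, "baseline_frames") <- baseline_frames
  out
}
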