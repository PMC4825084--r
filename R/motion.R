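#' Motion-correct a perfusion series
#'
#' Estimates and removes in-plane cardiac/respiratory motion with a
#' translation (rigid) model: displacements between consecutive frames are
#' measured by FFT cross-correlation of Gaussian-smoothed, mean-removed
#' frames with parabolic sub-pixel refinement, composed to a reference
#' frame, and then refined against the temporal mean of the corrected
#' stack.  Consecutive-frame matching keeps the brightness-constancy
#' assumption workable despite contrast wash-in; the reference is the frame
#' of maximal total intensity (near the LV bolus peak), the most stable
#' anchor.
#'
#' @param series a [perfusion_series()].
#' @param sigma_px Gaussian pre-smoothing standard deviation (px) before
#'   correlation.
#' @param reference `"auto"` (maximal-intensity frame) or a frame index.
#' @param refine_iters refinement passes against the temporal mean.
#' @return List with
#'   * `series`: the motion-corrected [perfusion_series()];
#'   * `displacements`: `T x 2` matrix of `(row, col)` shifts in px mapping
#'     corrected to original coordinates (`corrected(x) = original(x + d)`);
#'   * `reference`: the reference frame index.
#'   Degenerate (constant) frames get an identity displacement with a
#'   warning.
#' @export
register_series <- function(series, sigma_px = 1, reference = "auto",
                            refine_iters = 2) {
  nt <- n_frames(series)
  sm <- lapply(seq_len(nt), function(t) {
    f <- frame_mat(series, t)
    if (sigma_px > 0) f <- as.matrix(EBImage::gblur(f, sigma = sigma_px))
    f
  })
  flat <- vapply(sm, function(f) sd(f) == 0, logical(1))
  if (any(flat))
    warning("constant frame(s) encountered; identity displacement used")
  ref <- if (identical(reference, "auto")) {
    which.max(vapply(seq_len(nt), function(t) sum(frame_mat(series, t)), 0))
  } else as.integer(reference)

  # pairwise shifts composed to the reference
  step <- matrix(0, nt, 2)
  for (t in 2:nt) {
    if (flat[t] || flat[t - 1]) next
    step[t, ] <- xcorr_shift(sm[[t - 1]], sm[[t]])
  }
  cum <- apply(step, 2, cumsum)
  disp <- sweep(cum, 2, cum[ref, ])          # shift of frame t vs reference

  corrected <- function(d) {
    out <- series$data
    for (t in seq_len(nt))
      if (any(d[t, ] != 0))
        out[, , t] <- warp_translate(series$data[, , t], d[t, 1], d[t, 2])
    out
  }
  stack <- corrected(disp)
  for (it in seq_len(refine_iters)) {
    template <- apply(stack, c(1, 2), mean)
    if (sigma_px > 0) template <- as.matrix(EBImage::gblur(template, sigma = sigma_px))
    upd <- FALSE
    for (t in seq_len(nt)) {
      if (flat[t]) next
      f <- stack[, , t]
      if (sigma_px > 0) f <- as.matrix(EBImage::gblur(f, sigma = sigma_px))
      r <- xcorr_shift(template, f, max_shift = 3)
      if (any(abs(r) > 0.02)) {
        disp[t, ] <- disp[t, ] + r
        upd <- TRUE
      }
    }
    if (!upd) break
    stack <- corrected(disp)
  }
  disp[flat, ] <- 0
  out <- series
  out$data <- stack
  list(series = out, displacements = disp, reference = ref)
}

# Translation of `img` relative to `refimg` (positive = img content moved
# towards larger row/col), via FFT circular cross-correlation and a
# parabolic sub-pixel fit around the integer peak.
xcorr_shift <- function(refimg, img, max_shift = Inf) {
  a <- refimg - mean(refimg)
  b <- img - mean(img)
  nr <- nrow(a); nc <- ncol(a)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE))
  # admissible circular lags
  rows <- c(0:(nr %/% 2), -((nr - 1) %/% 2):-1)
  cols <- c(0:(nc %/% 2), -((nc - 1) %/% 2):-1)
  ok <- outer(abs(rows) <= max_shift, abs(cols) <= max_shift)
  cc[!ok] <- -Inf
  pk <- arrayInd(which.max(cc), dim(cc))
  dr <- rows[pk[1]]; dc <- cols[pk[2]]
  sub <- function(ir, ic) cc[(ir - 1) %% nr + 1, (ic - 1) %% nc + 1]
  par1 <- function(m, z, p) {
    if (!is.finite(m) || !is.finite(p)) return(0)
    den <- m - 2 * z + p
    if (den >= 0) return(0)
    d <- 0.5 * (m - p) / den
    max(min(d, 0.5), -0.5)
  }
  fr <- par1(sub(pk[1] - 1, pk[2]), cc[pk[1], pk[2]], sub(pk[1] + 1, pk[2]))
  fc <- par1(sub(pk[1], pk[2] - 1), cc[pk[1], pk[2]], sub(pk[1], pk[2] + 1))
  # the correlation peak sits at minus the shift of img relative to refimg
  -c(dr + fr, dc + fc)
}
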