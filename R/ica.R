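# Canonicalise an ICA source: sign-flip so the dominant excursion is
# positive, then rescale to unit maximum.
canonicalize_source <- function(s) {
  if (max(s) < -min(s)) s <- -s
  mx <- max(s)
  if (mx > 0) s / mx else s
}

#' Separate the two ventricular source signals by ICA
#'
#' Treats the pixel curves of the selected candidate ventricle regions as
#' mixtures of two independent temporal sources (the RV and LV bolus
#' transits) and extracts them with FastICA (fixed-point iteration,
#' kurtosis contrast, deterministic initial rotation).  Sources are
#' canonicalised to a positive peak and unit maximum.  On failure the
#' extraction is retried with seeded random rotations and finally falls
#' back to the two candidate-region mean curves with a warning.
#'
#' @param series the intensity-corrected [perfusion_series()].
#' @param regions list of two `region_candidate`s (the vote winners), or
#'   any list of masks whose pixel curves to unmix.
#' @param seed seed for the retry rotations.
#' @param max_retries ICA restarts before falling back.
#' @return `T x 2` matrix of canonicalised source curves (unordered;
#'   chamber assignment happens in [classify_pixels()]), with attribute
#'   `"fallback"` when the mean-curve fallback was used.
#' @export
ica_sources <- function(series, regions, seed = 42L, max_retries = 5L) {
  masks <- lapply(regions, function(r) if (is.list(r)) r$mask else r)
  mask <- Reduce(`|`, masks)
  X <- pixel_curves(series, mask)     # T x n pixels
  if (ncol(X) < 2)
    aifx_error("aifx_ica_failure", "fewer than 2 pixels available for ICA")
  S <- NULL
  for (try in 0:max_retries) {
    Rmat <- if (try == 0) diag(2) else {
      set.seed(seed + try)
      qr.Q(qr(matrix(rnorm(4), 2)))
    }
    S <- tryCatch({
      fit <- ica::icafast(X, nc = 2, alg = "par", fun = "kur",
                          maxit = 500, Rmat = Rmat)
      if (any(!is.finite(fit$S))) NULL else fit$S
    }, error = function(e) NULL)
    if (!is.null(S)) break
  }
  if (is.null(S)) {
    if (length(masks) < 2)
      aifx_error("aifx_ica_failure", "ICA failed and no fallback curves available")
    warning("ICA did not converge; falling back to candidate mean curves")
    S <- cbind(mask_curve(series, masks[[1]]), mask_curve(series, masks[[2]]))
    attr(S, "fallback") <- TRUE
  }
  S <- apply(S, 2, canonicalize_source)
  S
}

#' Classify heart-box pixels to RV, LV or background
#'
#' Correlates every pixel curve inside the heart box with both ICA source
#' curves; pixels whose best Pearson correlation exceeds `corr_threshold`
#' are assigned to that source's chamber, the rest are background.  The
#' source peaking first is the RV (contrast reaches it before the LV);
#' zero-variance pixel curves correlate 0 and land in the background.
#'
#' @param series the intensity-corrected [perfusion_series()].
#' @param box a `heart_box` from [heart_box()].
#' @param sources `T x 2` source matrix from [ica_sources()].
#' @param corr_threshold assignment threshold (default 0.7).
#' @return A `ventricle_maps` object: `labels` (factor matrix over the box,
#'   levels background/RV/LV), correlation maps `cor_rv`/`cor_lv`, the
#'   chamber-ordered `sources` and `box`.  Use [lv_mask()] / [rv_mask()]
#'   for full-image masks.
#' @export
classify_pixels <- function(series, box, sources, corr_threshold = 0.7) {
  p1 <- which.max(sources[, 1])
  p2 <- which.max(sources[, 2])
  if (p1 == p2)
    aifx_error("aifx_ica_failure",
               "ambiguous chambers: both sources peak at the same time")
  rv_col <- if (p1 < p2) 1L else 2L
  rv <- sources[, rv_col]; lv <- sources[, 3 - rv_col]
  rows <- box[1]:box[3]; cols <- box[2]:box[4]
  nr <- length(rows); nc <- length(cols)
  cor_rv <- matrix(0, nr, nc); cor_lv <- matrix(0, nr, nc)
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    v <- series$data[rows[i], cols[j], ]
    cor_rv[i, j] <- safe_cor(v, rv)
    cor_lv[i, j] <- safe_cor(v, lv)
  }
  lab <- matrix("background", nr, nc)
  best <- pmax(cor_rv, cor_lv)
  lab[best > corr_threshold & cor_rv >= cor_lv] <- "RV"
  lab[best > corr_threshold & cor_lv > cor_rv] <- "LV"
  structure(list(
    labels = lab,
    cor_rv = cor_rv, cor_lv = cor_lv,
    sources = cbind(rv = rv, lv = lv),
    times = series$times,
    box = box, shape = dim(series)[1:2]
  ), class = "ventricle_maps")
}

#' @export
print.ventricle_maps <- function(x, ...) {
  cat(sprintf("<ventricle_maps: box (%d,%d)-(%d,%d), RV %d px, LV %d px>\n",
              x$box[1], x$box[2], x$box[3], x$box[4],
              sum(x$labels == "RV"), sum(x$labels == "LV")))
  invisible(x)
}

#' Full-image ventricle masks from a classification
#'
#' @param maps a `ventricle_maps` object.
#' @return Logical `H x W` mask of the LV (or RV) pixels.
#' @export
lv_mask <- function(maps) {
  m <- matrix(FALSE, maps$shape[1], maps$shape[2])
  m[maps$box[1]:maps$box[3], maps$box[2]:maps$box[4]] <- maps$labels == "LV"
  m
}

#' @rdname lv_mask
#' @export
rv_mask <- function(maps) {
  m <- matrix(FALSE, maps$shape[1], maps$shape[2])
  m[maps$box[1]:maps$box[3], maps$box[2]:maps$box[4]] <- maps$labels == "RV"
  m
}
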