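#' Temporal standard-deviation map
#'
#' Per-pixel population (1/T) standard deviation over time.  Pixels swept
#' by the contrast bolus vary strongly and light up; constantly bright
#' structures such as the chest wall do not.
#'
#' @param series a motion-corrected [perfusion_series()].
#' @return `H x W` matrix.
#' @export
std_map <- function(series) {
  m1 <- apply(series$data, c(1, 2), mean)
  m2 <- apply(series$data^2, c(1, 2), mean)
  sqrt(pmax(m2 - m1^2, 0))
}

# Dynamic threshold at k standard deviations above the map mean.
sd_threshold <- function(map, k_sigma) mean(map) + k_sigma * sd(map)

# Build a region candidate from a pixel mask: mean curve plus the features
# used by the rank-vote (robust fallbacks when timing detection fails on
# a non-bolus-like curve).
make_candidate <- function(series, mask, id, baseline_frames = 3) {
  curve <- mask_curve(series, mask)
  t <- series$times
  idx <- which(mask, arr.ind = TRUE)
  centroid <- colMeans(idx)
  area <- nrow(idx)
  bl3 <- mean(curve[seq_len(min(baseline_frames, length(curve)))])
  peak_idx <- which.max(curve)
  tp <- tryCatch(timing_points(curve, times = t), error = function(e) NULL)
  if (is.null(tp)) {
    above <- which(curve >= bl3 + 0.1 * (curve[peak_idx] - bl3))
    start_time <- if (length(above)) t[above[1]] else t[1]
    if (start_time >= t[peak_idx]) start_time <- t[max(peak_idx - 1, 1)]
    tp <- list(baseline_time = t[1], start_time = start_time,
               peak_time = t[peak_idx], baseline_value = bl3)
  }
  mc <- tryCatch(
    metrics_core(t, curve, tp$baseline_value, tp$start_time, tp$peak_time),
    error = function(e) list(pv = curve[peak_idx] - bl3, ttp = NA_real_,
                             fwhm = NA_real_, upslope = NA_real_, m = NA_real_))
  shape <- dim(series)[1:2]
  center <- (shape + 1) / 2
  structure(list(
    id = id, mask = mask, curve = curve, centroid = centroid,
    area = area, radius = sqrt(area / pi),
    baseline = bl3, peak_idx = peak_idx,
    features = c(area = area, pv = mc$pv, ttp = mc$ttp, fwhm = mc$fwhm,
                 upslope = mc$upslope, m = mc$m,
                 dist_center = sqrt(sum((centroid - center)^2)))
  ), class = "region_candidate")
}

#' Candidate ventricle regions from the standard-deviation map
#'
#' Binarises the map at `mean + k * sd` (k = 1 for the dedicated AIF
#' series, k = 2 for the myocardial series), labels 8-connected components
#' and keeps those above a minimum size, attaching each region's mean
#' time-signal curve and vote features.
#'
#' @param series the motion-corrected [perfusion_series()].
#' @param map standard-deviation map; computed from `series` when omitted.
#' @param k_sigma threshold offset in map standard deviations; defaults to
#'   1 or 2 according to `series$kind`.
#' @param min_px minimum region size in pixels (default 4 for the AIF
#'   series, 16 for the myocardial series; tiny specks break the feature
#'   estimates).
#' @return List of `region_candidate` objects.
#' @export
threshold_candidates <- function(series, map = std_map(series),
                                 k_sigma = NULL, min_px = NULL) {
  if (is.null(k_sigma)) k_sigma <- if (series$kind == "aif") 1 else 2
  if (is.null(min_px)) min_px <- if (series$kind == "aif") 4L else 16L
  thr <- sd_threshold(map, k_sigma)
  lab <- label8(map > thr)
  n <- max(lab)
  if (n == 0)
    aifx_error("aifx_empty_candidates",
               "no pixels survive the standard-deviation threshold")
  sizes <- tabulate(lab[lab > 0], n)
  keep <- which(sizes >= min_px)
  if (length(keep) == 0)
    aifx_error("aifx_empty_candidates",
               "all thresholded regions are below the minimum size")
  cands <- lapply(seq_along(keep), function(i)
    make_candidate(series, lab == keep[i], id = i))
  cands
}

#' Filter candidates by temporal signal characteristics
#'
#' Removes regions with minimal contrast enhancement (peak intensity less
#' than twice their baseline intensity, the mean of the first
#' `baseline_frames` frames) and regions whose peak falls within the first
#' or last 3 frames of the series.
#'
#' @param cands list of `region_candidate`s.
#' @param n_frames number of frames `T` in the series.
#' @param edge_frames frames at either end disqualifying a peak.
#' @return Filtered list; errors with class `aifx_empty_candidates` if
#'   nothing survives.
#' @export
filter_candidates <- function(cands, n_frames, edge_frames = 3) {
  keep <- vapply(cands, function(cn) {
    peak <- max(cn$curve)
    if (peak < 2 * cn$baseline) return(FALSE)
    if (cn$peak_idx <= edge_frames || cn$peak_idx > n_frames - edge_frames)
      return(FALSE)
    TRUE
  }, logical(1))
  if (!any(keep))
    aifx_error("aifx_empty_candidates",
               "no candidate region passes the enhancement/timing filters")
  cands[keep]
}

min_mask_distance <- function(m1, m2) {
  p1 <- which(m1, arr.ind = TRUE)
  p2 <- which(m2, arr.ind = TRUE)
  d2 <- outer(p1[, 1], p2[, 1], `-`)^2 + outer(p1[, 2], p2[, 2], `-`)^2
  sqrt(min(d2))
}

#' Merge similar candidate regions
#'
#' Regions whose mean curves have a Pearson correlation above `corr` and
#' whose minimum inter-pixel Euclidean distance is below the sum of their
#' average radii are treated as one ventricle split by papillary muscles
#' or artefacts, and unioned (transitively); curves and features are
#' recomputed over the union.
#'
#' @param cands list of `region_candidate`s.
#' @param series the series used to recompute merged curves.
#' @param corr correlation threshold (default 0.75).
#' @return List of merged `region_candidate`s.
#' @export
merge_similar <- function(cands, series, corr = 0.75) {
  n <- length(cands)
  if (n <= 1) return(cands)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    r <- safe_cor(cands[[i]]$curve, cands[[j]]$curve)
    if (r <= corr) next
    dmin <- min_mask_distance(cands[[i]]$mask, cands[[j]]$mask)
    if (dmin < cands[[i]]$radius + cands[[j]]$radius) {
      a <- find(i); b <- find(j)
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  groups <- split(seq_len(n), roots)
  out <- lapply(seq_along(groups), function(g) {
    ids <- groups[[g]]
    if (length(ids) == 1) {
      cn <- cands[[ids]]; cn$id <- g; return(cn)
    }
    mask <- Reduce(`|`, lapply(cands[ids], `[[`, "mask"))
    make_candidate(series, mask, id = g)
  })
  out
}

# One voting round: rank each feature 1..N (N best), ties averaged, total.
vote_round <- function(feats, lower_better) {
  scores <- sapply(colnames(feats), function(f) {
    x <- feats[, f]
    x[!is.finite(x)] <- if (f %in% lower_better) Inf else -Inf
    if (f %in% lower_better) rank(-x, ties.method = "average")
    else rank(x, ties.method = "average")
  })
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  rowSums(scores)
}

#' Rank-vote the two most ventricle-like candidate regions
#'
#' Linear voting: for each feature the candidates are ranked 1..N (N best:
#' larger area, PV, upslope and M; smaller TTP, FWHM and distance to image
#' centre) and the scores summed; the top total is the first ventricle.
#' The vote is repeated for the second pick with the distance to the first
#' selection as an additional (smaller-better) feature.  Ties break on
#' higher M-value, then smaller distance to centre.
#'
#' @param cands list of at least two `region_candidate`s.
#' @return List with `first` and `second` (`region_candidate`s) and
#'   `scores`, a tibble of per-candidate totals for both rounds.
#' @export
vote_ventricles <- function(cands) {
  n <- length(cands)
  if (n < 2)
    aifx_error("aifx_empty_candidates",
               "need at least two candidate regions to vote")
  feats <- do.call(rbind, lapply(cands, `[[`, "features"))
  lower <- c("ttp", "fwhm", "dist_center", "dist_prev")
  pick <- function(totals, idx) {
    ord <- order(-totals,
                 -vapply(cands[idx], function(cn) cn$features["m"], 0),
                 vapply(cands[idx], function(cn) cn$features["dist_center"], 0))
    idx[ord[1]]
  }
  t1 <- vote_round(feats, lower)
  first <- pick(t1, seq_len(n))
  rest <- setdiff(seq_len(n), first)
  dprev <- vapply(cands[rest], function(cn)
    min_mask_distance(cn$mask, cands[[first]]$mask), 0)
  f2 <- cbind(feats[rest, , drop = FALSE], dist_prev = dprev)
  t2 <- vote_round(f2, lower)
  second <- pick(t2, rest)
  scores <- tibble(
    id = vapply(cands, function(cn) as.integer(cn$id), 0L),
    total_round1 = t1,
    total_round2 = replace(rep(NA_real_, n), rest, t2),
    selected = ifelse(seq_len(n) == first, "first",
                      ifelse(seq_len(n) == second, "second", ""))
  )
  list(first = cands[[first]], second = cands[[second]], scores = scores)
}

#' Bounding box around the two selected ventricles
#'
#' Tight union box of the two regions expanded by `margin` of the box size
#' per side and clipped to the image; 1-based inclusive
#' `(row0, col0, row1, col1)`.
#'
#' @param first,second selected `region_candidate`s.
#' @param shape image shape `c(H, W)`.
#' @param margin fractional expansion per side.
#' @return Integer vector of class `heart_box`.
#' @export
heart_box <- function(first, second, shape, margin = 0.25) {
  both <- which(first$mask | second$mask, arr.ind = TRUE)
  r <- range(both[, 1]); c <- range(both[, 2])
  mr <- (r[2] - r[1] + 1) * margin
  mc <- (c[2] - c[1] + 1) * margin
  box <- c(max(1, floor(r[1] - mr)), max(1, floor(c[1] - mc)),
           min(shape[1], ceiling(r[2] + mr)), min(shape[2], ceiling(c[2] + mc)))
  structure(as.integer(box), class = "heart_box",
            names = c("row0", "col0", "row1", "col1"))
}

box_mask <- function(box, shape) {
  m <- matrix(FALSE, shape[1], shape[2])
  m[box[1]:box[3], box[2]:box[4]] <- TRUE
  m
}
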