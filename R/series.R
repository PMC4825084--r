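#' Construct a perfusion image series
#'
#' The canonical in-memory container for a dynamic first-pass perfusion
#' series: an `H x W x T` intensity stack (arbitrary units, one frame per
#' cardiac cycle), per-frame acquisition times in seconds, optional proton
#' density (PD) reference frames, and the series kind.  The dedicated AIF
#' series is a low-resolution acquisition with little signal saturation in
#' the blood pool; the myocardial series is the high-resolution acquisition
#' used for tissue curves.
#'
#' All masks and coordinates in this package are 1-based `(row, col)` with
#' frames indexed `1..T`; time is always seconds internally.
#'
#' @param data numeric `H x W x T` array of frame intensities (a.u.).
#' @param times numeric vector of frame acquisition times in seconds,
#'   strictly increasing.  Defaults to `(0:(T-1)) * rr_interval`.
#' @param rr_interval R-R interval in seconds used to synthesise `times`
#'   when per-frame times are unavailable.
#' @param pd optional list of `H x W` PD matrices (coil-sensitivity
#'   references).
#' @param kind `"aif"` (dedicated low-resolution AIF series) or
#'   `"myocardial"`.
#' @param spacing optional pixel spacing in mm, length 2.
#' @return An object of class `perfusion_series`.
#' @examples
#' s <- perfusion_series(array(rnorm(8 * 8 * 12), c(8, 8, 12)))
#' dim(s)
#' @export
perfusion_series <- function(data, times = NULL, rr_interval = 1,
                             pd = NULL, kind = c("aif", "myocardial"),
                             spacing = NULL) {
  kind <- match.arg(kind)
  if (!is.array(data) || length(dim(data)) != 3L)
    aifx_error("aifx_format_error", "`data` must be an H x W x T array")
  nt <- dim(data)[3]
  if (nt < 10L)
    aifx_error("aifx_insufficient_data",
               sprintf("series has %d frames; at least 10 are required", nt))
  if (is.null(times)) times <- (seq_len(nt) - 1) * rr_interval
  if (length(times) != nt || any(diff(times) <= 0))
    aifx_error("aifx_format_error",
               "`times` must be strictly increasing with one entry per frame")
  if (!is.null(pd)) {
    pd <- lapply(pd, function(p) {
      if (!all(dim(p) == dim(data)[1:2]))
        aifx_error("aifx_format_error", "PD frame shape differs from series")
      p
    })
  }
  structure(list(data = data, times = as.numeric(times), pd = pd,
                 kind = kind, spacing = spacing),
            class = "perfusion_series")
}

#' @export
dim.perfusion_series <- function(x) dim(x$data)

#' @export
print.perfusion_series <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<perfusion_series: %s, %d x %d px, %d frames, %.2f-%.2f s%s>\n",
              x$kind, d[1], d[2], d[3], x$times[1], x$times[d[3]],
              if (is.null(x$pd)) "" else sprintf(", %d PD frames", length(x$pd))))
  invisible(x)
}

n_frames <- function(series) dim(series$data)[3]

frame_mat <- function(series, t) series$data[, , t]

# T x n matrix of the time-curves of the pixels selected by a logical mask.
pixel_curves <- function(series, mask) {
  idx <- which(mask)
  t(apply(series$data, 3, function(f) f[idx]))
}

# Mean time-signal curve over a mask (length T).
mask_curve <- function(series, mask) {
  idx <- which(mask)
  apply(series$data, 3, function(f) mean(f[idx]))
}

#' Read a perfusion series from a NIfTI file
#'
#' Reads a 4-D NIfTI-1 volume (`x, y, 1, t` or `x, y, t`) as written by
#' [write_series()] or typical DICOM-to-NIfTI converters.  Per-frame times
#' are taken as `index * rr_interval`; frames are already in acquisition
#' order in a 4-D volume.  Classic DICOM series are not supported.
#'
#' @param path path to a `.nii` / `.nii.gz` file.
#' @param kind series kind, see [perfusion_series()].
#' @param rr_interval R-R interval (s) used for frame times.
#' @param pd_path optional NIfTI file holding PD frames (3-D, last dim =
#'   number of PD frames).
#' @return A [perfusion_series()].
#' @export
read_series <- function(path, kind = c("aif", "myocardial"),
                        rr_interval = 1, pd_path = NULL) {
  kind <- match.arg(kind)
  if (dir.exists(path))
    aifx_error("aifx_format_error",
               "directory input (DICOM) is not supported; supply a 4-D NIfTI file")
  vol <- RNifti::readNifti(path)
  d <- dim(vol)
  arr <- if (length(d) == 4L) {
    array(vol, c(d[1], d[2], d[4]))
  } else if (length(d) == 3L) {
    array(vol, d)
  } else aifx_error("aifx_format_error", "expected a 3-D or 4-D NIfTI volume")
  pd <- NULL
  if (!is.null(pd_path)) {
    pv <- RNifti::readNifti(pd_path)
    pdim <- dim(pv)
    pd <- lapply(seq_len(pdim[length(pdim)]), function(k)
      matrix(if (length(pdim) == 4L) pv[, , 1, k] else pv[, , k], pdim[1], pdim[2]))
  }
  perfusion_series(arr, rr_interval = rr_interval, pd = pd, kind = kind)
}

#' Write a perfusion series to NIfTI
#'
#' Stores the stack as a 4-D `(x, y, 1, t)` NIfTI-1 volume; PD frames, when
#' present, go to `<path stem>_pd.nii.gz`.
#'
#' @param series a [perfusion_series()].
#' @param path output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_series <- function(series, path) {
  d <- dim(series$data)
  vol <- array(series$data, c(d[1], d[2], 1, d[3]))
  RNifti::writeNifti(RNifti::asNifti(vol), path)
  if (!is.null(series$pd)) {
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    pdv <- array(unlist(series$pd), c(d[1], d[2], length(series$pd)))
    RNifti::writeNifti(RNifti::asNifti(pdv), paste0(stem, "_pd.nii.gz"))
  }
  invisible(path)
}

#' Write / read an AIF curve as CSV plus JSON sidecar
#'
#' The curve is written as a two-column CSV (`time_s`, `signal_au`); the
#' extraction provenance (percentile threshold, threshold value, number of
#' selected pixels, timing points when attached) goes to `<path>.json`.
#'
#' @param curve an [aif_curve] tibble as returned by [extract_aif()] or
#'   [resample_half_second()].
#' @param path output CSV path.
#' @return `path`, invisibly (`write_aif`); an `aif_curve` (`read_aif`).
#' @export
write_aif <- function(curve, path) {
  if (NROW(curve) == 0)
    aifx_error("aifx_format_error", "refusing to write an empty AIF curve")
  write.csv(data.frame(time_s = curve$time_s, signal_au = curve$signal_au),
            path, row.names = FALSE)
  meta <- list(
    percentile = attr(curve, "percentile"),
    threshold = attr(curve, "threshold"),
    n_pixels = attr(curve, "n_pixels"),
    timing = attr(curve, "timing")
  )
  meta <- meta[!vapply(meta, is.null, logical(1))]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_aif
#' @export
read_aif <- function(path) {
  df <- read.csv(path)
  curve <- new_aif_curve(df$time_s, df$signal_au)
  side <- paste0(path, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::read_json(side, simplifyVector = TRUE)
    for (nm in intersect(names(meta), c("percentile", "threshold", "n_pixels")))
      attr(curve, nm) <- meta[[nm]]
  }
  curve
}
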