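#' Plot an AIF curve
#'
#' @param object an `aif_curve`.
#' @param timing optional `aif_timing` whose points are marked.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.aif_curve <- function(object, timing = NULL, ...) {
  p <- ggplot(as_tibble(object), aes(x = .data$time_s, y = .data$signal_au)) +
    geom_line(colour = "#2c7fb8") +
    geom_point(size = 0.6, colour = "#2c7fb8") +
    labs(x = "time (s)", y = "signal (a.u.)", title = "AIF time-signal curve") +
    theme_minimal()
  if (!is.null(timing)) {
    p <- p + geom_vline(xintercept = c(timing$baseline_time,
                                       timing$start_time,
                                       timing$peak_time),
                        linetype = "dashed", colour = "grey40")
  }
  p
}

#' Plot the ventricle classification
#'
#' Label map of the heart box (background / RV / LV) as produced by
#' [classify_pixels()].
#'
#' @param object a `ventricle_maps` object.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.ventricle_maps <- function(object, ...) {
  df <- expand.grid(row = object$box[1]:object$box[3],
                    col = object$box[2]:object$box[4])
  df$label <- as.vector(object$labels)
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$label)) +
    geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_manual(values = c(background = "grey85",
                                          RV = "#fc8d62", LV = "#66c2a5")) +
    coord_fixed() +
    labs(x = "column", y = "row", title = "RV / LV pixel classification") +
    theme_minimal()
}

#' QC figure for a pipeline run
#'
#' Temporal maximum-intensity projection with the selected AIF pixels
#' overlaid, next to the extracted curve with its timing points.
#'
#' @param res an `aif_pipeline` result.
#' @return A ggplot (patchwork-free single figure: MIP with overlay, the
#'   curve inset is produced by [autoplot.aif_curve()] separately).
#' @export
plot_qc <- function(res) {
  mip <- apply(res$series$data, c(1, 2), max)
  df <- expand.grid(row = seq_len(nrow(mip)), col = seq_len(ncol(mip)))
  df$mip <- as.vector(mip)
  sel <- attr(res$aif, "pixels")
  df$selected <- as.vector(sel)
  ggplot(df, aes(x = .data$col, y = .data$row)) +
    geom_raster(aes(fill = .data$mip)) +
    geom_tile(data = df[df$selected, ], fill = "red", alpha = 0.6) +
    ggplot2::scale_y_reverse() +
    scale_fill_gradient(low = "black", high = "white", name = "MIP") +
    ggplot2::annotate("rect", xmin = res$box[2], xmax = res$box[4],
                      ymin = res$box[1], ymax = res$box[3],
                      fill = NA, colour = "yellow") +
    coord_fixed() +
    labs(x = "column", y = "row",
         title = sprintf("MIP with %d selected AIF pixels (%g%% threshold)",
                         attr(res$aif, "n_pixels"),
                         attr(res$aif, "percentile"))) +
    theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
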