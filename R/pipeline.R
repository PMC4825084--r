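#' Default pipeline configuration
#'
#' Every tunable knob of the automated AIF pipeline with its default.
#' Defaults are the method's standard constants: 1 (AIF series) / 2
#' (myocardial series) standard deviations for the candidate threshold,
#' 0.75 merge correlation, 0.7 ICA assignment correlation, 75th-percentile
#' LV threshold, 0.5 s resampling.
#'
#' @param ... named overrides of any default.
#' @return Named list of configuration values.
#' @export
aifx_config <- function(...) {
  cfg <- list(
    motion_enabled = TRUE, motion_sigma_px = 1, motion_reference = "auto",
    detect_k_sigma = NULL, detect_min_px = NULL, detect_corr_merge = 0.75,
    detect_box_margin = 0.25, detect_edge_frames = 3,
    intensity_enabled = TRUE, intensity_poly_order = 3,
    ica_seed = 42L, ica_max_retries = 5L, ica_corr_threshold = 0.7,
    aif_percentile = 75, aif_mode = "range"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown))
    aifx_error("aifx_parameter_error",
               paste("unknown config keys:", paste(unknown, collapse = ", ")))
  modifyList(cfg, overrides)
}

#' Run the full automated AIF pipeline
#'
#' Executes the stages in their fixed order — motion correction, heart
#' region detection (std-map threshold, enhancement/timing filters,
#' similarity merge, rank vote, bounding box), surface-coil intensity
#' correction and baseline removal, ICA separation and pixel
#' classification, bright-LV-pixel AIF extraction, half-second resampling,
#' timing-point detection and quality metrics.  Stage failures carry a
#' stage-specific condition class (`aifx_empty_candidates`,
#' `aifx_ica_failure`, `aifx_timing_error`) so they are distinguishable.
#'
#' @param series a [perfusion_series()], or a path readable by
#'   [read_series()].
#' @param kind series kind when `series` is a path.
#' @param config configuration list from [aifx_config()].
#' @param out optional output directory; when given, writes `aif.csv` (+
#'   JSON sidecar), `timing.json`, `metrics.json` and a QC figure
#'   `qc.png`.
#' @return An `aif_pipeline` list: `aif` (the extracted `aif_curve`),
#'   `timing`, `metrics`, `maps` (`ventricle_maps`), `box`, `candidates`,
#'   `vote`, `displacements`, and the corrected `series`.
#' @export
run_aif_pipeline <- function(series, kind = c("aif", "myocardial"),
                             config = aifx_config(), out = NULL) {
  kind <- match.arg(kind)
  if (is.character(series)) series <- read_series(series, kind = kind)
  stopifnot(inherits(series, "perfusion_series"))

  disp <- NULL
  reference <- NULL
  if (isTRUE(config$motion_enabled)) {
    reg <- register_series(series, sigma_px = config$motion_sigma_px,
                           reference = config$motion_reference)
    series <- reg$series
    disp <- reg$displacements
    reference <- reg$reference
  }

  cands <- threshold_candidates(series, k_sigma = config$detect_k_sigma,
                                min_px = config$detect_min_px)
  cands <- filter_candidates(cands, n_frames(series),
                             edge_frames = config$detect_edge_frames)
  cands <- merge_similar(cands, series, corr = config$detect_corr_merge)
  vote <- vote_ventricles(cands)
  box <- heart_box(vote$first, vote$second, dim(series)[1:2],
                   margin = config$detect_box_margin)

  if (isTRUE(config$intensity_enabled)) {
    if (is.null(series$pd)) {
      message("intensity correction skipped: no PD frames in series")
    } else {
      series <- coil_correct(series, box = box,
                             poly_order = config$intensity_poly_order)
    }
  }
  series <- remove_baseline(series)

  sources <- ica_sources(series, list(vote$first, vote$second),
                         seed = config$ica_seed,
                         max_retries = config$ica_max_retries)
  maps <- classify_pixels(series, box, sources,
                          corr_threshold = config$ica_corr_threshold)

  aif <- extract_aif(series, lv_mask(maps),
                     percentile = config$aif_percentile,
                     mode = config$aif_mode)
  timing <- timing_points(aif)
  metrics <- curve_metrics(aif, timing)
  attr(aif, "timing") <- unclass(timing)

  res <- structure(list(
    aif = aif, timing = timing, metrics = metrics, maps = maps,
    box = box, candidates = cands, vote = vote,
    displacements = disp, reference = reference, series = series
  ), class = "aif_pipeline")
  if (!is.null(out)) write_pipeline_outputs(res, out)
  res
}

write_pipeline_outputs <- function(res, out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  write_aif(res$aif, file.path(out, "aif.csv"))
  jsonlite::write_json(unclass(res$timing), file.path(out, "timing.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(res$metrics), file.path(out, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  qc <- plot_qc(res)
  ggplot2::ggsave(file.path(out, "qc.png"), qc, width = 7, height = 6,
                  dpi = 120)
  invisible(out)
}

#' @export
print.aif_pipeline <- function(x, ...) {
  cat("<aif_pipeline>\n")
  print(x$timing)
  cat(sprintf("  AIF: %d px selected at the %g%% threshold (%.2f a.u.)\n",
              attr(x$aif, "n_pixels"), attr(x$aif, "percentile"),
              attr(x$aif, "threshold")))
  print(x$metrics)
  invisible(x)
}
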