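#' Normalised gamma-variate bolus curve
#'
#' Standard first-pass bolus model
#' `A * ((t - t0) / (alpha * beta))^alpha * exp(alpha - (t - t0) / beta)`,
#' zero for `t <= t0`.  The normalisation makes the curve peak exactly at
#' `t = t0 + alpha * beta` with value `A`.
#'
#' @param t time in seconds (vectorised).
#' @param t0 bolus arrival time (s).
#' @param A peak amplitude (a.u.).
#' @param alpha dimensionless shape parameter, `> 0`.
#' @param beta scale parameter in seconds, `> 0`.
#' @return Signal in a.u., same length as `t`.
#' @examples
#' gamma_variate(9, t0 = 5, A = 100, alpha = 3, beta = 2)
#' @export
gamma_variate <- function(t, t0, A, alpha, beta) {
  if (alpha <= 0 || beta <= 0)
    aifx_error("aifx_parameter_error", "alpha and beta must be positive")
  tt <- t - t0
  out <- numeric(length(t))
  pos <- tt > 0
  out[pos] <- A * (tt[pos] / (alpha * beta))^alpha * exp(alpha - tt[pos] / beta)
  out
}

disc_mask <- function(nr, nc, center, radius) {
  r <- matrix(seq_len(nr), nr, nc)
  c <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  (r - center[1])^2 + (c - center[2])^2 <= radius^2
}

annulus_mask <- function(nr, nc, center, r_in, r_out) {
  d2 <- (matrix(seq_len(nr), nr, nc) - center[1])^2 +
    (matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2])^2
  d2 > r_in^2 & d2 <= r_out^2
}

#' Six equiangular myocardial sector masks
#'
#' Splits an annular myocardial mask into `n` equiangular sectors around a
#' centre, the standard subdivision for per-sector tissue curves.
#'
#' @param mask logical `H x W` myocardial mask.
#' @param center `(row, col)` of the LV centre.
#' @param n number of sectors.
#' @return List of `n` disjoint logical masks covering `mask`.
#' @export
sector_masks <- function(mask, center, n = 6) {
  nr <- nrow(mask); nc <- ncol(mask)
  ang <- atan2(matrix(seq_len(nc), nr, nc, byrow = TRUE) - center[2],
               matrix(seq_len(nr), nr, nc) - center[1])
  brk <- seq(-pi, pi, length.out = n + 1)
  sec <- findInterval(ang, brk, rightmost.closed = TRUE)
  lapply(seq_len(n), function(k) mask & sec == k)
}

#' Specify a synthetic dynamic perfusion phantom
#'
#' Defines the geometry, bolus dynamics, artefacts and acquisition
#' parameters of a synthetic first-pass perfusion series that emulates the
#' dual-sequence acquisition: an RV-then-LV gamma-variate bolus transit,
#' delayed low-amplitude myocardial enhancement driven by Fermi-model
#' convolution of the true AIF, dark papillary blobs inside the LV cavity,
#' multiplicative polynomial coil shading, static tissue base intensities,
#' rigid per-frame motion, and additive noise.
#'
#' Defaults describe a dedicated AIF series: 48 x 64 grid, 60 frames at a
#' 1 s R-R interval, RV bolus arriving at 5 s and the LV bolus 6 s later
#' (pulmonary transit).  `kind = "myocardial"` scales the geometry x4 to a
#' 192 x 256 grid.
#'
#' @param kind `"aif"` or `"myocardial"` (sets grid size via `scale`).
#' @param n_frames number of frames `T >= 10`.
#' @param rr_interval R-R interval in seconds.
#' @param rv_center,lv_center disc centres `(row, col)` in px at AIF scale.
#' @param rv_radius,lv_radius disc radii in px at AIF scale.
#' @param myo_thickness annular myocardium thickness (px, AIF scale).
#' @param papillary list of `list(center = c(row, col), radius)` blobs,
#'   AIF-scale coordinates relative to the image, strictly inside the LV.
#' @param bolus_rv,bolus_lv `list(A, t0, alpha, beta)` gamma-variate
#'   parameters (a.u., s); `bolus_lv$t0` is derived from `delay` when `NA`.
#' @param delay RV-to-LV bolus delay in seconds.
#' @param flows per-sector myocardial blood flow, ml/g/min, length 6.
#' @param fermi_k,fermi_tau Fermi impulse-response decay rate (1/s) and
#'   shoulder (s) used for the forward tissue model.
#' @param base static tissue intensities `list(background, blood, myo)` in
#'   a.u.; set all to 0 for a pure-bolus phantom.
#' @param papillary_enh fraction of the LV bolus seen by papillary pixels
#'   (they stay dark).
#' @param shading coefficients of the multiplicative polynomial coil
#'   shading surface over normalised coordinates, terms
#'   `1, x, y, x^2, x*y, y^2`; `c(1)` disables shading.
#' @param baseline_offset global additive offset (a.u.).
#' @param motion `T x 2` matrix of per-frame `(row, col)` displacements in
#'   px, or a single amplitude (px) from which a smooth respiratory-like
#'   schedule is built; `0` disables motion.
#' @param noise_sigma additive noise standard deviation (a.u.).
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param pd_scale intensity scale of the two PD frames.
#' @param seed integer RNG seed; generation is reproducible bitwise.
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(kind = c("aif", "myocardial"),
                         n_frames = 60, rr_interval = 1,
                         rv_center = c(22, 21), rv_radius = 7,
                         lv_center = c(27, 37), lv_radius = 7,
                         myo_thickness = 3.5,
                         papillary = list(
                           list(center = c(25, 34.5), radius = 1.3),
                           list(center = c(29.5, 38.5), radius = 1.2)),
                         bolus_rv = list(A = 100, t0 = 5, alpha = 3, beta = 1.5),
                         bolus_lv = list(A = 110, t0 = NA, alpha = 3, beta = 2),
                         delay = 6,
                         flows = rep(1.1, 6),
                         fermi_k = 0.25, fermi_tau = 4,
                         base = list(background = 8, blood = 40, myo = 30),
                         papillary_enh = 0.02,
                         shading = c(1, 0.22, -0.15, -0.10, 0.08, -0.05),
                         baseline_offset = 0,
                         motion = 1.5,
                         noise_sigma = 2,
                         noise_model = c("gaussian", "rician"),
                         pd_scale = 120,
                         seed = 1L) {
  kind <- match.arg(kind)
  noise_model <- match.arg(noise_model)
  scale <- if (kind == "aif") 1 else 4
  shape <- c(48, 64) * scale
  if (n_frames < 10) aifx_error("aifx_parameter_error", "need at least 10 frames")
  if (is.na(bolus_lv$t0)) bolus_lv$t0 <- bolus_rv$t0 + delay
  rv_peak <- bolus_rv$t0 + bolus_rv$alpha * bolus_rv$beta
  lv_peak <- bolus_lv$t0 + bolus_lv$alpha * bolus_lv$beta
  if (rv_peak >= lv_peak)
    aifx_error("aifx_parameter_error", "RV peak must precede LV peak")
  if (rv_radius <= 0 || lv_radius <= 0)
    aifx_error("aifx_parameter_error", "disc radii must be positive")
  geom_r <- (myo_thickness + lv_radius) * scale
  for (ctr in list(rv_center * scale, lv_center * scale)) {
    if (any(ctr < geom_r) || ctr[1] > shape[1] - geom_r + scale ||
        ctr[2] > shape[2] - geom_r + scale)
      aifx_error("aifx_parameter_error", "phantom geometry overflows the grid")
  }
  for (p in papillary) {
    d <- sqrt(sum((p$center - lv_center)^2))
    if (d + p$radius >= lv_radius)
      aifx_error("aifx_parameter_error",
                 "papillary blobs must lie strictly inside the LV disc")
  }
  if (is.matrix(motion)) {
    if (!all(dim(motion) == c(n_frames, 2)))
      aifx_error("aifx_parameter_error", "motion matrix must be T x 2")
  }
  structure(list(
    kind = kind, scale = scale, shape = shape,
    n_frames = n_frames, rr_interval = rr_interval,
    rv_center = rv_center * scale, rv_radius = rv_radius * scale,
    lv_center = lv_center * scale, lv_radius = lv_radius * scale,
    myo_thickness = myo_thickness * scale,
    papillary = lapply(papillary, function(p)
      list(center = p$center * scale, radius = p$radius * scale)),
    bolus_rv = bolus_rv, bolus_lv = bolus_lv,
    flows = flows, fermi_k = fermi_k, fermi_tau = fermi_tau,
    base = base, papillary_enh = papillary_enh,
    shading = shading, baseline_offset = baseline_offset,
    motion = motion, noise_sigma = noise_sigma, noise_model = noise_model,
    pd_scale = pd_scale, seed = as.integer(seed)
  ), class = "phantom_spec")
}

#' Randomised phantom specification
#'
#' Draws a phantom with jittered geometry (disc centres and radii), RV-to-LV
#' delay and noise level, for robustness batteries.
#'
#' @param seed integer seed controlling both the drawn parameters and the
#'   phantom noise.
#' @param kind series kind.
#' @return A [phantom_spec()].
#' @export
random_phantom_spec <- function(seed, kind = "aif") {
  set.seed(seed)
  jit <- function(n, s) round(runif(n, -s, s), 1)
  repeat {
    rv_c <- c(22, 21) + jit(2, 3); rv_r <- 7 + jit(1, 1.5)
    lv_c <- c(27, 37) + jit(2, 3); lv_r <- 7 + jit(1, 1.5)
    # redraw until the ventricles are clearly separated by a septum gap
    if (sqrt(sum((rv_c - lv_c)^2)) > rv_r + lv_r + 2) break
  }
  s <- lv_r / 7
  phantom_spec(
    kind = kind,
    rv_center = rv_c, rv_radius = rv_r,
    lv_center = lv_c, lv_radius = lv_r,
    papillary = list(
      list(center = lv_c + c(-2, -2.5) * s, radius = 1.3 * s),
      list(center = lv_c + c(2.5, 1.5) * s, radius = 1.2 * s)),
    delay = runif(1, 4.5, 8),
    noise_sigma = runif(1, 1, 3.5),
    motion = runif(1, 0.5, 2.5),
    seed = seed + 1L
  )
}

# Smooth respiratory-like translation schedule (zero-mean sinusoids).
motion_schedule <- function(n_frames, amplitude, rr_interval = 1) {
  t <- (seq_len(n_frames) - 1) * rr_interval
  cbind(amplitude * sin(2 * pi * t / 11),
        amplitude * 0.7 * cos(2 * pi * t / 7))
}

# Noiseless shading surface of a spec over its own grid.
shading_field <- function(spec) {
  X <- poly2d_design(rep(seq_len(spec$shape[1]), spec$shape[2]),
                     rep(seq_len(spec$shape[2]), each = spec$shape[1]),
                     spec$shape[1], spec$shape[2], 2)
  cf <- numeric(6); cf[seq_along(spec$shading)] <- spec$shading
  matrix(X %*% cf, spec$shape[1], spec$shape[2])
}

phantom_masks <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  rv <- disc_mask(nr, nc, spec$rv_center, spec$rv_radius)
  lv_full <- disc_mask(nr, nc, spec$lv_center, spec$lv_radius)
  pap <- Reduce(`|`, lapply(spec$papillary, function(p)
    disc_mask(nr, nc, p$center, p$radius)), matrix(FALSE, nr, nc))
  myo <- annulus_mask(nr, nc, spec$lv_center, spec$lv_radius,
                      spec$lv_radius + spec$myo_thickness) & !rv
  list(rv = rv & !lv_full, lv = lv_full & !pap, papillary = pap & lv_full,
       myo = myo & !lv_full)
}

#' Generate a synthetic perfusion series with ground truth
#'
#' Renders the phantom described by a [phantom_spec()]: per-pixel bolus
#' dynamics, coil shading, baseline structure, per-frame rigid motion and
#' noise, plus two PD frames.  The exported truth contains everything the
#' downstream stages can be validated against.
#'
#' @param spec a [phantom_spec()].
#' @return A list with elements
#'   * `series`: a [perfusion_series()] (with PD frames);
#'   * `truth`: list with `aif` (tibble `time_s`, `signal_au`; the noiseless
#'     LV bolus without baseline), `masks` (logical `rv`, `lv`, `papillary`,
#'     `myo`), `sectors` (list of sector masks), `tissue` (tibble of
#'     noiseless per-sector tissue enhancement), `displacements` (`T x 2`),
#'     `flows`, `shading` (matrix), and the `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  set.seed(spec$seed)
  nr <- spec$shape[1]; nc <- spec$shape[2]; nt <- spec$n_frames
  times <- (seq_len(nt) - 1) * spec$rr_interval
  masks <- phantom_masks(spec)
  sectors <- sector_masks(masks$myo, spec$lv_center, 6)

  rv_curve <- gamma_variate(times, spec$bolus_rv$t0, spec$bolus_rv$A,
                            spec$bolus_rv$alpha, spec$bolus_rv$beta)
  lv_curve <- gamma_variate(times, spec$bolus_lv$t0, spec$bolus_lv$A,
                            spec$bolus_lv$alpha, spec$bolus_lv$beta)
  # tissue = AIF (x) Fermi residue, computed on a 4x finer grid so the
  # discrete convolution approximates the continuous model, then sampled
  # at the frame times
  dt_fine <- spec$rr_interval / 4
  t_fine <- seq(times[1], times[nt], by = dt_fine)
  lv_fine <- gamma_variate(t_fine, spec$bolus_lv$t0, spec$bolus_lv$A,
                           spec$bolus_lv$alpha, spec$bolus_lv$beta)
  tissue <- vapply(spec$flows, function(f) {
    fine <- convolve_residue(lv_fine, fermi_residue(t_fine - t_fine[1], f,
                                                    spec$fermi_k, spec$fermi_tau),
                             dt_fine)
    fine[seq(1, by = 4, length.out = nt)]
  }, numeric(nt))

  base_map <- matrix(spec$base$background, nr, nc)
  base_map[masks$rv | masks$lv] <- spec$base$blood
  base_map[masks$myo | masks$papillary] <- spec$base$myo
  base_map <- base_map + spec$baseline_offset

  disp <- if (is.matrix(spec$motion)) spec$motion else
    motion_schedule(nt, spec$motion, spec$rr_interval)
  shade <- shading_field(spec)

  stack <- array(0, c(nr, nc, nt))
  for (t in seq_len(nt)) {
    frame <- base_map
    frame[masks$rv] <- frame[masks$rv] + rv_curve[t]
    frame[masks$lv] <- frame[masks$lv] + lv_curve[t]
    frame[masks$papillary] <- frame[masks$papillary] +
      spec$papillary_enh * lv_curve[t]
    for (s in seq_along(sectors))
      frame[sectors[[s]]] <- frame[sectors[[s]]] + tissue[t, s]
    frame <- frame * shade
    if (any(disp[t, ] != 0))
      frame <- warp_translate(frame, -disp[t, 1], -disp[t, 2])
    stack[, , t] <- frame
  }
  if (spec$noise_sigma > 0) {
    if (spec$noise_model == "gaussian") {
      stack <- stack + array(rnorm(length(stack), 0, spec$noise_sigma), dim(stack))
    } else {
      stack <- sqrt((stack + array(rnorm(length(stack), 0, spec$noise_sigma),
                                   dim(stack)))^2 +
                    array(rnorm(length(stack), 0, spec$noise_sigma), dim(stack))^2)
    }
  }
  pd <- make_pd_frames(spec)
  series <- perfusion_series(stack, times = times, pd = pd, kind = spec$kind)
  truth <- list(
    aif = tibble(time_s = times, signal_au = lv_curve),
    masks = masks, sectors = sectors,
    tissue = tibble(
      time_s = rep(times, 6),
      sector = rep(seq_len(6), each = nt),
      signal_au = as.vector(tissue)),
    displacements = disp, flows = spec$flows,
    shading = shade, spec = spec
  )
  list(series = series, truth = truth)
}

#' Proton-density reference frames of a phantom
#'
#' Two frames proportional to the coil-shading surface with independent
#' noise, emulating the unsaturated PD images acquired at the start of a
#' perfusion acquisition.
#'
#' @param spec a [phantom_spec()].
#' @return List of two `H x W` matrices.
#' @export
make_pd_frames <- function(spec) {
  shade <- shading_field(spec)
  lapply(1:2, function(i) {
    f <- spec$pd_scale * shade
    if (spec$noise_sigma > 0)
      f <- f + matrix(rnorm(length(f), 0, spec$noise_sigma), nrow(f))
    f
  })
}
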