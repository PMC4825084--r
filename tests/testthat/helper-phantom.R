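# Shared fixtures: all phantoms are generated in code at test time.

# A clean phantom: no noise, no motion, no shading, no static tissue —
# the LV mean curve then equals the analytic gamma-variate exactly.
clean_spec <- function(...) {
  args <- modifyList(
    list(noise_sigma = 0, motion = 0, shading = c(1),
         base = list(background = 0, blood = 0, myo = 0),
         flows = rep(0, 6), papillary_enh = 0),
    list(...))
  do.call(phantom_spec, args)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# Truth masks live in the phantom's base geometry; the corrected series
# lives in the geometry of the registration reference frame.  Shift the
# truth by the reference frame's (rounded) true displacement to compare.
align_truth <- function(mask, truth, reference) {
  d <- round(truth$displacements[reference, ])
  aifx:::shift_int(mask, d[1], d[2]) > 0.5
}

# Analytic gamma-variate evaluated independently of the package (plain
# formula transcription, used as the oracle for phantom curves).
gv_oracle <- function(t, t0, A, alpha, beta) {
  tt <- pmax(t - t0, 0)
  ifelse(tt > 0, A * (tt / (alpha * beta))^alpha * exp(alpha - tt / beta), 0)
}

# Build a minimal perfusion series from per-pixel curve assignments:
# `layers` is a list of list(mask=, curve=) added onto a constant base.
series_from_layers <- function(shape, times, layers, base = 0) {
  nt <- length(times)
  stack <- array(base, c(shape, nt))
  for (t in seq_len(nt)) {
    f <- stack[, , t]
    for (l in layers) f[l$mask] <- f[l$mask] + l$curve[t]
    stack[, , t] <- f
  }
  perfusion_series(stack, times = times)
}

# Bare-bones candidate for filter/vote unit tests (only the fields those
# operations read).
fake_candidate <- function(curve, baseline = mean(curve[1:3]),
                           mask = NULL, features = NULL, id = 1L) {
  structure(list(id = id, mask = mask, curve = curve,
                 baseline = baseline, peak_idx = which.max(curve),
                 area = if (is.null(mask)) NA else sum(mask),
                 radius = if (is.null(mask)) NA else sqrt(sum(mask) / pi),
                 features = features),
            class = "region_candidate")
}
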