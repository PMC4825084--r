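test_that("fermi residue is normalised and monotone", {
  t <- seq(0, 30, 0.5)
  for (p in list(c(0.1, 0), c(0.5, 3), c(2, 8))) {
    r <- fermi_residue(t, flow = 2.5, k = p[1], tau = p[2])
    expect_equal(r[1], 2.5)                      # R(0) = F
    expect_true(all(diff(r) <= 1e-12))           # non-increasing
  }
  # delta-like limit: large k with tau = 0 halves R at t = 0+ and kills the tail
  r <- fermi_residue(c(0, 0.5, 5), flow = 1, k = 50, tau = 0)
  expect_equal(r[1], 1)
  expect_lt(r[2], 1e-8)
  # random valid parameters stay monotone on a dense grid
  set.seed(9)
  for (i in 1:20) {
    r <- fermi_residue(seq(0, 20, 0.1), flow = runif(1, 0, 5),
                       k = runif(1, 0.05, 3), tau = runif(1, 0, 8))
    expect_true(all(diff(r) <= 1e-12))
  }
  expect_error(fermi_residue(t, -1, 1, 1), class = "aifx_parameter_error")
  expect_error(fermi_residue(t, 1, 0, 1), class = "aifx_parameter_error")
})

mbf_fixture <- function(flow, k = 0.5, tau = 3, noise = 0, seed = 1,
                        sectors = 1) {
  t <- seq(0, 40, 0.5)
  aifv <- gv_oracle(t, 2, 110, 3, 2)
  tis <- aifx:::convolve_residue(aifv, fermi_residue(t, flow, k, tau), 0.5)
  if (noise > 0) { set.seed(seed); tis <- tis + rnorm(length(tis), 0, noise * max(tis)) }
  list(
    aif = aifx:::new_aif_curve(t, aifv),
    tissue = tibble::tibble(time_s = rep(t, sectors),
                            sector = rep(seq_len(sectors), each = length(t)),
                            signal_au = rep(tis, sectors)),
    timing = structure(list(baseline_time = 0, start_time = 0.5,
                            peak_time = 8, baseline_value = 0),
                       class = "aif_timing"))
}

test_that("noiseless forward-simulated flow is recovered within 2%", {
  fx <- mbf_fixture(flow = 1.0)
  res <- estimate_mbf(fx$aif, fx$tissue, fx$timing)
  expect_lt(abs(res$fits$mbf - 1.0) / 1.0, 0.02)
  fx2 <- mbf_fixture(flow = 3.2)
  res2 <- estimate_mbf(fx2$aif, fx2$tissue, fx2$timing)
  expect_lt(abs(res2$fits$mbf - 3.2) / 3.2, 0.02)
})

test_that("deconvolution is homogeneous: scaling the AIF scales flow inversely", {
  fx <- mbf_fixture(flow = 2, k = 0.4)
  f1 <- estimate_mbf(fx$aif, fx$tissue, fx$timing)$fits$mbf
  aif2 <- aifx:::new_aif_curve(fx$aif$time_s, fx$aif$signal_au * 2)
  f2 <- estimate_mbf(aif2, fx$tissue, fx$timing)$fits$mbf
  expect_equal(f1 / f2, 2, tolerance = 1e-3)
})

test_that("tidy and glance summarise per-sector fits", {
  fx <- mbf_fixture(flow = 1.5, sectors = 6)
  res <- estimate_mbf(fx$aif, fx$tissue, fx$timing)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 6)
  expect_named(td, c("sector", "mbf", "k", "tau", "rss", "converged"))
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mbf_median, median(td$mbf))
  expect_equal(gl$n_sectors, 6)
})

test_that("tissue_curves cuts six equiangular sectors on the AIF grid", {
  ph <- generate_phantom(phantom_spec(motion = 0, noise_sigma = 0))
  tc <- tissue_curves(ph$series, ph$truth$masks$myo, ph$truth$spec$lv_center)
  expect_equal(sort(unique(tc$sector)), 1:6)
  expect_equal(nrow(tc), 6 * 60)
  # sector masks partition the myocardium
  secs <- sector_masks(ph$truth$masks$myo, ph$truth$spec$lv_center)
  expect_equal(Reduce(`+`, lapply(secs, sum)), sum(ph$truth$masks$myo))
})

test_that("threshold sensitivity reproduces the ROI-size directional effect", {
  # homogeneous bright LV: thresholds select equivalent pixels -> equal MBF
  nr <- 20; nc <- 20; t <- 0:39
  lv_core <- matrix(FALSE, nr, nc); lv_core[8:13, 8:13] <- TRUE
  aifv <- gv_oracle(t, 4, 100, 3, 2)
  tis <- aifx:::convolve_residue(aifv, fermi_residue(t, 2, 0.4, 3), 1)
  myo <- matrix(FALSE, nr, nc); myo[16:19, 2:19] <- TRUE
  s <- series_from_layers(c(nr, nc), t, list(
    list(mask = lv_core, curve = aifv),
    list(mask = myo, curve = tis)))
  tp <- structure(list(baseline_time = 0, start_time = 1, peak_time = 10,
                       baseline_value = 0), class = "aif_timing")
  tissue <- tibble::tibble(time_s = rep(t, 1), sector = 1, signal_au = tis)
  set.seed(1)
  tab <- threshold_sensitivity(s, lv_core, tissue, tp, n_boot = 50)
  expect_equal(tab$percentile, c(75, 50, 25))
  expect_lt(diff(range(tab$mbf_median)), 0.02 * mean(tab$mbf_median))

  # partial-volume rim (graded intermediate brightness): the 25% ROI pulls
  # in dimmer boundary pixels, underestimates the AIF peak, inflates flow
  rim <- matrix(FALSE, nr, nc); rim[7:14, 7:14] <- TRUE
  rim <- rim & !lv_core
  rim_hi <- rim & row(rim) <= 10      # 70% of LV brightness
  rim_lo <- rim & row(rim) > 10       # 40% of LV brightness
  s2 <- series_from_layers(c(nr, nc), t, list(
    list(mask = lv_core, curve = aifv),
    list(mask = rim_hi, curve = 0.7 * aifv),
    list(mask = rim_lo, curve = 0.4 * aifv),
    list(mask = myo, curve = tis)))
  set.seed(1)
  tab2 <- threshold_sensitivity(s2, lv_core | rim, tissue, tp, n_boot = 50)
  expect_gte(tab2$mbf_median[tab2$percentile == 25],
             tab2$mbf_median[tab2$percentile == 75])
  expect_gt(tab2$n_pixels[tab2$percentile == 25],
            tab2$n_pixels[tab2$percentile == 75])

  # empty percentile list -> empty table
  empty <- threshold_sensitivity(s, lv_core, tissue, tp,
                                 percentiles = numeric(0))
  expect_equal(nrow(empty), 0)
})
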