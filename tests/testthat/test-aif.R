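test_that("resampling interpolates linearly onto the half-second grid", {
  out <- resample_half_second(c(0, 1, 2), c(0, 2, 4))
  expect_equal(out$time_s, c(0, 0.5, 1, 1.5, 2))
  expect_equal(out$signal_au, c(0, 1, 2, 3, 4))
  # identity on data already on the grid
  t <- seq(0, 5, 0.5); v <- sin(t)
  out2 <- resample_half_second(t, v)
  expect_equal(out2$signal_au, v)
  # monotone input stays monotone
  v3 <- cumsum(runif(20)); t3 <- 0:19
  expect_true(all(diff(resample_half_second(t3, v3)$signal_au) >= 0))
  expect_error(resample_half_second(1, 1), class = "aifx_format_error")
})

test_that("extract_aif thresholds the LV MIP range", {
  # MIP values spanning [10, 50]: q = 75 selects pixels with MIP >= 40
  nr <- 6; nc <- 6; nt <- 12
  stack <- array(0, c(nr, nc, nt))
  mip_vals <- seq(10, 50, length.out = nr * nc)
  for (i in seq_len(nr * nc)) {
    rc <- arrayInd(i, c(nr, nc))
    stack[rc[1], rc[2], ] <- mip_vals[i] * gv_oracle(0:(nt - 1), 2, 1, 2, 1.5)
  }
  s <- perfusion_series(stack)
  lv <- matrix(TRUE, nr, nc)
  curve <- extract_aif(s, lv, percentile = 75)
  expect_equal(attr(curve, "threshold"), 40)
  expect_equal(attr(curve, "n_pixels"), sum(mip_vals >= 40))
  # nested thresholds: lower q selects at least as many pixels
  n75 <- attr(extract_aif(s, lv, 75), "n_pixels")
  n50 <- attr(extract_aif(s, lv, 50), "n_pixels")
  n25 <- attr(extract_aif(s, lv, 25), "n_pixels")
  expect_true(n25 >= n50 && n50 >= n75)
  expect_error(extract_aif(s, matrix(FALSE, nr, nc)),
               class = "aifx_empty_candidates")
})

test_that("dark papillary pixels never enter the 75% AIF ROI", {
  ph <- generate_phantom(phantom_spec(motion = 0, seed = 14))
  s <- remove_baseline(coil_correct(ph$series))
  lv <- ph$truth$masks$lv | ph$truth$masks$papillary
  curve <- extract_aif(s, lv, percentile = 75)
  expect_equal(sum(attr(curve, "pixels") & ph$truth$masks$papillary), 0)
  expect_gt(attr(curve, "n_pixels"), 0)
})

test_that("timing points solve the piecewise-linear geometry exactly", {
  t <- seq(0, 12, 0.5)
  v <- ifelse(t <= 5, 0, pmin((t - 5) * 20, 100))
  v[t > 10] <- 100 - (t[t > 10] - 10) * 30
  tp <- timing_points(aifx:::new_aif_curve(t, v))
  expect_equal(tp$peak_time, 10)
  expect_equal(tp$start_time, 5)
  expect_lte(tp$baseline_time, 5)
  expect_lte(tp$baseline_time, tp$start_time)
})

test_that("gamma-variate timing matches the oversampled geometric oracle", {
  t <- seq(0, 40, 0.5)
  v <- gv_oracle(t, 6, 100, 3, 2)
  tp <- timing_points(aifx:::new_aif_curve(t, v))
  expect_equal(tp$peak_time, 6 + 3 * 2)   # exact on the grid
  # same geometric rule at 1000x oversampling is the start-time oracle
  tf <- seq(0, 40, 0.0005)
  tpf <- timing_points(aifx:::new_aif_curve(tf, gv_oracle(tf, 6, 100, 3, 2)))
  expect_lte(abs(tp$start_time - tpf$start_time), 0.5)
  # translation equivariance
  tp2 <- timing_points(aifx:::new_aif_curve(t + 3, v))
  expect_equal(tp2$peak_time, tp$peak_time + 3)
  expect_equal(tp2$start_time, tp$start_time + 3)
  expect_equal(tp2$baseline_time, tp$baseline_time + 3)
})

test_that("degenerate curves raise timing errors", {
  t <- seq(0, 10, 0.5)
  expect_error(timing_points(aifx:::new_aif_curve(t, rep(1, length(t)))),
               class = "aifx_timing_error")
  expect_error(timing_points(aifx:::new_aif_curve(t, seq_along(t))),
               class = "aifx_timing_error")  # peak at last sample
})

test_that("curve metrics follow their definitions", {
  # direct arithmetic: M = PV / (TTP * FWHM)
  t <- seq(0, 20, 0.5)
  tri <- pmax(0, 2 - abs(t - 10) * (2 / 5))    # triangle: height 2, base 10 s
  tp <- timing_points(aifx:::new_aif_curve(t, tri))
  mt <- curve_metrics(aifx:::new_aif_curve(t, tri), tp)
  expect_equal(mt$pv, 2.0)
  expect_equal(mt$fwhm, 5.0)                   # half-height width of triangle
  expect_equal(mt$m, mt$pv / (mt$ttp * mt$fwhm))
  expect_equal(2.0 / (4.0 * 8.0), 0.0625)      # worked example of the formula
})

test_that("gamma-variate FWHM agrees with root-finding on the analytic curve", {
  t <- seq(0, 40, 0.5)
  crv <- aifx:::new_aif_curve(t, gv_oracle(t, 6, 100, 3, 2))
  tp <- timing_points(crv)
  mt <- curve_metrics(crv, tp)
  f <- function(x) gv_oracle(x, 6, 100, 3, 2) - (100 + tp$baseline_value) / 2
  lo <- uniroot(f, c(6, 12))$root
  hi <- uniroot(f, c(12, 40))$root
  expect_lt(abs(mt$fwhm - (hi - lo)), 0.5)
})

test_that("curve comparison reports r and range-normalised RMSE", {
  t <- seq(0, 30, 0.5)
  a <- aifx:::new_aif_curve(t, gv_oracle(t, 5, 100, 3, 2))
  expect_equal(compare_aifs(a, a)$pearson_r, 1)
  expect_equal(compare_aifs(a, a)$nrmse_pct, 0)
  b <- aifx:::new_aif_curve(t, 2 * a$signal_au + 5)
  cmp <- compare_aifs(a, b)
  expect_equal(cmp$pearson_r, 1)
  expect_gt(cmp$nrmse_pct, 0)
  # additive noise: NRMSE concentrates around sigma / range * 100
  set.seed(42)
  sigma <- 3
  reps <- vapply(1:50, function(i) {
    bn <- aifx:::new_aif_curve(t, a$signal_au + rnorm(length(t), 0, sigma))
    compare_aifs(a, bn)$nrmse_pct
  }, 0)
  expect_equal(mean(reps), sigma / diff(range(a$signal_au)) * 100,
               tolerance = 0.05)
  expect_error(compare_aifs(a[1:2, ], a), class = "aifx_format_error")
})
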