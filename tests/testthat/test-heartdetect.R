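test_that("std_map is the population temporal standard deviation", {
  arr <- array(0, c(2, 2, 10))
  arr[1, 1, ] <- 7                      # constant pixel
  arr[1, 2, ] <- rep(c(0, 2), 5)        # alternating 0/2
  s <- perfusion_series(arr)
  m <- std_map(s)
  expect_equal(m[1, 1], 0)
  expect_equal(m[1, 2], 1)              # population SD of {0,2}
  expect_equal(m[2, 1], 0)
})

test_that("LV pixels dominate the std map on a noiseless phantom", {
  ph <- generate_phantom(clean_spec(base = list(background = 8, blood = 40, myo = 30)))
  m <- std_map(ph$series)
  bg <- !(ph$truth$masks$rv | ph$truth$masks$lv | ph$truth$masks$myo |
            ph$truth$masks$papillary)
  expect_gt(min(m[ph$truth$masks$lv]), max(m[bg]))
})

test_that("candidate threshold sits k standard deviations above the mean", {
  map <- matrix(c(6, 10, 14, 10), 20, 20)  # mean 10, population-ish spread
  expect_equal(aifx:::sd_threshold(map, 1), mean(map) + sd(map))
  expect_equal(aifx:::sd_threshold(map, 2), mean(map) + 2 * sd(map))
  # the worked example: mean 10, sd 4
  set.seed(1)
  x <- rnorm(1000)
  map2 <- matrix(10 + (x - mean(x)) / sd(x) * 4, 40, 25)
  expect_equal(aifx:::sd_threshold(map2, 1), 14)
  expect_equal(aifx:::sd_threshold(map2, 2), 18)
})

test_that("connected components are 8-connected", {
  m <- matrix(FALSE, 5, 5)
  m[1, 1] <- TRUE; m[2, 2] <- TRUE; m[3, 3] <- TRUE  # diagonal chain
  m[5, 5] <- TRUE                                     # separate
  lab <- aifx:::label8(m)
  expect_equal(max(lab), 2)
  expect_equal(lab[1, 1], lab[2, 2])
  expect_equal(lab[2, 2], lab[3, 3])
  expect_false(lab[5, 5] == lab[1, 1])
})

test_that("thresholded candidates overlap the true ventricles", {
  ph <- generate_phantom(phantom_spec(motion = 0, noise_sigma = 1, seed = 6))
  cands <- threshold_candidates(ph$series)
  best_dice <- function(truth)
    max(vapply(cands, function(cn) dice(cn$mask, truth), 0))
  expect_gt(best_dice(ph$truth$masks$rv), 0.5)
  expect_gt(best_dice(ph$truth$masks$lv), 0.5)
  # empty-candidate error on a flat map
  flat <- perfusion_series(array(1, c(8, 8, 12)))
  expect_error(threshold_candidates(flat), class = "aifx_empty_candidates")
})

test_that("enhancement and peak-timing filters remove non-ventricle regions", {
  t <- 0:59
  weak <- fake_candidate(50 + 40 * gv_oracle(t, 20, 1, 3, 2))   # peak 90 < 2x50
  early <- fake_candidate(c(100, 90, rep(10, 58)))              # peaks at frame 1
  late <- fake_candidate(c(rep(10, 58), 90, 100))               # peaks at frame 60
  good <- fake_candidate(10 + gv_oracle(t, 15, 90, 3, 2))       # bolus-like
  kept <- filter_candidates(list(weak, early, late, good), n_frames = 60)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$curve, good$curve)
  expect_error(filter_candidates(list(weak), n_frames = 60),
               class = "aifx_empty_candidates")
})

test_that("similar adjacent regions merge; dissimilar or distant ones do not", {
  nr <- 24; nc <- 24; t <- 0:29
  curve <- gv_oracle(t, 6, 100, 3, 2)
  left <- matrix(FALSE, nr, nc); left[10:14, 8:10] <- TRUE
  right <- matrix(FALSE, nr, nc); right[10:14, 12:14] <- TRUE  # 2 px gap
  far <- matrix(FALSE, nr, nc); far[22:23, 22:23] <- TRUE
  anti <- matrix(FALSE, nr, nc); anti[10:14, 5:6] <- TRUE  # touches `left`
  s <- series_from_layers(c(nr, nc), t, list(
    list(mask = left, curve = curve),
    list(mask = right, curve = curve),
    list(mask = far, curve = curve),
    list(mask = anti, curve = rev(curve))))
  cands <- lapply(list(left, right, far, anti), function(m)
    aifx:::make_candidate(s, m, id = 1))
  merged <- merge_similar(cands, s)
  expect_length(merged, 3)   # left+right union; far and anti stay separate
  areas <- sort(vapply(merged, `[[`, 0, "area"))
  expect_equal(areas, c(4, 10, 30))
})

test_that("rank voting matches exhaustive enumeration on a hand-built table", {
  # three candidates, seven features; oracle enumerates ranks per feature
  feats <- rbind(
    c(area = 40, pv = 100, ttp = 6, fwhm = 8, upslope = 30, m = 2.0, dist_center = 5),
    c(area = 25, pv = 80, ttp = 9, fwhm = 12, upslope = 18, m = 0.8, dist_center = 9),
    c(area = 60, pv = 60, ttp = 7, fwhm = 10, upslope = 22, m = 0.9, dist_center = 3))
  lower <- c("ttp", "fwhm", "dist_center")
  oracle <- sapply(colnames(feats), function(f) {
    v <- feats[, f]
    if (f %in% lower) v <- -v
    vapply(v, function(x) sum(v <= x), 0)   # rank, no ties here
  })
  expect_equal(unname(aifx:::vote_round(feats, lower)),
               unname(rowSums(oracle)))
  # per-feature scores always sum to N(N+1)/2
  n <- nrow(feats)
  scores <- sapply(colnames(feats), function(f)
    aifx:::vote_round(feats[, f, drop = FALSE], lower))
  expect_true(all(colSums(scores) == n * (n + 1) / 2))
})

test_that("a candidate dominating every feature is selected first", {
  nr <- 30; nc <- 30; t <- 0:39
  m1 <- matrix(FALSE, nr, nc); m1[12:18, 12:18] <- TRUE   # big, central
  m2 <- matrix(FALSE, nr, nc); m2[2:4, 2:4] <- TRUE
  m3 <- matrix(FALSE, nr, nc); m3[26:28, 26:28] <- TRUE
  s <- series_from_layers(c(nr, nc), t, list(
    list(mask = m1, curve = gv_oracle(t, 5, 120, 3, 1.5)),  # tall, fast, narrow
    list(mask = m2, curve = gv_oracle(t, 9, 40, 3, 4)),
    list(mask = m3, curve = gv_oracle(t, 11, 30, 3, 5))))
  cands <- lapply(list(m1, m2, m3), function(m) aifx:::make_candidate(s, m, 1))
  v <- vote_ventricles(cands)
  expect_equal(v$first$area, sum(m1))
  # permuting candidate order does not change the selection
  v2 <- vote_ventricles(cands[c(3, 1, 2)])
  expect_equal(v2$first$area, sum(m1))
  expect_equal(sort(c(v2$first$area, v2$second$area)),
               sort(c(v$first$area, v$second$area)))
  expect_error(vote_ventricles(cands[1]), class = "aifx_empty_candidates")
})

test_that("heart box bounds the selections with margin and clipping", {
  nr <- 40; nc <- 40
  a <- matrix(FALSE, nr, nc); a[10:20, 8:15] <- TRUE
  b <- matrix(FALSE, nr, nc); b[12:18, 20:30] <- TRUE
  box0 <- heart_box(list(mask = a), list(mask = b), c(nr, nc), margin = 0)
  expect_equal(unname(unclass(box0)), c(10L, 8L, 20L, 30L))
  # margin expansion clips at the image border
  box <- heart_box(list(mask = a), list(mask = b), c(22, 32), margin = 0.5)
  expect_equal(unname(unclass(box)), c(4L, 1L, 22L, 32L))
  # phantom: the box contains essentially all true ventricle pixels
  ph <- generate_phantom(phantom_spec(motion = 0, seed = 9))
  cands <- filter_candidates(threshold_candidates(ph$series), 60)
  cands <- merge_similar(cands, ph$series)
  v <- vote_ventricles(cands)
  hb <- heart_box(v$first, v$second, dim(ph$series)[1:2])
  inside <- aifx:::box_mask(hb, dim(ph$series)[1:2])
  truth <- ph$truth$masks$rv | ph$truth$masks$lv
  expect_gte(sum(inside & truth) / sum(truth), 0.99)
})
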