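# Frame sampling, binarization, blob extraction, copulation calling,
# space-time volume.

test_that("sample_frames keeps the stated cadence", {
  blank <- matrix(0.5, 8, 8)
  rec <- assay_recording(rep(list(blank), 3601), 0:3600)
  s <- sample_frames(rec, 10)
  expect_equal(length(s$frames), 361L)          # floor(3600/10) + 1
  expect_equal(s$times_s, seq(0, 3600, by = 10))
  # interval equal to native spacing is the identity
  s1 <- sample_frames(rec, 1)
  expect_equal(s1$times_s, rec$times_s)
  # 65 s at 1 fps gives t = 0, 10, ..., 60
  rec65 <- assay_recording(rep(list(blank), 66), 0:65)
  expect_equal(sample_frames(rec65, 10)$times_s, seq(0, 60, by = 10))
  expect_error(sample_frames(rec, 0.5), "finer")
  expect_error(assay_recording(list(), numeric(0)), "empty")
})

test_that("binarization recovers fly pixels from clean and noisy frames", {
  cfg <- quick_config(10, seed = 2, noise_sd = 0)
  sim <- simulate_assay(sim_config(arena = cfg$arena, duration_s = 10,
                                   noise_sd = 0, seed = 2,
                                   keep_truth_masks = TRUE))
  img <- sim$recording$frames[[1]]
  truth <- attr(sim$recording, "truth_masks")[[1]]
  expect_identical(unname(binarize(img)), unname(truth))
  # default noise level: >= 99% of true fly pixels recovered
  noisy <- simulate_assay(sim_config(arena = cfg$arena, duration_s = 10,
                                     seed = 2, keep_truth_masks = TRUE))
  for (k in 1:5) {
    m <- binarize(noisy$recording$frames[[k]])
    tr <- attr(noisy$recording, "truth_masks")[[k]]
    expect_gte(sum(m & tr) / sum(tr), 0.99)
  }
  expect_warning(b <- binarize(matrix(0.5, 10, 10)), "constant")
  expect_false(any(b))
})

test_that("blob extraction counts components with 8-connectivity", {
  m <- matrix(FALSE, 20, 20)
  m[3:8, 3:6] <- TRUE          # blob A, 24 px
  m[12:16, 12:16] <- TRUE      # blob B, 25 px
  b <- extract_blobs(m)
  expect_equal(b$component_count, 2L)
  expect_equal(b$areas, c(25, 24))      # sorted descending
  expect_equal(b$centroids[1, ], c(14, 14))
  # overlapping shapes form one region
  m2 <- matrix(FALSE, 20, 20)
  m2[3:10, 3:10] <- TRUE; m2[8:15, 8:15] <- TRUE
  expect_equal(extract_blobs(m2)$component_count, 1L)
  # a 3-px speck is dropped at min_area 20
  m3 <- m; m3[18, 18:20] <- TRUE
  expect_equal(extract_blobs(m3, min_area_px = 20)$component_count, 2L)
  expect_equal(extract_blobs(m3, min_area_px = 1)$component_count, 3L)
  # corner-touching pixels belong to one component (8-connectivity)
  m4 <- matrix(FALSE, 6, 6); m4[2, 2] <- TRUE; m4[3, 3] <- TRUE
  expect_equal(extract_blobs(m4)$component_count, 1L)
  expect_equal(max(label8(m4)), 1L)
})

test_that("the sustained merged-shape rule defines copulation", {
  # 7 consecutive merged 10-s samples span 70 s: success
  s7 <- fake_series(c(rep(FALSE, 3), rep(TRUE, 7), rep(FALSE, 3)))
  call7 <- call_copulation(s7, min_duration_s = 60,
                           single_fly_area_px = 80)
  expect_true(call7$success)
  expect_equal(nrow(call7$intervals), 1L)
  expect_equal(call7$intervals$end_s - call7$intervals$start_s, 70)
  # 5 merged samples (span 50 s): no call
  s5 <- fake_series(c(rep(FALSE, 3), rep(TRUE, 5), rep(FALSE, 3)))
  expect_false(call_copulation(s5, 60, 80)$success)
  # 6 merged samples span exactly 60 s and the rule is strict
  s6 <- fake_series(c(rep(FALSE, 3), rep(TRUE, 6), rep(FALSE, 3)))
  expect_false(call_copulation(s6, 60, 80)$success)
  expect_error(call_copulation(list()), "empty")
})

test_that("a merged run reaching the final sample is truncated", {
  s <- fake_series(c(rep(FALSE, 5), rep(TRUE, 3)))
  call <- call_copulation(s, 60, 80)
  expect_true(call$success)
  expect_true(call$intervals$truncated)
})

test_that("the single-fly reference area is estimated from split frames", {
  s <- fake_series(c(rep(FALSE, 4), rep(TRUE, 8), rep(FALSE, 2)))
  call <- call_copulation(s, 60)
  expect_equal(call$single_fly_area_px, 80)
  expect_true(call$success)
  all_merged <- fake_series(rep(TRUE, 10))
  expect_error(call_copulation(all_merged, 60), "single-fly")
})

test_that("detected intervals track scripted ground truth", {
  ev <- data.frame(state = "copulation", start_s = 100, end_s = 260)
  sim <- simulate_assay(quick_config(360, ev, seed = 21))
  call <- detect_copulation(sim$recording, interval_s = 10,
                            min_duration_s = 60)
  expect_true(call$success)
  expect_equal(nrow(call$intervals), 1L)
  expect_lte(abs(call$intervals$start_s - 100), 10)
  expect_lte(abs(call$intervals$end_s - 260), 10)
})

test_that("run extension and min-duration act monotonically", {
  base <- c(rep(FALSE, 3), rep(TRUE, 7), rep(FALSE, 4))
  longer <- c(rep(FALSE, 3), rep(TRUE, 9), rep(FALSE, 2))
  n_base <- nrow(call_copulation(fake_series(base), 60, 80)$intervals)
  n_long <- nrow(call_copulation(fake_series(longer), 60, 80)$intervals)
  expect_gte(n_long, n_base)
  for (md in c(30, 60, 90, 120)) {
    n_md <- nrow(call_copulation(fake_series(base), md, 80)$intervals)
    if (md > 30)
      expect_lte(n_md, nrow(call_copulation(fake_series(base), md - 30,
                                            80)$intervals))
  }
  # gap tolerance merges runs split by one dropout sample
  gappy <- c(rep(FALSE, 2), rep(TRUE, 4), FALSE, rep(TRUE, 4),
             rep(FALSE, 3))
  expect_false(call_copulation(fake_series(gappy), 60, 80)$success)
  expect_true(call_copulation(fake_series(gappy), 60, 80,
                              allow_gap_samples = 1)$success)
})

test_that("space-time volumes stack, look up and round-trip", {
  set.seed(5)
  masks <- lapply(1:25, function(i) matrix(runif(64) > 0.6, 8, 8))
  vol <- build_volume(masks, times_s = seq(0, 240, by = 10))
  expect_equal(dim(vol)[3], 25L)
  expect_identical(volume_slice(vol, 100), masks[[11]])
  expect_error(volume_slice(vol, 247), "half a sampling interval")
  path <- withr::local_tempfile(fileext = ".tif")
  write_volume(vol, path)
  back <- read_volume(path)
  expect_identical(unclass(back)[seq_along(back)],
                   unclass(vol)[seq_along(vol)])
  expect_equal(attr(back, "times_s"), attr(vol, "times_s"))
  bad <- c(masks[1:3], list(matrix(FALSE, 4, 4)))
  expect_error(build_volume(bad), "dimensions")
})
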