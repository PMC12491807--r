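test_that("unmixing inverts the mixing matrix and guards singularity", {
  cfg <- quick_cfg(seed = 21, duration = 4, bleed_fraction = 0.2)
  mv <- gen_calcium_movie(cfg, event_rate = 3)
  expect_equal(unmix_channels(mv$movie, diag(2))$data, mv$movie$data,
               tolerance = 1e-12)
  um <- unmix_channels(mv$movie, mv$mixing_matrix)
  expect_equal(um$data, mv$clean, tolerance = 1e-9)
  expect_error(unmix_channels(mv$movie, matrix(c(1, 1, 0, 0), 2)),
               "singular")
})

test_that("ROI traces are per-frame means over the ROI pixels", {
  arr <- array(7, dim = c(3, 4, 4, 1))
  lab <- matrix(0L, 4, 4); lab[1, 1] <- 1L; lab[2, 2] <- 1L
  arr[, 1, 1, 1] <- 3; arr[, 2, 2, 1] <- 5
  mov <- fluorescence_movie(arr, 10)
  rois <- roi_set(lab, data.frame(roi_id = 1L, compartment = "soma",
                                  pericyte_id = "p", pericyte_type = "e",
                                  branch_order = 1L))
  expect_equal(extract_roi_trace(mov, rois, 1L), rep(4, 3))
  expect_error(extract_roi_trace(mov, rois, 2L), "empty")
})

test_that("roi trace peaks at a planted blob's peak frame", {
  cfg <- quick_cfg(seed = 22, duration = 20, noise_sd = 0.5)
  ev <- data.frame(roi_id = 1L, time = 8, amplitude = 1)
  mv <- gen_calcium_movie(cfg, events = ev)
  tr <- extract_roi_trace(mv$movie, mv$rois, 1L)
  expect_equal(which.max(tr), round(8 * cfg$frame_rate) + 1L,
               tolerance = 1)
})

test_that("dF/F uses the 5-s baseline and is scale invariant", {
  x <- c(rep(100, 60), rep(150, 40))
  ca <- compute_dff(x, 12)
  expect_equal(ca$f0, 100)
  expect_equal(ca$dff[70], 0.5)
  expect_true(all(compute_dff(rep(5, 100), 10)$dff == 0))
  expect_equal(compute_dff(3.7 * x, 12)$dff, ca$dff, tolerance = 1e-12)
  expect_error(compute_dff(rep(0, 100), 10), "non-positive")
  expect_error(compute_dff(1:10, 10), "longer")
})

test_that("planted amplitude is recovered by dF/F within kernel discretization", {
  cfg <- quick_cfg(seed = 23, duration = 30)
  g <- gen_calcium_trace(cfg, event_rate = 4, amp_mean = 0.7, amp_cv = 0)
  ca <- compute_dff(g$trace, cfg$frame_rate)
  expect_equal(max(ca$dff), 0.7, tolerance = 0.05)
})

test_that("basal F0 averages the first 2.5 s, per ROI for movies", {
  expect_equal(compute_f0_basal(rep(10, 100), 10), 10)
  ramp <- seq(0, 719) # 60 s at 12 fps
  expect_equal(compute_f0_basal(ramp, 12), mean(ramp[1:30]))
  arr <- array(0, dim = c(60, 4, 4, 1))
  lab <- matrix(0L, 4, 4); lab[1, 1] <- 1L; lab[3, 3] <- 2L
  arr[, 1, 1, 1] <- 4; arr[, 3, 3, 1] <- 9
  mov <- fluorescence_movie(arr, 12)
  rois <- roi_set(lab, data.frame(roi_id = c(1L, 2L),
                                  compartment = c("soma", "process"),
                                  pericyte_id = "p", pericyte_type = "e",
                                  branch_order = 1L))
  expect_equal(unname(compute_f0_basal(mov, rois = rois)), c(4, 9))
})

test_that("peak detection recovers planted transients and rejects flat traces", {
  flat <- calcium_trace(rep(0, 720), 100, 12)
  res <- detect_peaks(flat)
  expect_equal(res$summary$n_events, 0L)
  expect_equal(res$summary$events_per_min, 0)
  cfg <- quick_cfg(seed = 5, duration = 60, noise_sd = 10)  # SNR 8
  g <- gen_calcium_trace(cfg, event_rate = 6, amp_mean = 0.8, amp_cv = 0)
  ca <- compute_dff(g$trace, cfg$frame_rate)
  pk <- detect_peaks(ca)
  n_true <- length(g$truth$event_times)
  expect_lte(abs(pk$summary$n_events - n_true), 1)
  expect_lt(abs(pk$summary$amp_mean - 0.8) / 0.8, 0.15)
  expect_error(detect_peaks(ca, band = c(0.01, 10)), "Nyquist")
})

test_that("3-D event detection finds planted blobs only inside the vessel", {
  cfg <- quick_cfg(seed = 31, duration = 60, noise_sd = 6)
  ev <- data.frame(roi_id = 1L, time = c(10, 25, 40), amplitude = 0.6)
  mv <- gen_calcium_movie(cfg, events = ev)    # amp*f0 = 30 = 5 x SD
  det <- detect_events_3d(mv$movie, mv$rois)
  expect_gte(unname(det$frequency["1"]), 3)    # all three found
  # noise-free, event-free -> nothing anywhere
  cfg0 <- quick_cfg(seed = 32, duration = 10)
  mv0 <- gen_calcium_movie(cfg0, event_rate = 0)
  det0 <- detect_events_3d(mv0$movie, mv0$rois)
  expect_equal(nrow(det0$events), 0L)
  expect_true(all(det0$frequency == 0))
})

test_that("events outside the vessel mask are excluded", {
  cfg <- quick_cfg(seed = 33, duration = 20, noise_sd = 1)
  arr <- array(rnorm(240 * 32 * 32, 50, 1), dim = c(240, 32, 32, 1))
  # blob far from the vessel mask, in background
  arr[120:130, 2:4, 28:30, 1] <- arr[120:130, 2:4, 28:30, 1] + 30
  lab <- matrix(0L, 32, 32); lab[14:18, 14:18] <- 1L
  rois <- roi_set(lab, data.frame(roi_id = 1L, compartment = "soma",
                                  pericyte_id = "p", pericyte_type = "e",
                                  branch_order = 1L),
                  vessel_mask = lab > 0L)
  mov <- fluorescence_movie(arr, 12)
  det <- detect_events_3d(mov, rois)
  expect_equal(nrow(det$events), 0L)
})

test_that("3-D event count is monotone non-increasing in the threshold", {
  # well-separated planted transients: raising the threshold can only
  # shrink or drop a blob, never split one
  cfg <- quick_cfg(seed = 34, duration = 30, noise_sd = 5)
  ev <- data.frame(roi_id = 1L, time = c(5, 12, 19, 26),
                   amplitude = c(0.4, 0.6, 0.8, 1.2))
  mv <- gen_calcium_movie(cfg, events = ev, decay_tau = 0.5)
  counts <- vapply(c(2.5, 3, 4, 6, 25), function(k) {
    d <- detect_events_3d(mv$movie, mv$rois, k = k)
    nrow(d$events)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  expect_equal(counts[5], 0L)                   # k -> infinity: no events
})

test_that("PSD peak finds the dominant band component; Parseval holds", {
  fs <- 12; t <- (0:719) / fs
  x <- sin(2 * pi * 0.05 * t) + 0.5 * sin(2 * pi * 0.3 * t)
  ps <- compute_psd_peak(x, sampling_rate = fs)
  expect_equal(ps$peak_freq, 0.05, tolerance = 1 / 60 + 1e-9)
  # Parseval: sum(psd) * df equals the population variance
  xr <- rnorm(720)
  ps2 <- compute_psd_peak(xr, sampling_rate = fs, band = c(0.01, 0.5))
  df <- fs / 720
  expect_equal(sum(ps2$psd) * df, mean((xr - mean(xr))^2),
               tolerance = 0.01)
  expect_error(compute_psd_peak(x[1:10], sampling_rate = 12),
               "band")
})

test_that("white-noise PSD peaks spread across the searched band", {
  withr::with_seed(77, {
    peaks <- vapply(1:300, function(i) {
      compute_psd_peak(rnorm(720), sampling_rate = 12)$peak_freq
    }, 0)
  })
  # roughly uniform over [0.0167, 0.5]: both halves populated
  mid <- (min(peaks) + 0.5) / 2
  expect_gt(mean(peaks < mid), 0.3)
  expect_lt(mean(peaks < mid), 0.7)
})
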