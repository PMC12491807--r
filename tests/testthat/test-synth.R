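test_that("noise-free event-free calcium trace is exactly constant", {
  cfg <- quick_cfg(seed = 3, duration = 60)
  g <- gen_calcium_trace(cfg, event_rate = 0, f0 = 100)
  expect_true(all(g$trace == 100))
  expect_length(g$truth$event_times, 0)
  expect_error(gen_calcium_trace(cfg, event_rate = 0, f0 = -1),
               "positive")
  expect_error(gen_calcium_trace(cfg, decay_tau = 0), "positive")
})

test_that("oscillation-only trace has its Fourier peak at the programmed bin", {
  cfg <- quick_cfg(seed = 4, duration = 60)
  g <- gen_calcium_trace(cfg, event_rate = 0, oscillation = c(0.1, 0.2))
  ps <- compute_psd_peak(g$trace, sampling_rate = cfg$frame_rate)
  # bin width 1/60 Hz; nearest bin to 0.1 Hz
  bins <- ps$freqs
  expect_equal(ps$peak_freq, bins[which.min(abs(bins - 0.1))])
})

test_that("event counts follow the programmed Poisson process", {
  counts <- vapply(1:300, function(s) {
    cfg <- quick_cfg(seed = s, duration = 60)
    length(gen_calcium_trace(cfg, event_rate = 6)$truth$event_times)
  }, 0)
  expect_lt(abs(mean(counts) - 6), 3 * sqrt(6 / 300))
  # index of dispersion near 1 for a Poisson count
  expect_gt(var(counts) / mean(counts), 0.7)
  expect_lt(var(counts) / mean(counts), 1.4)
})

test_that("generators are bit-reproducible under a fixed seed", {
  cfg <- quick_cfg(seed = 11, duration = 5, noise_sd = 2)
  expect_identical(gen_calcium_trace(cfg)$trace, gen_calcium_trace(cfg)$trace)
  k1 <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 10)
  k2 <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 10)
  expect_identical(k1$kym$data, k2$kym$data)
  expect_identical(k1$truth$entry_times, k2$truth$entry_times)
  m1 <- gen_calcium_movie(cfg, event_rate = 2)
  m2 <- gen_calcium_movie(cfg, event_rate = 2)
  expect_identical(m1$movie$data, m2$movie$data)
  # and no global RNG state is consumed
  set.seed(99); before <- .Random.seed
  invisible(gen_calcium_trace(cfg))
  expect_identical(before, .Random.seed)
})

test_that("movie bleed-through mixes channels linearly and is invertible", {
  cfg <- quick_cfg(seed = 7, duration = 5, bleed_fraction = 0.2)
  mv <- gen_calcium_movie(cfg, event_rate = 3, amp = 1)
  b <- 0.2
  expect_equal(mv$movie$data[, , , 1],
               mv$clean[, , , 1] + b * mv$clean[, , , 2], tolerance = 1e-12)
  um <- unmix_channels(mv$movie, mv$mixing_matrix)
  expect_equal(um$data, mv$clean, tolerance = 1e-9)
})

test_that("noise-free no-event movie is constant inside the mask", {
  cfg <- quick_cfg(seed = 8, duration = 5)
  mv <- gen_calcium_movie(cfg, event_rate = 0)
  tr <- extract_roi_trace(mv$movie, mv$rois, 1L)
  expect_equal(diff(range(tr)), 0)
})

test_that("diameter kymograph renders plateau width and oscillation count", {
  cfg <- quick_cfg(seed = 5, duration = 60)
  cfg$pixel_size <- 1
  dk <- gen_diameter_kymograph(cfg, D0 = 10, vaso_amp = 0, edge_blur = 0,
                               scan_px = 40L)
  # every line has FWHM exactly 10 px at 1 um/px (even scan width puts
  # the plateau edges mid-pixel, where interpolation is exact)
  d <- diameter_from_kymograph(dk$kym, window_lines = 1L)
  expect_true(all(abs(d$values - 10) < 1e-9))
  # 0.1 Hz x 60 s = 6 full oscillations in the programmed truth
  dk2 <- gen_diameter_kymograph(cfg, D0 = 10, vaso_amp = 0.1,
                                vaso_freq = 0.1, scan_px = 41L)
  crossings_up <- sum(diff(dk2$truth$diameter_um > 10) == 1)
  expect_equal(crossings_up, 6)
  expect_error(gen_diameter_kymograph(cfg, D0 = 100, scan_px = 41L),
               "exceeds")
})

test_that("velocity kymograph streak displacement matches v * dt / px", {
  cfg <- quick_cfg(seed = 6, duration = 2)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 5)
  # 2 mm/s, 0.5 um/px, 2 ms/line -> 8 px per line
  expect_true(all(abs(vk$truth$step_px_per_line - 8) < 1e-12))
  segs <- Filter(function(p) !is.null(p) && nrow(p) >= 2,
                 vk$truth$positions)
  steps <- unlist(lapply(segs, function(p) diff(p[, "pos_px"])))
  expect_true(all(abs(steps - 8) < 0.5))   # rendering quantization bound
})

test_that("stalled cells hold their position and zero velocity needs a stall epoch", {
  cfg <- quick_cfg(seed = 9, duration = 4)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 10,
                               stall_epochs = list(c(1, 2)))
  expect_true(all(vk$truth$velocity_mm_s[vk$truth$times >= 1 &
                                           vk$truth$times < 2] == 0))
  in_stall <- function(p) p[p[, "line"] %in% which(vk$truth$times >= 1 &
                                                     vk$truth$times < 2), ,
                            drop = FALSE]
  for (p in vk$truth$positions) {
    if (is.null(p)) next
    q <- in_stall(p)
    if (nrow(q) >= 2) expect_lt(diff(range(q[, "pos_px"])), 1e-9)
  }
  expect_error(gen_velocity_kymograph(cfg, velocity = 0, flux_rate = 5),
               "stall")
  expect_error(gen_velocity_kymograph(cfg, velocity = 60, flux_rate = 5),
               "50")
})

test_that("poisson cell arrivals have the programmed mean rate", {
  n <- vapply(1:200, function(s) {
    cfg <- quick_cfg(seed = s, duration = 10)
    vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 5)
    # count cells entering the scan during the recording
    sum(vk$truth$entry_times >= 0 & vk$truth$entry_times <= 10)
  }, 0)
  expect_lt(abs(mean(n) - 50), 4 * sqrt(50 / 200))
})

test_that("NVC trial programs the stated response magnitudes", {
  cfg <- quick_cfg(seed = 10, duration = 25)
  tr <- gen_nvc_trial(cfg, ca_dip = 0, dilation = 0.1,
                      velocity_gain = 0.2, D0 = 10)
  expect_equal(min(tr$calcium$trace), 100, tolerance = 1e-9)
  expect_equal(max(tr$diameter$values), 11, tolerance = 1e-9)
  expect_equal(max(tr$velocity$values) / 2, 1.2, tolerance = 1e-9)
  expect_error(gen_nvc_trial(cfg, stim = stimulus_epoch(2, 5)),
               "baseline")
})

test_that("grouped observations carry the programmed hierarchy", {
  g <- gen_grouped_observations(n_animals = 4, units_per_animal = 3,
                                treatment_effect = 2, sd_animal = 1,
                                sd_unit = 0.5, sd_resid = 0.2, seed = 2)
  tab <- g$table
  expect_equal(nrow(tab), 4 * 3 * 2)
  expect_true(all(table(tab$unit_id) == 2))       # pre and post per unit
  nest <- tapply(tab$animal_id, tab$unit_id, function(a) length(unique(a)))
  expect_true(all(nest == 1))
  md <- mean(tab$value[tab$treatment == "post"]) -
    mean(tab$value[tab$treatment == "pre"])
  expect_lt(abs(md - 2), 3 * 0.2 / sqrt(12))      # paired: only resid noise
})
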