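test_that("FWHM diameter is exact on plateaus and matches the Gaussian closed form", {
  cfg <- quick_cfg(seed = 41, duration = 2)
  cfg$pixel_size <- 1
  # even scan width: the 10-px plateau edges fall mid-pixel, the exact
  # geometry for which interpolated half-max crossings are error-free
  dk <- gen_diameter_kymograph(cfg, D0 = 10, vaso_amp = 0, edge_blur = 0,
                               scan_px = 40L)
  d <- diameter_from_kymograph(dk$kym)
  expect_true(all(abs(d$values - 10) < 1e-9))
  gk <- gen_diameter_kymograph(cfg, profile = "gaussian",
                               gauss_sigma_px = 3, scan_px = 41L)
  dg <- diameter_from_kymograph(gk$kym)
  fwhm_true <- 2 * sqrt(2 * log(2)) * 3
  expect_lt(max(abs(dg$values - fwhm_true)) / fwhm_true, 0.01)
})

test_that("FWHM is invariant to intensity scale and offset", {
  cfg <- quick_cfg(seed = 42, duration = 2, noise_sd = 1)
  dk <- gen_diameter_kymograph(cfg, D0 = 8, vaso_amp = 0, scan_px = 41L)
  d1 <- diameter_from_kymograph(dk$kym)
  k2 <- kymograph(3.5 * dk$kym$data + 40, dk$kym$line_period,
                  dk$kym$pixel_size, "perpendicular")
  d2 <- diameter_from_kymograph(k2)
  expect_equal(d1$values, d2$values, tolerance = 1e-9)
})

test_that("a vessel filling the scan is flagged invalid, not guessed", {
  prof <- matrix(100, 10, 20)     # all bright: no crossing
  k <- kymograph(prof, 0.002, 1, "perpendicular")
  d <- diameter_from_kymograph(k, window_lines = 5L)
  expect_true(all(is.na(d$values)))
  expect_true(all(d$quality_flags == "invalid"))
})

test_that("sinusoidal diameter is tracked within 2% RMS at SNR 10", {
  cfg <- quick_cfg(seed = 43, duration = 60, noise_sd = 10)  # amp 100/10
  dk <- gen_diameter_kymograph(cfg, D0 = 10, vaso_amp = 0.1,
                               vaso_freq = 0.1, scan_px = 65L)
  d <- diameter_from_kymograph(dk$kym)
  truth <- 10 * (1 + 0.1 * sin(2 * pi * 0.1 * d$times))
  rms <- sqrt(mean((d$values - truth)^2))
  expect_lt(rms, 0.02 * 10)
})

test_that("vasomotion metrics match the sinusoid conventions", {
  tt <- (0:599) * 0.1
  d <- hemo_trace("diameter", tt, 10 + 1 * sin(2 * pi * 0.1 * tt))
  vm <- vasomotion_metrics(d)
  expect_equal(vm$frequency_per_min, 6)
  expect_equal(vm$vasomotor_index, 2 / 10, tolerance = 1e-3)
  expect_equal(vm$peak_freq_hz, 0.1, tolerance = 1e-9)
  # constant diameter: no oscillations
  dc <- hemo_trace("diameter", tt, rep(10, length(tt)))
  vmc <- vasomotion_metrics(dc)
  expect_equal(vmc$frequency_per_min, 0)
  expect_equal(vmc$vasomotor_index, 0)
})

test_that("two-tone vasomotion matches a brute-force cycle count", {
  tt <- (0:599) * 0.1
  x <- 10 + 1 * sin(2 * pi * 0.1 * tt) + 0.2 * sin(2 * pi * 0.3 * tt)
  vm <- vasomotion_metrics(hemo_trace("diameter", tt, x))
  # brute-force oracle for the documented detector (topographic
  # prominence >= 5% of the mean, >= 2 s apart), computed cycle by
  # cycle with plain O(n^2) scans on the noise-free trace
  n <- length(x)
  locmax <- which(diff(sign(diff(x))) == -2) + 1
  prom <- vapply(locmax, function(i) {
    higher_l <- which(x[seq_len(i - 1)] > x[i])
    lbase <- if (length(higher_l)) min(x[(max(higher_l) + 1):i])
             else min(x[1:i])
    higher_r <- which(x[(i + 1):n] > x[i]) + i
    rbase <- if (length(higher_r)) min(x[i:(min(higher_r) - 1)])
             else min(x[i:n])
    x[i] - max(lbase, rbase)
  }, 0)
  cand <- locmax[prom >= 0.05 * mean(x)]
  keep <- integer(0)
  for (i in cand[order(x[cand], decreasing = TRUE)]) {
    if (!length(keep) || all(abs(tt[keep] - tt[i]) >= 2)) keep <- c(keep, i)
  }
  expect_equal(vm$n_cycles, length(keep))
  expect_equal(vm$frequency_per_min, length(keep) / (n * 0.1 / 60))
  # mean cycle excursion against prominence-gated troughs (the same
  # rule applied to the inverted trace), brute force
  y <- -x
  locmin <- which(diff(sign(diff(y))) == -2) + 1
  promt <- vapply(locmin, function(i) {
    higher_l <- which(y[seq_len(i - 1)] > y[i])
    lbase <- if (length(higher_l)) min(y[(max(higher_l) + 1):i])
             else min(y[1:i])
    higher_r <- which(y[(i + 1):n] > y[i]) + i
    rbase <- if (length(higher_r)) min(y[i:(min(higher_r) - 1)])
             else min(y[i:n])
    y[i] - max(lbase, rbase)
  }, 0)
  tcand <- locmin[promt >= 0.05 * mean(x)]
  tkeep <- integer(0)
  for (i in tcand[order(y[tcand], decreasing = TRUE)]) {
    if (!length(tkeep) || all(abs(tt[tkeep] - tt[i]) >= 2))
      tkeep <- c(tkeep, i)
  }
  exc <- vapply(sort(keep), function(i)
    x[i] - x[tkeep[which.min(abs(tkeep - i))]], 0)
  expect_equal(vm$vasomotor_index, mean(exc) / mean(x), tolerance = 1e-9)
})

test_that("radon velocimetry recovers the centroid-slope oracle", {
  cfg <- quick_cfg(seed = 44, duration = 3, noise_sd = 8)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 20,
                               scan_px = 128L)
  v_oracle <- centroid_slope_mm_s(vk)
  vel <- velocity_from_kymograph(vk$kym)
  expect_lt(abs(median(vel$values, na.rm = TRUE) - v_oracle) /
              abs(v_oracle), 0.05)
  expect_lt(abs(v_oracle - 2) / 2, 0.02)    # oracle agrees with truth
})

test_that("velocity is sign-equivariant under position flip and shift-invariant", {
  cfg <- quick_cfg(seed = 45, duration = 3, noise_sd = 4)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 20,
                               scan_px = 128L)
  vel <- velocity_from_kymograph(vk$kym)
  flipped <- kymograph(vk$kym$data[, ncol(vk$kym$data):1],
                       vk$kym$line_period, vk$kym$pixel_size, "parallel")
  vel_f <- velocity_from_kymograph(flipped)
  expect_equal(median(vel_f$values, na.rm = TRUE),
               -median(vel$values, na.rm = TRUE), tolerance = 0.05)
  # dropping whole leading windows only shifts the time origin
  shift <- kymograph(vk$kym$data[-(1:40), ], vk$kym$line_period,
                     vk$kym$pixel_size, "parallel")
  vel_s <- velocity_from_kymograph(shift, overlap_fraction = 0)
  vel_0 <- velocity_from_kymograph(vk$kym, overlap_fraction = 0)
  expect_equal(vel_0$values[-1], vel_s$values, tolerance = 1e-9)
})

test_that("stalls read as near-zero velocity within grid resolution", {
  cfg <- quick_cfg(seed = 46, duration = 4, noise_sd = 4)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 20,
                               scan_px = 128L,
                               stall_epochs = list(c(1.5, 2.5)))
  vel <- velocity_from_kymograph(vk$kym)
  stall <- vel$times >= 1.7 & vel$times <= 2.3
  expect_lt(median(abs(vel$values[stall]), na.rm = TRUE), 0.05)
  moving <- vel$times < 1.3 | vel$times > 2.7
  expect_gt(median(vel$values[moving], na.rm = TRUE), 1.8)
})

test_that("flux counting is exact for sparse streaks and handles edge cases", {
  cfg <- quick_cfg(seed = 47, duration = 10, noise_sd = 5)
  vk <- gen_velocity_kymograph(cfg, velocity = 2, flux_rate = 5,
                               scan_px = 128L)
  fl <- flux_from_kymograph(vk$kym)
  expect_equal(sum(fl$values), truth_crossings(vk, 64))
  # no streaks -> zero flux
  k0 <- gen_velocity_kymograph(quick_cfg(seed = 48, duration = 5,
                                         noise_sd = 0.01),
                               velocity = 2, flux_rate = 0,
                               scan_px = 128L)
  expect_true(all(flux_from_kymograph(k0$kym)$values == 0))
  # zero dynamic range -> flagged invalid
  kc <- kymograph(matrix(50, 100, 20), 0.002, 0.5, "parallel")
  fc <- flux_from_kymograph(kc)
  expect_true(all(fc$quality_flags == "invalid"))
})

test_that("cleaning replaces isolated deviants and runs Rosner ESD", {
  ht <- hemo_trace("velocity", 1:4, c(5, 5, 500, 5))
  ct <- clean_trace(ht, bounds = c(-100, 100), esd = FALSE)
  expect_equal(ct$values, c(5, 5, 5, 5))
  expect_equal(ct$quality_flags[3], "replaced")
  # ESD removes exactly the planted outliers
  withr::with_seed(7, x <- c(rnorm(100, 2, 0.1), 10, 10, 10))
  ht2 <- hemo_trace("velocity", seq_along(x), x)
  ct2 <- clean_trace(ht2, bounds = c(-50, 50))
  expect_equal(which(ct2$quality_flags == "removed"), 101:103)
  expect_equal(attr(ct2, "n_outliers_removed"), 3L)
  # in-bounds trace passes through untouched
  ht3 <- hemo_trace("diameter", 1:50, rep(10, 50) + sin(1:50) * 0.1)
  ct3 <- clean_trace(ht3)
  expect_identical(ct3$values, ht3$values)
  expect_true(all(ct3$quality_flags == "ok"))
  # mostly-garbage traces are rejected
  bad <- hemo_trace("diameter", 1:10, c(rep(500, 6), rep(10, 4)))
  expect_error(clean_trace(bad), "50%")
})

test_that("rosner matches an independent t-distribution critical-value table", {
  withr::with_seed(12, x <- c(rnorm(60, 5, 0.5), 20, -9))
  out <- pericyteflow:::rosner_outliers(x, k_max = 15, alpha = 0.05)
  # independent oracle: sequential max-deviation removal with lambda
  # recomputed from scratch
  oracle <- local({
    y <- x; n <- length(x); removed <- integer(0); R <- lam <- numeric(15)
    pool <- seq_len(n)
    for (i in 1:15) {
      dev <- abs(y[pool] - mean(y[pool]))
      j <- which.max(dev)
      R[i] <- dev[j] / sd(y[pool])
      removed <- c(removed, pool[j]); pool <- pool[-j]
      nn <- n - i
      tq <- qt(1 - 0.05 / (2 * (nn + 1)), nn - 1)
      lam[i] <- nn * tq / sqrt((nn - 1 + tq^2) * (nn + 1))
    }
    hits <- which(R > lam)
    if (length(hits)) removed[seq_len(max(hits))] else integer(0)
  })
  expect_identical(sort(out), sort(oracle))
  expect_identical(sort(out), c(61L, 62L))
})

test_that("resampling preserves ramps and attenuates by the window response", {
  r <- hemo_trace("diameter", seq(0, 10, by = 0.05), seq(0, 10, by = 0.05))
  rs <- resample_smooth(r)
  mid <- rs$times > 1 & rs$times < 9
  expect_lt(max(abs(rs$values[mid] - rs$times[mid])), 1e-9)
  expect_equal(median(diff(rs$times)), 0.1, tolerance = 1e-12)
  # constant stays constant
  cc <- resample_smooth(hemo_trace("flux", seq(0, 5, 0.21), rep(3, 24)))
  expect_true(all(abs(cc$values - 3) < 1e-12))
  # 0.1 Hz tone attenuated by the discrete moving-average response
  tt <- seq(0, 60, by = 0.02)
  s <- hemo_trace("diameter", tt, 10 + sin(2 * pi * 0.1 * tt))
  ss <- resample_smooth(s)
  inner <- ss$times > 5 & ss$times < 55
  amp <- (max(ss$values[inner]) - min(ss$values[inner])) / 2
  H <- (1 / 11) * sin(11 * pi * 0.1 / 10) / sin(pi * 0.1 / 10)
  expect_lt(abs(amp - H) / H, 0.02)
})
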