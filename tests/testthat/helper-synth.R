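# Shared fixture builders. Everything is generated in code; seeds are
# fixed so expectations are deterministic.

quick_cfg <- function(seed = 1L, duration = 10, noise_sd = 0, ...) {
  synth_config(seed = seed, frame_rate = 12, duration = duration,
               image_size = c(32L, 32L), line_period = 0.002,
               pixel_size = 0.5, noise_sd = noise_sd, ...)
}

# least-squares slope through streak centroids: the independent oracle
# for radon velocimetry (uses only the generator's ground truth).
centroid_slope_mm_s <- function(vk) {
  segs <- Filter(function(p) !is.null(p) && nrow(p) >= 3, vk$truth$positions)
  slopes <- vapply(segs, function(p) {
    stats::coef(stats::lm(p[, "pos_px"] ~ p[, "line"]))[2]
  }, 0)
  stats::median(slopes) * vk$kym$pixel_size / (vk$kym$line_period * 1000)
}

# cells whose trajectory crosses a reference column inside the recording
truth_crossings <- function(vk, ref_col) {
  sum(vapply(vk$truth$positions, function(p) {
    !is.null(p) && min(p[, "pos_px"]) <= ref_col &&
      max(p[, "pos_px"]) >= ref_col
  }, TRUE))
}
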