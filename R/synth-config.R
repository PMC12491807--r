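#' Synthetic-acquisition configuration
#'
#' Bundles the acquisition parameters shared by all synthetic
#' generators. Defaults mirror the imaging protocol the pipeline was
#' designed for: 60-s movies at 11--15 frames/s (default 12), 128 x 128
#' px fields of view, and line scans at ~1.8--4 ms per line (default
#' 2 ms).
#'
#' @param seed Integer seed; all randomness in a generator call flows
#'   from it (no global RNG state is consumed or altered).
#' @param frame_rate Movie frame rate, Hz.
#' @param duration Trial duration, seconds.
#' @param image_size `c(ny, nx)` image size in pixels.
#' @param line_period Line-scan period in seconds (plausible range
#'   0.5--10 ms).
#' @param pixel_size Micrometres per pixel.
#' @param noise_sd Additive Gaussian noise SD, intensity units.
#' @param bleed_fraction Cross-channel bleed-through fraction in
#'   `[0, 1)`.
#'
#' @return An object of class `SynthConfig`.
#' @export
synth_config <- function(seed = 1L, frame_rate = 12, duration = 60,
                         image_size = c(128L, 128L), line_period = 0.002,
                         pixel_size = 0.5, noise_sd = 2,
                         bleed_fraction = 0) {
  stopifnot(frame_rate > 0, duration > 0, line_period > 0,
            pixel_size > 0, noise_sd >= 0)
  if (bleed_fraction < 0 || bleed_fraction >= 1)
    stop("`bleed_fraction` must be in [0, 1)", call. = FALSE)
  structure(list(seed = as.integer(seed), frame_rate = frame_rate,
                 duration = duration, image_size = as.integer(image_size),
                 line_period = line_period, pixel_size = pixel_size,
                 noise_sd = noise_sd, bleed_fraction = bleed_fraction),
            class = "SynthConfig")
}

# Run `expr` under the config's seed without touching the caller's RNG.
with_cfg_seed <- function(cfg, expr) {
  withr::with_seed(cfg$seed, expr)
}

# Instant-rise, single-exponential-decay transient kernel evaluated on
# sample times `t` for an event at `t0` with amplitude `a` and decay
# `tau` (s). The simplest kinetics consistent with slow genetically
# encoded calcium indicators.
event_kernel <- function(t, t0, a, tau) {
  out <- numeric(length(t))
  idx <- t >= t0
  out[idx] <- a * exp(-(t[idx] - t0) / tau)
  out
}
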