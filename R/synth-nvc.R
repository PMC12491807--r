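# Smooth stimulus response kernel: raised-cosine onset/offset ramps of
# `ramp_s` seconds around a plateau spanning the stimulus window.
response_ramp <- function(t, onset, duration, ramp_s = 1) {
  r <- numeric(length(t))
  up <- t >= onset & t < onset + ramp_s
  r[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp_s))
  plateau <- t >= onset + ramp_s & t <= onset + duration
  r[plateau] <- 1
  down <- t > onset + duration & t < onset + duration + ramp_s
  r[down] <- 0.5 * (1 + cos(pi * (t[down] - onset - duration) / ramp_s))
  r
}

#' Generate a synthetic neurovascular-coupling trial
#'
#' Emulates a single stimulus trial (by default a 5-s, 4-Hz whisker-pad
#' stimulus after a 5-s pre-stimulus baseline over a 25-s trial): the
#' pericyte calcium trace dips by `ca_dip`, the vessel diameter rises by
#' `dilation`, and blood-cell velocity rises by `velocity_gain`, each
#' following a smooth raised-cosine onset/offset kernel that reaches its
#' full programmed magnitude within the stimulus window.
#'
#' @param cfg A [synth_config()]; `cfg$duration` should cover
#'   `stim$onset + stim$duration` (default trials are 25 s).
#' @param stim A [stimulus_epoch()]; `onset` must be at least
#'   `baseline_s`.
#' @param baseline_s Pre-stimulus baseline window, seconds.
#' @param ca_dip Fractional calcium dip during the stimulus (0.2 = 20%).
#' @param dilation Fractional diameter increase during the stimulus.
#' @param velocity_gain Fractional velocity increase during the
#'   stimulus.
#' @param f0 Baseline calcium fluorescence, intensity units.
#' @param D0 Baseline diameter, micrometres.
#' @param v0 Baseline velocity, mm/s.
#' @param sample_rate Sampling rate of the hemodynamic traces, Hz.
#'
#' @return A list with `calcium` (list `trace`, `times` raw
#'   fluorescence), `diameter` and `velocity` ([hemo_trace()]s), and
#'   `truth` holding the programmed response magnitudes (percent).
#' @export
gen_nvc_trial <- function(cfg, stim = stimulus_epoch(10, 5),
                          baseline_s = 5, ca_dip = 0.2, dilation = 0.1,
                          velocity_gain = 0.2, f0 = 100, D0 = 10,
                          v0 = 2, sample_rate = 10) {
  if (stim$onset < baseline_s)
    stop("stimulus onset must be >= the baseline window", call. = FALSE)
  n_ca <- round(cfg$duration * cfg$frame_rate)
  t_ca <- (seq_len(n_ca) - 1) / cfg$frame_rate
  n_h <- round(cfg$duration * sample_rate)
  t_h <- (seq_len(n_h) - 1) / sample_rate
  with_cfg_seed(cfg, {
    r_ca <- response_ramp(t_ca, stim$onset, stim$duration)
    ca <- f0 * (1 - ca_dip * r_ca) + rnorm(n_ca, 0, cfg$noise_sd)
    r_h <- response_ramp(t_h, stim$onset, stim$duration)
    d_noise <- cfg$noise_sd / 100          # noise scaled to trace units
    dia <- D0 * (1 + dilation * r_h) + rnorm(n_h, 0, d_noise * D0)
    vel <- v0 * (1 + velocity_gain * r_h) + rnorm(n_h, 0, d_noise * v0)
    list(calcium = list(trace = ca, times = t_ca,
                        sampling_rate = cfg$frame_rate),
         diameter = hemo_trace("diameter", t_h, dia),
         velocity = hemo_trace("velocity", t_h, vel),
         stim = stim,
         truth = list(ca_dip_pct = -100 * ca_dip,
                      dilation_pct = 100 * dilation,
                      velocity_gain_pct = 100 * velocity_gain,
                      f0 = f0, D0 = D0, v0 = v0))
  })
}
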