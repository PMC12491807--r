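#' Generate a synthetic perpendicular (diameter) kymograph
#'
#' Each scan line is a bright plateau of width
#' `D(t) = D0 * (1 + vaso_amp * sin(2 pi vaso_freq t))` centred in the
#' scan, on a dark background, with edges softened by a Gaussian edge
#' model whose half-maximum falls exactly at the programmed radius.
#' An optional stimulus-locked dilation transient can be added on top of
#' `D(t)`. With `profile = "gaussian"` each line is instead a Gaussian
#' of SD `gauss_sigma_px`, for closed-form FWHM checks.
#'
#' @param cfg A [synth_config()]; `cfg$duration`, `cfg$line_period`,
#'   `cfg$pixel_size` and `cfg$noise_sd` are used.
#' @param D0 Resting diameter, micrometres (> 0).
#' @param vaso_amp Vasomotion amplitude as a fraction of `D0` in
#'   `[0, 1)`.
#' @param vaso_freq Vasomotion frequency, Hz.
#' @param edge_blur Gaussian edge softness, pixels (0 = hard edge).
#' @param scan_px Number of pixels per scan line.
#' @param amplitude,baseline Plateau and background intensities.
#' @param stim Optional list `list(stim = stimulus_epoch(...),
#'   dilation = fraction)` adding a smooth stimulus-locked dilation.
#' @param profile `"plateau"` (default) or `"gaussian"`.
#' @param gauss_sigma_px Gaussian SD in pixels for
#'   `profile = "gaussian"`.
#'
#' @return A list with `kym` ([kymograph()], perpendicular) and `truth`
#'   (`diameter_um` per line, `times`, and the programmed parameters).
#' @export
gen_diameter_kymograph <- function(cfg, D0 = 10, vaso_amp = 0.1,
                                   vaso_freq = 0.1, edge_blur = 1,
                                   scan_px = 64L, amplitude = 100,
                                   baseline = 10, stim = NULL,
                                   profile = c("plateau", "gaussian"),
                                   gauss_sigma_px = 3) {
  profile <- match.arg(profile)
  stopifnot(D0 > 0, vaso_amp >= 0, vaso_amp < 1)
  n_lines <- round(cfg$duration / cfg$line_period)
  t <- (seq_len(n_lines) - 1) * cfg$line_period
  D <- D0 * (1 + vaso_amp * sin(2 * pi * vaso_freq * t))
  if (!is.null(stim))
    D <- D * (1 + stim$dilation *
                response_ramp(t, stim$stim$onset, stim$stim$duration))
  if (max(D) / cfg$pixel_size >= scan_px)
    stop("vessel width exceeds the scan length", call. = FALSE)
  x <- seq_len(scan_px)
  centre <- (scan_px + 1) / 2
  dist_px <- abs(x - centre)                       # distance from centre, px
  with_cfg_seed(cfg, {
    if (profile == "gaussian") {
      prof <- exp(-(x - centre)^2 / (2 * gauss_sigma_px^2))
      img <- matrix(baseline + amplitude * prof, n_lines, scan_px,
                    byrow = TRUE)
    } else {
      R_px <- D / (2 * cfg$pixel_size)             # per-line radius, px
      if (edge_blur > 0) {
        img <- baseline + amplitude *
          stats::pnorm(outer(R_px, dist_px, "-") / edge_blur)
      } else {
        img <- baseline + amplitude * (outer(R_px, dist_px, ">="))
      }
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd),
                          nrow(img), ncol(img))
    list(kym = kymograph(img, cfg$line_period, cfg$pixel_size,
                         "perpendicular"),
         truth = list(times = t, diameter_um = D, D0 = D0,
                      vaso_amp = vaso_amp, vaso_freq = vaso_freq,
                      profile = profile, gauss_sigma_px = gauss_sigma_px,
                      stim = stim))
  })
}

#' Generate a synthetic parallel (velocity/flux) kymograph
#'
#' Renders dark blood-cell streaks on a bright plasma background. Cells
#' arrive as a Poisson process at `flux_rate`; each cell advances
#' `v * line_period / pixel_size` pixels per scan line, so its streak
#' slope encodes the velocity. During declared stall epochs the velocity
#' is zero and streaks run parallel to the time axis. Streaks are
#' anti-aliased dark bands of width `cell_width` with multiplicative
#' contrast `contrast`; overlapping cells multiply their attenuation
#' (saturating at 0).
#'
#' @param cfg A [synth_config()].
#' @param velocity Blood-cell velocity, mm/s; scalar, or a function of
#'   time returning mm/s. Nonzero values must satisfy
#'   `|v| <= 50` mm/s; zero velocity outside stall epochs is an error
#'   (a degenerate slope must be declared explicitly).
#' @param flux_rate Cell arrival rate, cells/s (>= 0).
#' @param cell_width Cell (streak) width, micrometres.
#' @param stall_epochs `NULL` or a list of `c(start, end)` second pairs
#'   during which the velocity is forced to zero.
#' @param scan_px Pixels per scan line.
#' @param plasma_intensity Background (plasma) intensity.
#' @param contrast Multiplicative streak attenuation in (0, 1]; a fully
#'   covered pixel retains `contrast` of the background per cell.
#'
#' @return A list with `kym` ([kymograph()], parallel) and `truth`
#'   (`entry_times` at which each cell's centre crosses position 0,
#'   per-line cell positions, the velocity profile, stall epochs).
#' @export
gen_velocity_kymograph <- function(cfg, velocity = 2, flux_rate = 5,
                                   cell_width = 6, stall_epochs = NULL,
                                   scan_px = 128L, plasma_intensity = 100,
                                   contrast = 0.6) {
  stopifnot(flux_rate >= 0)
  n_lines <- round(cfg$duration / cfg$line_period)
  t <- (seq_len(n_lines) - 1) * cfg$line_period
  in_stall <- rep(FALSE, n_lines)
  for (ep in stall_epochs) in_stall <- in_stall | (t >= ep[1] & t < ep[2])
  v_t <- if (is.function(velocity)) velocity(t) else rep(velocity, n_lines)
  if (any(abs(v_t) > 50))
    stop("|velocity| must be <= 50 mm/s", call. = FALSE)
  if (any(v_t == 0 & !in_stall))
    stop("zero velocity outside declared stall epochs", call. = FALSE)
  v_t[in_stall] <- 0
  # cumulative displacement in pixels since t = 0
  step_px <- v_t * 1000 * cfg$line_period / cfg$pixel_size  # um per line / um per px
  disp_px <- cumsum(c(0, step_px[-n_lines]))
  w_px <- cell_width / cfg$pixel_size
  half <- w_px / 2

  with_cfg_seed(cfg, {
    # entry times: when a cell's centre crosses position 0 (for forward
    # flow). Extend the window so streaks already mid-scan at t = 0 and
    # those entering late are included.
    span_px <- scan_px
    v_ref <- max(abs(v_t[v_t != 0]), 0.1)
    t_extra <- span_px * cfg$pixel_size / (v_ref * 1000)
    t_lo <- -t_extra
    total_stall <- sum(vapply(stall_epochs, function(e) e[2] - e[1], 0))
    t_hi <- cfg$duration + total_stall
    n_cells <- rpois(1L, flux_rate * (t_hi - t_lo))
    entry <- sort(runif(n_cells, t_lo, t_hi))
    img <- matrix(plasma_intensity, n_lines, scan_px)
    # cumulative displacement (px) at an arbitrary time, extrapolating
    # with the boundary velocity outside the recorded window
    disp_at <- function(e) {
      if (e <= 0) return(e * v_t[1] * 1000 / cfg$pixel_size)
      j <- findInterval(e, t)
      if (j >= n_lines)
        return(disp_px[n_lines] +
                 (e - t[n_lines]) * v_t[n_lines] * 1000 / cfg$pixel_size)
      disp_px[j] + (e - t[j]) * v_t[j] * 1000 / cfg$pixel_size
    }
    # forward flow enters at position 0, reverse flow at the far edge
    entry_pos <- if (sum(step_px) >= 0) 0 else scan_px
    positions <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      # cell centre position at each line: displacement since entry
      pos <- entry_pos + disp_px - disp_at(entry[i])
      vis <- which(pos > -half & pos < scan_px + half)
      if (!length(vis)) { positions[[i]] <- NULL; next }
      positions[[i]] <- cbind(line = vis, pos_px = pos[vis])
      k_lo <- pmax(1L, floor(pos[vis] - half + 0.5))
      k_hi <- pmin(scan_px, ceiling(pos[vis] + half + 0.5))
      for (m in seq_along(vis)) {
        ks <- k_lo[m]:k_hi[m]
        cov <- pmax(0, pmin(ks + 0.5, pos[vis[m]] + half) -
                       pmax(ks - 0.5, pos[vis[m]] - half))
        cov <- pmin(cov, 1)
        img[vis[m], ks] <- img[vis[m], ks] * (1 - (1 - contrast) * cov)
      }
    }
    if (cfg$noise_sd > 0)
      img <- img + matrix(rnorm(length(img), 0, cfg$noise_sd),
                          n_lines, scan_px)
    list(kym = kymograph(img, cfg$line_period, cfg$pixel_size, "parallel"),
         truth = list(entry_times = entry, positions = positions,
                      velocity_mm_s = v_t, times = t,
                      step_px_per_line = step_px,
                      stall_epochs = stall_epochs,
                      cell_width_um = cell_width))
  })
}
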