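#' Generate a synthetic calcium fluorescence trace
#'
#' Simulates a raw fluorescence trace of a pericyte compartment:
#' baseline `f0` modulated by Poisson-arriving calcium transients
#' (instant rise, exponential decay), an optional slow sinusoidal
#' oscillation (emulating vasomotion-coupled calcium in the 0.05--0.1 Hz
#' band), and additive Gaussian noise.
#'
#' The generated trace is `f0 * (1 + sum(transients) + oscillation) +
#' noise`, so event amplitudes are expressed in dF/F units relative to
#' `f0`.
#'
#' @param cfg A [synth_config()].
#' @param event_rate Mean transient rate, events per minute (>= 0).
#' @param amp_mean Mean transient amplitude in dF/F units.
#' @param amp_cv Coefficient of variation of amplitudes (gamma-
#'   distributed); 0 gives identical amplitudes.
#' @param decay_tau Transient decay time constant, seconds (> 0).
#'   Default 1.0 s (GCaMP6s-like); use ~0.5 s for RCaMP-like kinetics.
#' @param oscillation `NULL`, or `c(freq_hz, amplitude)` adding
#'   `amplitude * sin(2 pi freq t)` in dF/F units.
#' @param f0 Baseline fluorescence, intensity units (> 0).
#'
#' @return A list with `trace` (numeric vector), `times` (s), and
#'   `truth`: a ground-truth ledger with `event_times`,
#'   `event_amplitudes`, `f0`, `oscillation`.
#' @export
gen_calcium_trace <- function(cfg, event_rate = 6, amp_mean = 0.5,
                              amp_cv = 0.2, decay_tau = 1,
                              oscillation = NULL, f0 = 100) {
  stopifnot(event_rate >= 0)
  if (f0 <= 0) stop("`f0` must be positive", call. = FALSE)
  if (decay_tau <= 0) stop("`decay_tau` must be positive", call. = FALSE)
  n <- round(cfg$duration * cfg$frame_rate)
  t <- (seq_len(n) - 1) / cfg$frame_rate
  with_cfg_seed(cfg, {
    n_ev <- rpois(1L, event_rate * cfg$duration / 60)
    ev_t <- sort(runif(n_ev, 0, cfg$duration))
    ev_a <- if (n_ev == 0L) numeric(0)
            else if (amp_cv <= 0) rep(amp_mean, n_ev)
            else rgamma(n_ev, shape = 1 / amp_cv^2,
                        scale = amp_mean * amp_cv^2)
    s <- numeric(n)
    for (i in seq_len(n_ev)) s <- s + event_kernel(t, ev_t[i], ev_a[i],
                                                   decay_tau)
    if (!is.null(oscillation))
      s <- s + oscillation[2] * sin(2 * pi * oscillation[1] * t)
    trace <- f0 * (1 + s) + rnorm(n, 0, cfg$noise_sd)
    list(trace = trace, times = t,
         truth = list(event_times = ev_t, event_amplitudes = ev_a,
                      f0 = f0, decay_tau = decay_tau,
                      oscillation = oscillation))
  })
}

# Default ROI layout: a diagonal vessel band crossing the field of view
# with a pericyte soma (disc) and a process (narrow band along the
# vessel axis) sitting on it.
default_roi_layout <- function(ny, nx) {
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  # vessel axis: line through the centre at 30 degrees
  cx <- (nx + 1) / 2; cy <- (ny + 1) / 2
  th <- pi / 6
  d_axis <- -(xx - cx) * sin(th) + (yy - cy) * cos(th)   # distance from axis
  along  <-  (xx - cx) * cos(th) + (yy - cy) * sin(th)   # position along axis
  vw <- max(4, round(min(ny, nx) / 10))                  # vessel half-width
  vessel <- abs(d_axis) <= vw
  soma_c <- -round(min(ny, nx) / 6)
  soma <- vessel & (along - soma_c)^2 + d_axis^2 <= (vw * 0.9)^2
  process <- vessel & !soma & abs(d_axis) <= max(2, vw / 3) &
    along > soma_c & along < round(min(ny, nx) / 3)
  lab <- matrix(0L, ny, nx)
  lab[process] <- 2L
  lab[soma] <- 1L
  roi_set(lab,
          meta = data.frame(roi_id = c(1L, 2L),
                            compartment = c("soma", "process"),
                            pericyte_id = "p1",
                            pericyte_type = "ensheathing",
                            branch_order = 1L),
          vessel_mask = vessel)
}

#' Generate a synthetic two-channel calcium movie
#'
#' Channel 1 carries the calcium indicator: baseline fluorescence on the
#' pericyte (ROI) structure plus transients rendered as spatiotemporal
#' Gaussian blobs confined to the target ROI. Channel 2 carries the
#' plasma label: bright inside the vessel lumen. Cross-channel
#' bleed-through mixes the clean channels with the matrix
#' `M = [[1, b], [b, 1]]` where `b = cfg$bleed_fraction`.
#'
#' @param cfg A [synth_config()].
#' @param rois An [roi_set()]; `NULL` uses a built-in vessel + soma +
#'   process layout. ROIs must lie within the image bounds.
#' @param events `NULL` for Poisson-generated events (rate
#'   `event_rate` per ROI), or a data frame with columns `roi_id`,
#'   `time` (s), `amplitude` (dF/F) planting events explicitly.
#' @param event_rate Events per minute per ROI when `events` is `NULL`.
#' @param amp Mean event amplitude (dF/F).
#' @param decay_tau Event decay constant, seconds.
#' @param sigma_px Spatial Gaussian SD of an event blob, pixels.
#' @param f0_roi Baseline intensity on the pericyte structure.
#' @param f0_bg Background intensity.
#' @param plasma_intensity Plasma-channel intensity inside the vessel.
#'
#' @return A list with `movie` ([fluorescence_movie()], observed i.e.
#'   after bleed and noise), `clean` (4-D array before mixing/noise),
#'   `rois`, `mixing_matrix`, and `truth` (per-event roi/time/amplitude
#'   and per-ROI counts).
#' @export
gen_calcium_movie <- function(cfg, rois = NULL, events = NULL,
                              event_rate = 3, amp = 1, decay_tau = 1,
                              sigma_px = 2, f0_roi = 50, f0_bg = 5,
                              plasma_intensity = 80) {
  ny <- cfg$image_size[1]; nx <- cfg$image_size[2]
  if (is.null(rois)) rois <- default_roi_layout(ny, nx)
  if (!identical(dim(rois$label_image), c(ny, nx)))
    stop("ROI label image does not fit the configured image size",
         call. = FALSE)
  n <- round(cfg$duration * cfg$frame_rate)
  t <- (seq_len(n) - 1) / cfg$frame_rate
  lab <- rois$label_image
  vessel <- if (is.null(rois$vessel_mask)) lab > 0L else rois$vessel_mask

  with_cfg_seed(cfg, {
    if (is.null(events)) {
      events <- do.call(rbind, lapply(rois$meta$roi_id, function(r) {
        k <- rpois(1L, event_rate * cfg$duration / 60)
        if (k == 0L) return(NULL)
        data.frame(roi_id = r, time = sort(runif(k, 0, cfg$duration * 0.9)),
                   amplitude = rep(amp, k))
      }))
      if (is.null(events))
        events <- data.frame(roi_id = integer(0), time = numeric(0),
                             amplitude = numeric(0))
    }
    # clean channel 1: baseline structure + event blobs
    base1 <- matrix(f0_bg, ny, nx)
    base1[lab > 0L] <- f0_roi
    ch1 <- array(rep(base1, n), dim = c(ny, nx, n))
    ev_centers <- vector("list", nrow(events))
    for (i in seq_len(nrow(events))) {
      r <- events$roi_id[i]
      px <- which(lab == r, arr.ind = TRUE)
      c_yx <- px[sample.int(nrow(px), 1L), ]
      ev_centers[[i]] <- c_yx
      yy <- matrix(seq_len(ny), ny, nx)
      xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
      blob <- exp(-((yy - c_yx[1])^2 + (xx - c_yx[2])^2) / (2 * sigma_px^2))
      blob[lab != r] <- 0            # events confined to their compartment
      kt <- event_kernel(t, events$time[i], events$amplitude[i], decay_tau)
      on <- which(kt > 1e-3 * events$amplitude[i])
      for (j in on) ch1[, , j] <- ch1[, , j] + f0_roi * kt[j] * blob
    }
    # clean channel 2: plasma
    base2 <- matrix(f0_bg, ny, nx)
    base2[vessel] <- plasma_intensity
    ch2 <- array(rep(base2, n), dim = c(ny, nx, n))

    b <- cfg$bleed_fraction
    obs1 <- ch1 + b * ch2
    obs2 <- ch2 + b * ch1
    if (cfg$noise_sd > 0) {
      obs1 <- obs1 + array(rnorm(length(obs1), 0, cfg$noise_sd), dim(obs1))
      obs2 <- obs2 + array(rnorm(length(obs2), 0, cfg$noise_sd), dim(obs2))
    }
    # to (t, y, x, ch)
    data <- array(0, dim = c(n, ny, nx, 2L))
    data[, , , 1L] <- aperm(obs1, c(3, 1, 2))
    data[, , , 2L] <- aperm(obs2, c(3, 1, 2))
    clean <- array(0, dim = c(n, ny, nx, 2L))
    clean[, , , 1L] <- aperm(ch1, c(3, 1, 2))
    clean[, , , 2L] <- aperm(ch2, c(3, 1, 2))

    counts <- table(factor(events$roi_id, levels = rois$meta$roi_id))
    list(movie = fluorescence_movie(data, cfg$frame_rate,
                                    c("calcium", "plasma")),
         clean = clean, rois = rois,
         mixing_matrix = matrix(c(1, b, b, 1), 2, 2, byrow = TRUE),
         truth = list(events = events, event_centers = ev_centers,
                      counts_per_roi = as.integer(counts),
                      f0_roi = f0_roi))
  })
}
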