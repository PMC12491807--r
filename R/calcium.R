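#' Spectrally unmix a two-channel movie
#'
#' Removes cross-channel bleed-through by applying the inverse of the
#' linear mixing matrix to every pixel's observed channel vector:
#' `clean = M^-1 %*% observed`, where
#' `observed_i = sum_j M[i, j] clean_j`. Negative unmixed intensities
#' are clipped to zero (photon counts cannot be negative); the number of
#' clipped values is attached as the `"n_clipped"` attribute.
#'
#' @param movie A two-channel [fluorescence_movie()].
#' @param matrix 2 x 2 mixing matrix; must be invertible.
#'
#' @return A [fluorescence_movie()] of the same dimensions.
#' @export
unmix_channels <- function(movie, matrix) {
  d <- dim(movie$data)
  if (d[4] != 2L) stop("unmixing requires a two-channel movie",
                       call. = FALSE)
  if (!is.matrix(matrix) || !all(dim(matrix) == c(2L, 2L)))
    stop("`matrix` must be 2 x 2", call. = FALSE)
  if (abs(det(matrix)) < 1e-12 || rcond(matrix) < 1e-12)
    stop("mixing matrix is singular", call. = FALSE)
  inv <- solve(matrix)
  obs <- base::matrix(movie$data, ncol = 2L)      # (t*y*x, ch)
  clean <- obs %*% t(inv)
  n_clip <- sum(clean < 0)
  clean[clean < 0] <- 0
  out <- array(clean, dim = d)
  res <- fluorescence_movie(out, movie$frame_rate, movie$channel_names)
  attr(res, "n_clipped") <- n_clip
  res
}

#' Extract a mean-intensity ROI trace from a movie
#'
#' @param movie A [fluorescence_movie()].
#' @param rois An [roi_set()] whose label image matches the movie frame
#'   size.
#' @param roi_id Label of the ROI to extract.
#' @param channel Channel index (default 1, the calcium channel).
#'
#' @return Numeric vector: per-frame mean intensity over the ROI's
#'   pixels.
#' @export
extract_roi_trace <- function(movie, rois, roi_id, channel = 1L) {
  d <- dim(movie$data)
  if (!identical(dim(rois$label_image), d[2:3]))
    stop("ROI label image does not match the movie frame size",
         call. = FALSE)
  mask <- rois$label_image == roi_id
  if (!any(mask)) stop("ROI ", roi_id, " is empty", call. = FALSE)
  flat <- base::matrix(movie$data[, , , channel], nrow = d[1])  # (t, y*x)
  rowMeans(flat[, which(mask), drop = FALSE])
}

#' Compute dF/F from a raw fluorescence trace
#'
#' The baseline `F0` is the mean of the first `baseline_window_s`
#' seconds of the trial; `dF/F = (F - F0) / F0`. Multiplying the raw
#' trace by any positive constant leaves the result unchanged.
#'
#' @param trace Numeric raw fluorescence vector.
#' @param sampling_rate Sampling rate, Hz.
#' @param baseline_window_s Baseline window length, seconds (default the
#'   first 5 s of the trial).
#' @param roi_ref Optional ROI identifier carried through.
#'
#' @return A [calcium_trace()].
#' @export
compute_dff <- function(trace, sampling_rate, baseline_window_s = 5,
                        roi_ref = NULL) {
  nb <- round(baseline_window_s * sampling_rate)
  if (length(trace) <= nb)
    stop("trace must be longer than the baseline window", call. = FALSE)
  f0 <- mean(trace[seq_len(nb)])
  if (!is.finite(f0) || f0 <= 0)
    stop("baseline F0 is non-positive; trace flagged unusable",
         call. = FALSE)
  calcium_trace((trace - f0) / f0, f0, sampling_rate, roi_ref)
}

#' Basal fluorescence over the start of a recording
#'
#' Mean fluorescence over the first `window_s` seconds -- used to
#' compare resting indicator fluorescence (hence resting calcium)
#' between conditions. Given a movie plus ROI set, returns one value per
#' ROI.
#'
#' @param x Numeric trace, or a [fluorescence_movie()].
#' @param sampling_rate Sampling rate, Hz (ignored for movies, which
#'   carry their own frame rate).
#' @param window_s Window length, seconds (default 2.5).
#' @param rois [roi_set()], required when `x` is a movie.
#' @param channel Movie channel (default 1).
#'
#' @return A single value for a trace; a named vector (one per ROI) for
#'   a movie.
#' @export
compute_f0_basal <- function(x, sampling_rate = NULL, window_s = 2.5,
                             rois = NULL, channel = 1L) {
  if (inherits(x, "FluorescenceMovie")) {
    if (is.null(rois)) stop("`rois` required for a movie", call. = FALSE)
    nb <- round(window_s * x$frame_rate)
    if (dim(x$data)[1] < nb)
      stop("movie shorter than the basal window", call. = FALSE)
    vals <- vapply(rois$meta$roi_id, function(r)
      mean(extract_roi_trace(x, rois, r, channel)[seq_len(nb)]), 0)
    return(setNames(vals, rois$meta$roi_id))
  }
  nb <- round(window_s * sampling_rate)
  if (length(x) < nb) stop("trace shorter than the basal window",
                           call. = FALSE)
  mean(x[seq_len(nb)])
}

#' Detect calcium transients on a dF/F trace
#'
#' The dF/F trace is band-pass filtered (zero phase), and peaks whose
#' prominence exceeds `prominence_sd` times the SD of the filtered trace
#' over the baseline window are reported as transients. Amplitudes are
#' read from the *unfiltered* dF/F at the peak sample: the filter is for
#' detection only. A minimum peak separation (default 1 s) merges
#' near-coincident peaks, counting the taller one.
#'
#' @param ca A [calcium_trace()].
#' @param band Pass band `c(lo, hi)` in Hz; both edges must lie inside
#'   `(0, fs/2]`.
#' @param prominence_sd Prominence threshold in baseline-SD units. The
#'   default (7) was calibrated on band-limited pure noise: noise-peak
#'   prominences in a 2-Hz band regularly reach 5--6 baseline SDs, so
#'   lower gates admit several false transients per minute, while real
#'   transients at physiological amplitudes sit above 10 SDs.
#' @param min_separation_s Minimum separation between peaks, seconds.
#' @param baseline_window_s Window (from trial start) defining the noise
#'   SD of the filtered trace.
#'
#' @return A list with `events` (data frame `time`, `amplitude`,
#'   `prominence`, `source = "peak"`) and `summary` (`n_events`,
#'   `events_per_min`, `amp_mean`).
#' @export
detect_peaks <- function(ca, band = c(0.01, 2), prominence_sd = 7,
                         min_separation_s = 1, baseline_window_s = 5) {
  fs <- ca$sampling_rate
  if (band[1] <= 0 || band[2] > fs / 2)
    stop("band edges must lie inside (0, Nyquist)", call. = FALSE)
  filt <- bandpass_fft(ca$dff, fs, band[1], band[2])
  nb <- max(2L, round(baseline_window_s * fs))
  base_sd <- sd(filt[seq_len(min(nb, length(filt)))])
  base_sd <- max(base_sd, 1e-6 * max(mean(abs(ca$dff)), 1e-12), 1e-12)
  pk <- find_peaks(filt, min_prominence = prominence_sd * base_sd,
                   min_distance = max(1L, round(min_separation_s * fs)))
  duration_min <- length(ca$dff) / fs / 60
  # amplitude from the unfiltered dF/F apex around the detected peak:
  # the zero-phase filter reshapes/shifts the apex by a fraction of a
  # second, so the raw maximum is read in a half-separation window
  half_w <- max(1L, round(min_separation_s * fs / 2))
  amp <- vapply(pk$index, function(i) {
    w <- max(1L, i - half_w):min(length(ca$dff), i + half_w)
    max(ca$dff[w])
  }, 0)
  events <- data.frame(time = (pk$index - 1) / fs,
                       amplitude = amp,
                       prominence = pk$prominence,
                       source = rep("peak", nrow(pk)))
  list(events = events,
       summary = list(n_events = nrow(events),
                      events_per_min = nrow(events) / duration_min,
                      amp_mean = if (nrow(events)) mean(events$amplitude)
                                 else NA_real_))
}

# 26-connected components over active voxels of a (t, y, x) logical
# array, returned as a membership vector over the active voxel list.
components_3d <- function(coords, dims) {
  n <- nrow(coords)
  if (n == 0L) return(integer(0))
  enc <- function(t, y, x) (t - 1) + dims[1] * ((y - 1) + dims[2] * (x - 1))
  codes <- enc(coords[, 1], coords[, 2], coords[, 3])
  offs <- expand.grid(dt = -1:1, dy = -1:1, dx = -1:1)
  offs <- offs[offs$dt != 0 | offs$dy != 0 | offs$dx != 0, ]
  offs <- offs[with(offs, dt > 0 | (dt == 0 & (dy > 0 | (dy == 0 & dx > 0)))), ]
  edges <- NULL
  for (i in seq_len(nrow(offs))) {
    t2 <- coords[, 1] + offs$dt[i]
    y2 <- coords[, 2] + offs$dy[i]
    x2 <- coords[, 3] + offs$dx[i]
    ok <- t2 >= 1 & t2 <= dims[1] & y2 >= 1 & y2 <= dims[2] &
      x2 >= 1 & x2 <= dims[3]
    m <- match(enc(t2[ok], y2[ok], x2[ok]), codes)
    hit <- !is.na(m)
    if (any(hit))
      edges <- rbind(edges, cbind(which(ok)[hit], m[hit]))
  }
  if (is.null(edges)) return(seq_len(n))     # all isolated
  g <- igraph::make_empty_graph(n, directed = FALSE)
  g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership
}

#' Detect three-dimensional calcium events in a movie
#'
#' Implements the spatiotemporal (x, y, t) event detector: per-pixel
#' baseline mean and SD are estimated from the first `baseline_s`
#' seconds, voxels with `F > mean + k * SD` are marked active, active
#' voxels are grouped into 26-connected components over (x, y, t), and
#' components are retained if they meet the minimum size and duration
#' and intersect the vessel structure. Per-ROI event frequency
#' (signals/minute) counts retained components whose footprint
#' intersects that ROI.
#'
#' A floor of `1e-6 * |baseline mean|` is applied to the per-pixel SD so
#' that noise-free input does not divide by zero.
#'
#' @param movie A single-channel (or unmixed) [fluorescence_movie()];
#'   channel 1 is analysed.
#' @param rois An [roi_set()]; its `vessel_mask` (or, failing that, the
#'   union of ROI labels) defines the vessel structure events must
#'   intersect.
#' @param k SD-multiplier threshold (default 3, the 3 x SD rule).
#' @param min_size Minimum component size, voxels.
#' @param min_duration Minimum component duration, frames.
#' @param baseline_s Baseline period, seconds.
#'
#' @return A list with `events` (data frame: `t_start`, `t_end`,
#'   `n_voxels`, `peak_dff`, `roi_ids` comma-separated, `source =
#'   "event3d"`) and `frequency` (named vector, events/min per ROI).
#' @export
detect_events_3d <- function(movie, rois, k = 3, min_size = 4L,
                             min_duration = 2L, baseline_s = 5) {
  d <- dim(movie$data)
  fs <- movie$frame_rate
  nb <- round(baseline_s * fs)
  if (nb < 2L || d[1] <= nb)
    stop("movie too short for the baseline period", call. = FALSE)
  dat <- movie$data[, , , 1L]                 # (t, y, x)
  flat <- base::matrix(dat, nrow = d[1])      # (t, y*x)
  bmu <- colMeans(flat[seq_len(nb), , drop = FALSE])
  bsd <- apply(flat[seq_len(nb), , drop = FALSE], 2L, sd)
  bsd <- pmax(bsd, 1e-6 * abs(bmu), 1e-12)
  thr <- bmu + k * bsd
  active <- flat > base::matrix(thr, d[1], length(thr), byrow = TRUE)
  idx <- which(active)
  if (!length(idx)) {
    freq <- setNames(rep(0, nrow(rois$meta)), rois$meta$roi_id)
    return(list(events = data.frame(), frequency = freq))
  }
  tt <- ((idx - 1) %% d[1]) + 1
  pix <- ((idx - 1) %/% d[1]) + 1
  yy <- ((pix - 1) %% d[2]) + 1
  xx <- ((pix - 1) %/% d[2]) + 1
  coords <- cbind(tt, yy, xx)
  memb <- components_3d(coords, c(d[1], d[2], d[3]))
  vessel <- if (!is.null(rois$vessel_mask)) rois$vessel_mask
            else rois$label_image > 0L
  lab <- rois$label_image
  duration_min <- d[1] / fs / 60
  ev <- lapply(split(seq_along(memb), memb), function(ii) {
    sz <- length(ii)
    tr <- range(coords[ii, 1])
    if (sz < min_size || (tr[2] - tr[1] + 1L) < min_duration) return(NULL)
    pidx <- cbind(coords[ii, 2], coords[ii, 3])
    if (!any(vessel[pidx])) return(NULL)       # outside vessel structure
    rids <- unique(lab[pidx]); rids <- rids[rids > 0L]
    vals <- dat[cbind(coords[ii, 1], coords[ii, 2], coords[ii, 3])]
    mus <- bmu[(coords[ii, 3] - 1) * d[2] + coords[ii, 2]]
    data.frame(t_start = (tr[1] - 1) / fs, t_end = (tr[2] - 1) / fs,
               n_voxels = sz,
               peak_dff = max((vals - mus) / pmax(mus, 1e-12)),
               roi_ids = paste(sort(rids), collapse = ","),
               source = "event3d")
  })
  ev <- do.call(rbind, ev[!vapply(ev, is.null, TRUE)])
  if (is.null(ev)) ev <- data.frame()
  freq <- vapply(rois$meta$roi_id, function(r) {
    if (!nrow(ev)) return(0)
    hit <- vapply(strsplit(ev$roi_ids, ","), function(s) any(s == r), TRUE)
    sum(hit) / duration_min
  }, 0)
  list(events = ev, frequency = setNames(freq, rois$meta$roi_id))
}

#' Power spectral density and peak frequency of a calcium trace
#'
#' Computes the periodogram of the mean-removed trace (full-length, no
#' segment averaging, so the lowest resolvable bins remain available),
#' the single-sided amplitude spectrum, and the frequency of maximum
#' power within the search band (default 0.01--0.5 Hz, the vasomotion
#' band). The one-sided PSD is normalized so that
#' `sum(psd) * df` equals the (population) variance of the mean-removed
#' series.
#'
#' @param x A [calcium_trace()], [hemo_trace()] (must be uniformly
#'   sampled), or numeric vector.
#' @param sampling_rate Required when `x` is a bare numeric vector.
#' @param band Search band `c(lo, hi)` in Hz. An error is raised when no
#'   frequency bin of the series falls inside the band.
#'
#' @return A list of class `SpectralSummary`: `freqs`, `psd`,
#'   `amplitude`, `peak_freq` (Hz, argmax of the PSD within the band).
#' @export
compute_psd_peak <- function(x, sampling_rate = NULL,
                             band = c(0.01, 0.5)) {
  if (inherits(x, "CalciumTrace")) {
    v <- x$dff; fs <- x$sampling_rate
  } else if (inherits(x, "HemoTrace")) {
    ok <- is.finite(x$values)
    v <- x$values[ok]
    dt <- diff(x$times[ok])
    if (max(dt) - min(dt) > 1e-6 * mean(dt))
      stop("HemoTrace must be uniformly sampled; resample first",
           call. = FALSE)
    fs <- 1 / mean(dt)
  } else {
    if (is.null(sampling_rate))
      stop("`sampling_rate` required for a numeric vector", call. = FALSE)
    v <- as.numeric(x); fs <- sampling_rate
  }
  n <- length(v)
  X <- fft(v - mean(v))
  half <- floor(n / 2)
  kk <- seq_len(half)                       # bins 1..n/2 (excludes DC)
  freqs <- kk * fs / n
  amp <- 2 * Mod(X[kk + 1]) / n
  psd <- 2 * Mod(X[kk + 1])^2 / (fs * n)
  if (n %% 2 == 0) {                        # Nyquist bin is not doubled
    amp[half] <- amp[half] / 2
    psd[half] <- psd[half] / 2
  }
  inband <- freqs >= band[1] - 1e-12 & freqs <= band[2] + 1e-12
  if (!any(inband))
    stop("no frequency bin falls inside the requested band; ",
         "the trace is too short to resolve it", call. = FALSE)
  pk <- which(inband)[which.max(psd[inband])]
  structure(list(freqs = freqs, psd = psd, amplitude = amp,
                 peak_freq = freqs[pk], band = band),
            class = "SpectralSummary")
}

#' @export
print.SpectralSummary <- function(x, ...) {
  cat(sprintf("<SpectralSummary> %d bins, peak %.4g Hz in [%.3g, %.3g] Hz\n",
              length(x$freqs), x$peak_freq, x$band[1], x$band[2]))
  invisible(x)
}
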