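#' Fluorescence movie container
#'
#' A time-resolved fluorescence image stack with acquisition metadata.
#' Data are stored time-major: `data[t, y, x, channel]`.
#'
#' @param data Numeric array, `(time, y, x)` or `(time, y, x, channel)`.
#'   A 3-D array is promoted to a single-channel 4-D array.
#' @param frame_rate Acquisition rate in Hz; must lie in (0, 1000].
#' @param channel_names Optional character vector naming the channels.
#'
#' @return An object of class `FluorescenceMovie`: a list with elements
#'   `data`, `frame_rate`, `channel_names`.
#' @export
fluorescence_movie <- function(data, frame_rate, channel_names = NULL) {
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  if (length(dim(data)) != 4L)
    stop("`data` must be a (time, y, x[, channel]) array", call. = FALSE)
  if (!is.numeric(frame_rate) || length(frame_rate) != 1L ||
      !is.finite(frame_rate) || frame_rate <= 0 || frame_rate > 1000)
    stop("`frame_rate` must be a single value in (0, 1000] Hz", call. = FALSE)
  n_ch <- dim(data)[4L]
  if (is.null(channel_names)) channel_names <- paste0("ch", seq_len(n_ch))
  if (length(channel_names) != n_ch)
    stop("`channel_names` length must match the number of channels",
         call. = FALSE)
  structure(list(data = data, frame_rate = frame_rate,
                 channel_names = channel_names),
            class = "FluorescenceMovie")
}

#' @export
print.FluorescenceMovie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<FluorescenceMovie> %d frames, %d x %d px, %d channel(s) @ %.3g Hz\n",
    d[1], d[2], d[3], d[4], x$frame_rate))
  invisible(x)
}

#' Line-scan kymograph container
#'
#' A 2-D image built from a repeated 1-D laser line scan. Rows are scan
#' lines (time), columns are positions along the scanned line.
#' Perpendicular scans encode vessel width; parallel scans encode moving
#' blood-cell streaks whose slope encodes velocity.
#'
#' @param data Numeric matrix `(line, position)`, at least 2 lines.
#' @param line_period Time per scan line in seconds. Plausibility band
#'   0.5--10 ms.
#' @param pixel_size Micrometres per pixel along the scan line.
#' @param orientation `"perpendicular"` (across the vessel, for
#'   diameter) or `"parallel"` (along the vessel, for velocity/flux).
#'
#' @return An object of class `Kymograph`.
#' @export
kymograph <- function(data, line_period, pixel_size,
                      orientation = c("perpendicular", "parallel")) {
  orientation <- match.arg(orientation)
  if (!is.matrix(data) || nrow(data) < 2L)
    stop("`data` must be a (line, position) matrix with >= 2 lines",
         call. = FALSE)
  if (!is.numeric(line_period) || length(line_period) != 1L ||
      line_period < 5e-4 || line_period > 1e-2)
    stop("`line_period` must be a single value in [0.5, 10] ms ",
         "(given in seconds)", call. = FALSE)
  if (!is.numeric(pixel_size) || pixel_size <= 0)
    stop("`pixel_size` must be positive (um/px)", call. = FALSE)
  structure(list(data = data, line_period = line_period,
                 pixel_size = pixel_size, orientation = orientation),
            class = "Kymograph")
}

#' @export
print.Kymograph <- function(x, ...) {
  cat(sprintf(
    "<Kymograph %s> %d lines x %d px, %.3g ms/line, %.3g um/px (%.3g s)\n",
    x$orientation, nrow(x$data), ncol(x$data), 1000 * x$line_period,
    x$pixel_size, nrow(x$data) * x$line_period))
  invisible(x)
}

#' Calcium dF/F trace container
#'
#' @param dff Numeric vector of dF/F values over time.
#' @param f0 Baseline fluorescence (intensity units); must be > 0.
#' @param sampling_rate Sampling rate in Hz.
#' @param roi_ref Optional identifier of the source ROI.
#'
#' @return An object of class `CalciumTrace`.
#' @export
calcium_trace <- function(dff, f0, sampling_rate, roi_ref = NULL) {
  if (!is.numeric(f0) || length(f0) != 1L || !is.finite(f0) || f0 <= 0)
    stop("`f0` must be a single positive value", call. = FALSE)
  if (sampling_rate <= 0) stop("`sampling_rate` must be positive",
                               call. = FALSE)
  structure(list(dff = as.numeric(dff), f0 = f0,
                 sampling_rate = sampling_rate, roi_ref = roi_ref),
            class = "CalciumTrace")
}

#' @export
print.CalciumTrace <- function(x, ...) {
  cat(sprintf("<CalciumTrace> %d samples @ %.3g Hz, F0 = %.4g\n",
              length(x$dff), x$sampling_rate, x$f0))
  invisible(x)
}

#' Hemodynamic time-series container
#'
#' Holds one of the three single-vessel hemodynamic measurements derived
#' from line scans, with per-sample quality flags.
#'
#' @param kind One of `"diameter"` (um), `"velocity"` (mm/s) or
#'   `"flux"` (cells/s).
#' @param times Numeric vector of sample times in seconds, strictly
#'   increasing.
#' @param values Numeric vector, same length as `times`. Invalid samples
#'   may be `NA`.
#' @param quality_flags Character vector of per-sample flags (`"ok"`,
#'   `"invalid"`, `"replaced"`, `"removed"`, `"unresolved"`).
#'
#' @return An object of class `HemoTrace`.
#' @export
hemo_trace <- function(kind = c("diameter", "velocity", "flux"),
                       times, values, quality_flags = NULL) {
  kind <- match.arg(kind)
  times <- as.numeric(times); values <- as.numeric(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same length", call. = FALSE)
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("`times` must be strictly increasing", call. = FALSE)
  if (is.null(quality_flags)) quality_flags <- rep("ok", length(values))
  quality_flags[!is.finite(values) & quality_flags == "ok"] <- "invalid"
  structure(list(kind = kind, times = times, values = values,
                 quality_flags = quality_flags),
            class = "HemoTrace")
}

#' @export
print.HemoTrace <- function(x, ...) {
  unit <- c(diameter = "um", velocity = "mm/s", flux = "cells/s")[x$kind]
  ok <- x$quality_flags == "ok"
  cat(sprintf("<HemoTrace %s> %d samples (%d ok), mean %.4g %s\n",
              x$kind, length(x$values), sum(ok),
              mean(x$values[ok], na.rm = TRUE), unit))
  invisible(x)
}

#' ROI set container
#'
#' A labeled image of regions of interest (manually selected pericyte
#' subcellular compartments in the original workflow) plus per-ROI
#' metadata and an optional vessel mask used to confirm that detected
#' events occur within the vessel structure.
#'
#' @param label_image Integer matrix `(y, x)`; 0 = background, positive
#'   labels identify ROIs. Labels must be disjoint by construction and
#'   every listed ROI non-empty.
#' @param meta Data frame with one row per ROI: columns `roi_id`
#'   (matching labels), `compartment` (`"soma"`/`"process"`),
#'   `pericyte_id`, `pericyte_type` (`"ensheathing"`/`"thin-strand"`),
#'   `branch_order`.
#' @param vessel_mask Optional logical matrix `(y, x)` marking the
#'   vessel structure.
#'
#' @return An object of class `ROISet`.
#' @export
roi_set <- function(label_image, meta, vessel_mask = NULL) {
  storage.mode(label_image) <- "integer"
  labs <- sort(unique(label_image[label_image > 0L]))
  if (!all(meta$roi_id %in% labs))
    stop("every `meta$roi_id` must be a non-empty label in `label_image`",
         call. = FALSE)
  if (!is.null(vessel_mask) && !identical(dim(vessel_mask), dim(label_image)))
    stop("`vessel_mask` must match the label image dimensions", call. = FALSE)
  structure(list(label_image = label_image, meta = meta,
                 vessel_mask = vessel_mask),
            class = "ROISet")
}

#' @export
print.ROISet <- function(x, ...) {
  cat(sprintf("<ROISet> %d ROI(s): %s\n", nrow(x$meta),
              paste0(x$meta$roi_id, ":", x$meta$compartment,
                     collapse = ", ")))
  invisible(x)
}

#' Stimulus epoch descriptor
#'
#' Describes one stimulation period, e.g. the 500 uA, 4 Hz, 5 s
#' electrical whisker-pad stimulus used to evoke neurovascular coupling.
#'
#' @param onset Stimulus onset in seconds from trial start.
#' @param duration Stimulus duration in seconds (> 0).
#' @param description Free-text description of the stimulus.
#'
#' @return An object of class `StimulusEpoch`.
#' @export
stimulus_epoch <- function(onset, duration,
                           description = "500 uA at 4 Hz") {
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (onset < 0) stop("`onset` must be >= 0", call. = FALSE)
  structure(list(onset = onset, duration = duration,
                 description = description),
            class = "StimulusEpoch")
}
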