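#' Percentage-change trace relative to a pre-stimulus baseline
#'
#' Re-references a series to the mean of the `baseline_s` window
#' immediately before stimulus onset and expresses it as percent change:
#' `pct = 100 * (x - baseline) / baseline`. For calcium this is applied
#' to the dF/F-carrying raw series so that trial-start F0 and the
#' pre-stimulus baseline may differ. Invariant to multiplying the raw
#' series by any positive constant.
#'
#' @param values Numeric series (or a [hemo_trace()] /
#'   [calcium_trace()]).
#' @param times Sample times in seconds (ignored when `values` carries
#'   its own).
#' @param stim A [stimulus_epoch()]; the series must cover
#'   `[onset - baseline_s, onset + duration]`.
#' @param baseline_s Baseline window, seconds (default 5, matching the
#'   5-s pre-stimulus period).
#'
#' @return A list of class `NVCTrace`: `times`, `pct` (percent),
#'   `baseline_value`, `stim`.
#' @export
pct_change_trace <- function(values, times = NULL, stim,
                             baseline_s = 5) {
  if (inherits(values, "HemoTrace")) {
    times <- values$times; values <- values$values
  } else if (inherits(values, "CalciumTrace")) {
    times <- (seq_along(values$dff) - 1) / values$sampling_rate
    values <- values$dff
  }
  if (is.null(times)) stop("`times` required", call. = FALSE)
  t0 <- stim$onset - baseline_s
  if (t0 < min(times) - 1e-9 ||
      stim$onset + stim$duration > max(times) + 1e-9)
    stop("series does not cover the baseline + stimulus window",
         call. = FALSE)
  in_base <- times >= t0 & times < stim$onset
  baseline <- mean(values[in_base], na.rm = TRUE)
  if (!is.finite(baseline) || baseline <= 0)
    stop("pre-stimulus baseline is non-positive", call. = FALSE)
  structure(list(times = times,
                 pct = 100 * (values - baseline) / baseline,
                 baseline_value = baseline, stim = stim,
                 baseline_window_s = baseline_s),
            class = "NVCTrace")
}

#' Stimulus-window extremum of a percentage-change trace
#'
#' The response magnitude used for neurovascular coupling: the minimum
#' (calcium dip) or maximum (diameter / velocity / flux rise) of the
#' percent-change trace strictly within the stimulus window
#' `[onset, onset + duration]`.
#'
#' @param pct_trace An `NVCTrace` from [pct_change_trace()].
#' @param mode `"min"` for calcium, `"max"` for hemodynamic series; the
#'   caller's choice is recorded in the result.
#'
#' @return A list: `value` (percent), `time` (s, location of the
#'   extremum), `mode`.
#' @export
response_extrema <- function(pct_trace, mode = c("min", "max")) {
  mode <- match.arg(mode)
  stim <- pct_trace$stim
  idx <- which(pct_trace$times >= stim$onset - 1e-9 &
                 pct_trace$times <= stim$onset + stim$duration + 1e-9)
  idx <- idx[is.finite(pct_trace$pct[idx])]
  if (!length(idx)) stop("no samples within the stimulus window",
                         call. = FALSE)
  j <- if (mode == "min") idx[which.min(pct_trace$pct[idx])]
       else idx[which.max(pct_trace$pct[idx])]
  list(value = pct_trace$pct[j], time = pct_trace$times[j], mode = mode)
}

#' Average percentage-change traces across trials
#'
#' Arithmetic mean across repeated stimulation trials (traces must
#' share one time grid; resample first if needed), with the standard
#' error of the mean per time point, matching the mean + SEM convention
#' of stimulus-locked response figures.
#'
#' @param traces List of `NVCTrace` objects on a common time grid.
#'
#' @return A list: `times`, `mean_pct`, `sem_pct`, `n_trials`.
#' @export
average_trials <- function(traces) {
  if (!length(traces)) stop("no traces supplied", call. = FALSE)
  tmat <- vapply(traces, function(x) x$pct, traces[[1]]$pct)
  if (is.null(dim(tmat))) tmat <- base::matrix(tmat, ncol = length(traces))
  list(times = traces[[1]]$times,
       mean_pct = rowMeans(tmat),
       sem_pct = apply(tmat, 1L, sd) / sqrt(length(traces)),
       n_trials = length(traces))
}
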