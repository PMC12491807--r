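#' Pipeline configuration
#'
#' Assembles and validates the configuration of an end-to-end synthetic
#' cohort run. Unknown keys are rejected. The resolved configuration is
#' written next to the outputs of every run.
#'
#' @param seed Master seed; all randomness in the run derives from it.
#' @param out_dir Output directory.
#' @param n_animals,units_per_animal Cohort size.
#' @param duration Trial length per unit, seconds.
#' @param frame_rate Movie frame rate, Hz.
#' @param image_size Movie frame size `c(ny, nx)` in pixels.
#' @param noise_sd Acquisition noise SD, intensity units.
#' @param effect_dilation Fractional post-treatment diameter change
#'   programmed into the synthetic cohort (e.g. 0.1 = +10%).
#' @param effect_event_rate Multiplier on post-treatment calcium event
#'   rate (e.g. 0.5 halves the rate).
#' @param velocity,flux_rate,D0 Baseline hemodynamic parameters.
#' @param with_movies Generate and analyse calcium movies (slower) in
#'   addition to traces.
#'
#' @return A validated list of class `PipelineConfig`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("run"),
                            n_animals = 3L, units_per_animal = 2L,
                            duration = 60, frame_rate = 12,
                            image_size = c(64L, 64L), noise_sd = 2,
                            effect_dilation = 0.1,
                            effect_event_rate = 0.5,
                            velocity = 2, flux_rate = 80, D0 = 10,
                            with_movies = FALSE) {
  cfg <- list(seed = as.integer(seed), out_dir = out_dir,
              n_animals = as.integer(n_animals),
              units_per_animal = as.integer(units_per_animal),
              duration = duration, frame_rate = frame_rate,
              image_size = as.integer(image_size), noise_sd = noise_sd,
              effect_dilation = effect_dilation,
              effect_event_rate = effect_event_rate,
              velocity = velocity, flux_rate = flux_rate, D0 = D0,
              with_movies = isTRUE(with_movies))
  stopifnot(cfg$n_animals >= 2L, cfg$units_per_animal >= 1L,
            cfg$duration > 0, cfg$frame_rate > 0)
  structure(cfg, class = "PipelineConfig")
}

#' Run the end-to-end synthetic cohort pipeline
#'
#' For each unit (vessel + pericyte) in each animal, and for both
#' treatment conditions (`pre`, `post`), the pipeline generates
#' synthetic data, then executes the full analysis chain: calcium trace
#' -> dF/F -> peak detection -> PSD peak (plus optional movie ->
#' unmixing -> 3-D events), and diameter/velocity/flux kymographs ->
#' cleaning -> resampling -> vasomotion metrics. Unit-level summaries
#' are then compared pre vs. post with the mixed-model layer, and all
#' tables are written as CSV with the resolved configuration (JSON) and
#' its hash beside them. Runs are deterministic: the same configuration
#' yields byte-identical summary tables.
#'
#' @param config A [pipeline_config()].
#'
#' @return Invisibly, a list with `units` (per-unit summary data
#'   frame), `lmm` (per-metric mixed-model results), `files` (paths
#'   written), `n_failed` (units that failed and were skipped).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_hash <- rlang::hash(unclass(config)[setdiff(names(config),
                                                  "out_dir")])
  jsonlite::write_json(unclass(config), file.path(config$out_dir,
                                                  "config.json"),
                       auto_unbox = TRUE, digits = NA)
  log_lines <- character(0)
  log_add <- function(...) log_lines <<- c(log_lines, paste0(...))
  units <- list()
  n_failed <- 0L
  uid <- 0L
  for (a in seq_len(config$n_animals)) {
    for (u in seq_len(config$units_per_animal)) {
      for (cond in c("pre", "post")) {
        uid <- uid + 1L
        seed_u <- config$seed + 7919L * uid
        res <- tryCatch(
          analyze_unit(config, a, u, cond, seed_u),
          error = function(e) e)
        if (inherits(res, "error")) {
          n_failed <- n_failed + 1L
          log_add("unit a", a, "_u", u, " [", cond, "] FAILED: ",
                  conditionMessage(res))
          next
        }
        log_add("unit a", a, "_u", u, " [", cond, "] ok; outliers=",
                res$n_outliers)
        units[[length(units) + 1L]] <- res$row
      }
    }
  }
  units <- do.call(rbind, units)
  metrics <- c("mean_diameter_um", "vasomotor_index",
               "vasomotion_freq_per_min", "mean_velocity_mm_s",
               "mean_flux_cells_s", "ca_events_per_min",
               "ca_amp_mean_dff", "ca_peak_freq_hz")
  lmm <- lapply(metrics, function(m) {
    tab <- data.frame(animal_id = units$animal_id,
                      unit_id = units$unit_id,
                      treatment = units$treatment, value = units[[m]])
    tab <- tab[is.finite(tab$value), ]
    out <- tryCatch(fit_lmm(tab), error = function(e) NULL)
    if (is.null(out)) return(NULL)
    data.frame(metric = m, estimate = out$estimate,
               ci_lo = out$ci[1], ci_hi = out$ci[2],
               lrt = out$lrt_statistic, p_value = out$p_value,
               singular = out$singular)
  })
  lmm <- do.call(rbind, lmm[!vapply(lmm, is.null, TRUE)])
  if (!is.null(lmm) && nrow(lmm))
    lmm$holm_p <- holm_adjust(lmm$p_value)
  f_units <- file.path(config$out_dir, "units.csv")
  f_lmm <- file.path(config$out_dir, "lmm_results.csv")
  f_log <- file.path(config$out_dir, "run.log")
  write_observations(units, f_units, cfg_hash)
  write_observations(lmm, f_lmm, cfg_hash)
  writeLines(log_lines, f_log)
  invisible(list(units = units, lmm = lmm,
                 files = c(f_units, f_lmm, f_log), n_failed = n_failed,
                 config_hash = cfg_hash))
}

# One unit x condition: generate, analyse, summarize.
analyze_unit <- function(config, a, u, cond, seed_u) {
  post <- cond == "post"
  dil <- if (post) 1 + config$effect_dilation else 1
  evr <- if (post) config$effect_event_rate else 1
  scfg <- synth_config(seed = seed_u, frame_rate = config$frame_rate,
                       duration = config$duration,
                       image_size = config$image_size,
                       noise_sd = config$noise_sd)
  # calcium trace analysis
  tr <- gen_calcium_trace(scfg, event_rate = 6 * evr, amp_mean = 0.6,
                          oscillation = c(0.1, 0.1))
  ca <- compute_dff(tr$trace, config$frame_rate)
  pk <- detect_peaks(ca)
  ps <- compute_psd_peak(ca)
  f0b <- compute_f0_basal(tr$trace, config$frame_rate)
  ev3 <- NULL
  if (config$with_movies) {
    mcfg <- synth_config(seed = seed_u + 1L,
                         frame_rate = config$frame_rate,
                         duration = min(config$duration, 30),
                         image_size = config$image_size,
                         noise_sd = config$noise_sd,
                         bleed_fraction = 0.1)
    mv <- gen_calcium_movie(mcfg, event_rate = 3 * evr, amp = 1.5)
    um <- unmix_channels(mv$movie, mv$mixing_matrix)
    ev3 <- detect_events_3d(um, mv$rois)
  }
  # hemodynamics
  kcfg <- synth_config(seed = seed_u + 2L, duration = 20,
                       line_period = 0.002, pixel_size = 0.5,
                       noise_sd = 4)
  dk <- gen_diameter_kymograph(kcfg, D0 = config$D0 * dil,
                               vaso_amp = if (post) 0.05 else 0.1,
                               vaso_freq = 0.1, scan_px = 64L)
  kcfg2 <- synth_config(seed = seed_u + 3L, duration = 35,
                        line_period = 0.002, pixel_size = 0.5,
                        noise_sd = 4)
  dk_vaso <- gen_diameter_kymograph(kcfg2, D0 = config$D0 * dil,
                                    vaso_amp = if (post) 0.05 else 0.1,
                                    vaso_freq = 0.1, scan_px = 64L)
  dia <- clean_trace(diameter_from_kymograph(dk_vaso$kym))
  vaso <- vasomotion_metrics(resample_smooth(dia))
  vk <- gen_velocity_kymograph(kcfg, velocity = config$velocity *
                                 (if (post) 0.8 else 1),
                               flux_rate = config$flux_rate)
  vel <- resample_smooth(clean_trace(
    velocity_from_kymograph(vk$kym)))
  flx <- resample_smooth(clean_trace(flux_from_kymograph(vk$kym)))
  n_out <- (attr(dia, "n_outliers_removed") %||% 0L)
  row <- data.frame(
    animal_id = paste0("a", a),
    unit_id = paste0("a", a, "_u", u),
    treatment = cond,
    mean_diameter_um = mean(dia$values, na.rm = TRUE),
    vasomotor_index = vaso$vasomotor_index,
    vasomotion_freq_per_min = vaso$frequency_per_min,
    vasomotion_psd_peak_hz = vaso$peak_freq_hz,
    mean_velocity_mm_s = mean(vel$values, na.rm = TRUE),
    mean_flux_cells_s = mean(flx$values, na.rm = TRUE),
    ca_events_per_min = pk$summary$events_per_min,
    ca_amp_mean_dff = if (is.na(pk$summary$amp_mean)) 0
                      else pk$summary$amp_mean,
    ca_peak_freq_hz = ps$peak_freq,
    ca_f0_basal = f0b,
    ca_events3d_per_min = if (is.null(ev3)) NA_real_
                          else sum(ev3$frequency))
  list(row = row, n_outliers = n_out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
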