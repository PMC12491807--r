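# TIFF float pages must lie in [0, 1]; intensities are mapped as
# v / (2 s) + 0.5 with s a power of two >= max |v|. The power-of-two
# scale makes the mapping exact in floating point, so a file re-written
# from its own read-back is bit-identical. The scale is recorded in the
# JSON sidecar and reused when an object carries one.
tiff_scale <- function(x, reuse = NULL) {
  if (!is.null(reuse)) return(reuse)
  m <- max(abs(x), 1e-12)
  2^ceiling(log2(m))
}
tiff_encode <- function(x, s) x / (2 * s) + 0.5
tiff_decode <- function(x, s) (x - 0.5) * (2 * s)

#' Write a fluorescence movie to multi-page TIFF + JSON sidecar
#'
#' Pages are written as 32-bit float TIFF in frame order, channels
#' interleaved frame-by-frame (all channels of frame 1, then frame 2,
#' ...). The sidecar (`<path>.json`) records `frame_rate`,
#' `channel_names` and the array dimensions, making the file
#' self-describing.
#'
#' @param movie A [fluorescence_movie()].
#' @param path Output TIFF path.
#'
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  s <- tiff_scale(movie$data, attr(movie, "intensity_scale"))
  pages <- list()
  for (t in seq_len(d[1]))
    for (c in seq_len(d[4]))
      pages[[length(pages) + 1L]] <- tiff_encode(movie$data[t, , , c], s)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- list(frame_rate = movie$frame_rate,
               channel_names = movie$channel_names,
               n_frames = d[1], height = d[2], width = d[3],
               n_channels = d[4], intensity_scale = s)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a fluorescence movie from multi-page TIFF + JSON sidecar
#'
#' @param path TIFF path written by [write_movie()] (sidecar at
#'   `<path>.json`). 1--2 channels are supported.
#'
#' @return A [fluorescence_movie()].
#' @export
read_movie <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for movie: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$frame_rate) || meta$frame_rate <= 0)
    stop("invalid frame_rate in sidecar: ", sidecar, call. = FALSE)
  if (meta$n_channels > 2L)
    stop("unsupported channel count (", meta$n_channels, ") in ", path,
         call. = FALSE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (length(pages) != meta$n_frames * meta$n_channels)
    stop("page count inconsistent with sidecar for ", path, call. = FALSE)
  data <- array(0, dim = c(meta$n_frames, meta$height, meta$width,
                           meta$n_channels))
  p <- 1L
  for (t in seq_len(meta$n_frames))
    for (c in seq_len(meta$n_channels)) {
      data[t, , , c] <- tiff_decode(pages[[p]], meta$intensity_scale)
      p <- p + 1L
    }
  out <- fluorescence_movie(data, meta$frame_rate,
                            unlist(meta$channel_names))
  attr(out, "intensity_scale") <- meta$intensity_scale
  out
}

#' Write a kymograph to TIFF + JSON sidecar
#'
#' @param kym A [kymograph()].
#' @param path Output TIFF path; metadata goes to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_kymograph <- function(kym, path) {
  s <- tiff_scale(kym$data, attr(kym, "intensity_scale"))
  tiff::writeTIFF(list(tiff_encode(kym$data, s)), path,
                  bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(line_period = kym$line_period,
                            pixel_size = kym$pixel_size,
                            orientation = kym$orientation,
                            intensity_scale = s),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a kymograph from TIFF (or CSV matrix) + JSON sidecar
#'
#' @param path TIFF or CSV path; sidecar `<path>.json` must hold
#'   `line_period` (s), `pixel_size` (um/px) and `orientation`.
#' @return A [kymograph()].
#' @export
read_kymograph <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing JSON sidecar for kymograph: ", sidecar, call. = FALSE)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  data <- if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    as.matrix(read.csv(path, header = FALSE))
  } else {
    pg <- tiff::readTIFF(path, all = TRUE)
    tiff_decode(pg[[1L]], meta$intensity_scale)
  }
  dimnames(data) <- NULL
  out <- kymograph(data, meta$line_period, meta$pixel_size,
                   meta$orientation)
  attr(out, "intensity_scale") <- meta$intensity_scale
  out
}

#' Write an observation table as CSV
#'
#' Long-format unit-level table with the standard columns
#' `(animal_id, unit_id, compartment, branch_order, treatment, trial,
#' value)`.
#'
#' @param table Data frame.
#' @param path Output CSV path.
#' @param config_hash Optional hash string written as a `#` header
#'   comment, making the file traceable to its resolved configuration.
#' @return `path`, invisibly.
#' @export
write_observations <- function(table, path, config_hash = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  write.csv(table, con, row.names = FALSE)
  invisible(path)
}

#' Read an observation table CSV
#'
#' @param path CSV written by [write_observations()] (header comment
#'   lines starting with `#` are skipped).
#' @return Data frame.
#' @export
read_observations <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
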