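#' Find local maxima by topographic prominence
#'
#' Locates local maxima of a numeric vector, computes each candidate's
#' topographic prominence (height above the higher of the two key
#' saddles separating it from taller terrain), and enforces a minimum
#' peak separation by keeping the taller of any two peaks closer than
#' `min_distance` samples. On a flat-topped (plateau) maximum only the
#' first sample of the plateau is reported, so two identical adjacent
#' peaks within the separation window count once.
#'
#' @param x Numeric vector.
#' @param min_prominence Minimum prominence to report a peak.
#' @param min_distance Minimum index separation between reported peaks.
#'
#' @return A data frame with columns `index`, `value`, `prominence`,
#'   sorted by index; zero rows when nothing qualifies.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1L) {
  n <- length(x)
  if (n < 3L) return(data.frame(index = integer(0), value = numeric(0),
                                prominence = numeric(0)))
  dx <- diff(x)
  # strict rise then (possibly after a plateau) a fall
  cand <- integer(0)
  i <- 2L
  while (i <= n - 1L) {
    if (x[i] > x[i - 1L]) {
      j <- i
      while (j < n && x[j + 1L] == x[j]) j <- j + 1L   # walk plateau
      if (j < n && x[j + 1L] < x[j]) cand <- c(cand, i)
      i <- j + 1L
    } else i <- i + 1L
  }
  if (!length(cand)) return(data.frame(index = integer(0),
                                       value = numeric(0),
                                       prominence = numeric(0)))
  prom <- vapply(cand, function(p) {
    h <- x[p]
    lmin <- h; k <- p
    while (k > 1L && x[k - 1L] <= h) { k <- k - 1L; lmin <- min(lmin, x[k]) }
    if (k == 1L) lmin <- min(x[1:p])
    rmin <- h; k <- p
    while (k < n && x[k + 1L] <= h) { k <- k + 1L; rmin <- min(rmin, x[k]) }
    if (k == n) rmin <- min(x[p:n])
    h - max(lmin, rmin)
  }, 0)
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (!length(cand)) return(data.frame(index = integer(0),
                                       value = numeric(0),
                                       prominence = numeric(0)))
  # enforce separation: greedily accept by decreasing height
  ord <- order(x[cand], decreasing = TRUE)
  accepted <- integer(0)
  for (k in ord) {
    if (!length(accepted) ||
        all(abs(cand[accepted] - cand[k]) >= min_distance))
      accepted <- c(accepted, k)
  }
  sel <- sort(cand[accepted])
  data.frame(index = sel, value = x[sel],
             prominence = prom[match(sel, cand)])
}

#' Zero-phase FFT band-pass filter
#'
#' Band-limits a series by masking Fourier coefficients outside
#' `[lo, hi]` Hz and inverting the transform. Applied in the frequency
#' domain the filter is exactly zero-phase, and it remains well
#' conditioned for pass bands reaching far below the sampling rate
#' (e.g. 0.01 Hz at ~12 Hz sampling), where recursive filters become
#' numerically fragile. The DC component is removed whenever `lo > 0`.
#'
#' @param x Numeric vector.
#' @param fs Sampling rate, Hz.
#' @param lo,hi Pass-band edges, Hz; must satisfy
#'   `0 <= lo < hi <= fs/2`.
#'
#' @return Filtered numeric vector, same length as `x`.
#' @export
bandpass_fft <- function(x, fs, lo, hi) {
  if (lo < 0 || hi <= lo || hi > fs / 2)
    stop("band edges must satisfy 0 <= lo < hi <= fs/2", call. = FALSE)
  n <- length(x)
  X <- fft(x)
  k <- 0:(n - 1)
  f <- pmin(k, n - k) * fs / n          # two-sided frequency magnitude
  X[f < lo | f > hi] <- 0
  Re(fft(X, inverse = TRUE)) / n
}
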