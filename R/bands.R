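#' Canonical ECoG frequency band table
#'
#' The seven spectral bands used throughout the package. Band edges are chosen
#' to cover the classical sensorimotor rhythms while avoiding 60 Hz line noise
#' and its harmonics: delta (0-4 Hz), theta (4-8), mu (7-13), beta (14-30),
#' low gamma (30-50), high gamma 1 (70-110) and high gamma 2 (130-200).
#'
#' @return A data.frame with columns `name`, `lo`, `hi` (Hz), one row per band,
#'   in canonical order.
#' @export
#' @examples
#' band_table()
band_table <- function() {
  data.frame(
    name = c("delta", "theta", "mu", "beta", "low_gamma",
             "high_gamma_1", "high_gamma_2"),
    lo = c(0, 4, 7, 14, 30, 70, 130),
    hi = c(4, 8, 13, 30, 50, 110, 200),
    stringsAsFactors = FALSE
  )
}

#' Feature type labels (7 bands followed by the LMP)
#' @return Character vector of length 8.
#' @export
feature_types <- function() c(band_table()$name, "lmp")

band_def <- function(name) {
  tab <- band_table()
  i <- match(name, tab$name)
  if (is.na(i)) stop("unknown band: ", name)
  tab[i, ]
}

#' Design a zero-phase-ready FIR bandpass filter for one band
#'
#' Builds a 401-tap (order 400) linear-phase FIR filter with a Hamming window.
#' The delta band is realized as a 0-4 Hz low-pass, since a 0 Hz band edge is
#' not realizable as a bandpass. Coefficients are normalized to unit gain at
#' the band center (DC for delta).
#'
#' @param band Band name (see [band_table()]) or a one-row data.frame with
#'   `name`, `lo`, `hi`.
#' @param fs Sampling rate in Hz.
#' @param order Filter order (number of delay elements); the filter has
#'   `order + 1` taps. Default 400.
#' @return Numeric coefficient vector of length `order + 1`, symmetric.
#' @export
#' @examples
#' b <- design_bandpass("mu", fs = 1000)
#' length(b)  # 401
design_bandpass <- function(band, fs, order = 400) {
  if (is.character(band)) band <- band_def(band)
  stopifnot(is.data.frame(band), nrow(band) == 1)
  lo <- band$lo; hi <- band$hi
  if (hi >= fs / 2) stop("band upper edge ", hi, " Hz >= Nyquist (", fs / 2, " Hz)")
  if (lo >= hi) stop("invalid band: lo >= hi")
  nyq <- fs / 2
  if (lo <= 0) {
    b <- signal::fir1(order, hi / nyq, type = "low", scale = FALSE)
    fc <- 0
  } else {
    b <- signal::fir1(order, c(lo, hi) / nyq, type = "pass", scale = FALSE)
    fc <- (lo + hi) / 2
  }
  b <- as.numeric(b)
  b / fir_gain(b, fc, fs)
}

#' Magnitude response of an FIR filter at given frequencies
#'
#' @param b FIR coefficient vector.
#' @param f Frequencies in Hz (vector).
#' @param fs Sampling rate in Hz.
#' @return `|H(f)|`, same length as `f`.
#' @export
fir_gain <- function(b, f, fs) {
  k <- seq_along(b) - 1
  vapply(f, function(fi) Mod(sum(b * exp(-2i * pi * fi * k / fs))), numeric(1))
}
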