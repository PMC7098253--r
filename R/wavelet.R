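#' Daubechies-4 analysis filter pair
#'
#' Returns the 8-tap decomposition filters of the 'db4' wavelet (four
#' vanishing moments) in the convention used by standard multilevel DWT
#' implementations: `lo` is the reversed scaling filter, `hi` the reversed
#' wavelet filter.
#'
#' @return A list with numeric vectors `lo` and `hi`, each of length 8.
#' @export
db4_filters <- function() {
  lo <- c(-0.010597401785069032, 0.0328830116668852, 0.030841381835560764,
          -0.18703481171909309, -0.027983769416859854, 0.6308807679298589,
          0.7148465705529157, 0.2303778133088965)
  hi <- c(-0.2303778133088965, 0.7148465705529157, -0.6308807679298589,
          -0.027983769416859854, 0.18703481171909309, 0.030841381835560764,
          -0.0328830116668852, -0.010597401785069032)
  list(lo = lo, hi = hi)
}

#' Dyadic wavelet scale / frequency band map
#'
#' Builds the mapping from wavelet decomposition levels ("scales") to the
#' frequency bands they analyse under the dyadic partition: scale k spans
#' `[fs/2^(k+1), fs/2^k]` Hz, and the deepest scale additionally absorbs the
#' final approximation so its band reaches down to 0 Hz. The scales are
#' grouped into the three MWP sub-bands: low frequency (lf, scales 7-11,
#' 0-234 Hz at 30 kHz), mid frequency (mf, scales 3-6, 234 Hz-3.75 kHz) and
#' high frequency (hf, scales 1-2, above 3.75 kHz).
#'
#' @param fs Sampling rate in Hz (default 30000).
#' @param n_scales Number of decomposition levels (default 11).
#' @param wavelet Mother wavelet label; only `"db4"` is provided.
#' @return An object of class `scale_band_map`: list with `fs`, `n_scales`,
#'   `wavelet`, a data frame `bands` (columns `scale`, `f_low`, `f_high`, Hz)
#'   and `groups`, a named list of scale indices for `lf`, `mf`, `hf`.
#' @examples
#' m <- scale_band_map()
#' m$bands[m$groups$mf, ]   # the mid-frequency band, 234 Hz - 3.75 kHz
#' @export
scale_band_map <- function(fs = 30000, n_scales = 11, wavelet = "db4") {
  stopifnot(fs > 0, n_scales >= 2)
  if (!identical(wavelet, "db4"))
    stop("only the 'db4' mother wavelet is supported")
  k <- seq_len(n_scales)
  f_high <- fs / 2^k
  f_low <- fs / 2^(k + 1)
  f_low[n_scales] <- 0 # deepest scale pools the approximation band
  groups <- list(lf = 7:11, mf = 3:6, hf = 1:2)
  if (n_scales != 11)
    groups <- list(lf = seq(min(7, n_scales), n_scales),
                   mf = intersect(3:6, k), hf = intersect(1:2, k))
  structure(list(fs = fs, n_scales = n_scales, wavelet = wavelet,
                 bands = data.frame(scale = k, f_low = f_low, f_high = f_high),
                 groups = groups),
            class = "scale_band_map")
}

#' @export
print.scale_band_map <- function(x, ...) {
  cat(sprintf("<scale_band_map> %s, fs = %g Hz, %d scales\n",
              x$wavelet, x$fs, x$n_scales))
  print(x$bands, row.names = FALSE)
  invisible(x)
}

#' Single-level discrete wavelet transform
#'
#' One analysis step of the db4 DWT, returning approximation and detail
#' coefficients. `mode` selects the boundary treatment: `"symmetric"`
#' (half-sample reflection, the default used for feature extraction) or
#' `"periodization"` (periodic wrap; exactly energy-conserving for this
#' orthonormal filter pair).
#'
#' @param x Numeric vector, length at least 2.
#' @param mode Boundary mode, `"symmetric"` or `"periodization"`.
#' @return List with numeric vectors `a` (approximation) and `d` (detail).
#' @export
dwt_step <- function(x, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  f <- db4_filters()
  .dwt_step_cpp(as.numeric(x), f$lo, f$hi, mode)
}

#' Multilevel wavelet decomposition
#'
#' Repeatedly applies [dwt_step()] to the approximation, returning the detail
#' coefficients of every level plus the final approximation.
#'
#' @inheritParams dwt_step
#' @param levels Number of decomposition levels.
#' @return List with `d` (list of detail-coefficient vectors, level 1 first)
#'   and `a` (final approximation vector).
#' @export
wavedec <- function(x, levels, mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  f <- db4_filters()
  .wavedec_cpp(as.numeric(x), f$lo, f$hi, as.integer(levels), mode)
}

#' Mean absolute wavelet coefficient per scale for one bin
#'
#' The per-bin core of MWP feature extraction: decomposes one bin of raw
#' voltage into `map$n_scales` levels and returns the mean absolute detail
#' coefficient of each scale. The deepest scale pools its detail and
#' approximation coefficients, so the analysed bands jointly cover 0 Hz to
#' the Nyquist frequency.
#'
#' @param bin_samples Numeric vector of raw voltage samples (one channel, one
#'   bin); must be at least as long as the 8-tap wavelet filter.
#' @param map A [scale_band_map()].
#' @param mode Boundary mode passed to the transform.
#' @return Numeric vector of length `map$n_scales`, all entries >= 0.
#' @examples
#' map <- scale_band_map()
#' t <- seq(0, 0.1, length.out = 3000)
#' which.max(wavelet_mean_abs(sin(2 * pi * 1000 * t), map)) # scale 4
#' @export
wavelet_mean_abs <- function(bin_samples, map = scale_band_map(),
                             mode = c("symmetric", "periodization")) {
  mode <- match.arg(mode)
  bin_samples <- as.numeric(bin_samples)
  f <- db4_filters()
  if (length(bin_samples) < length(f$lo))
    stop("bin shorter than the wavelet filter length (8 samples)")
  drop(.mwp_bins_cpp(bin_samples, length(bin_samples), f$lo, f$hi,
                     as.integer(map$n_scales), mode))
}
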