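# Signal-quality summaries: per-window SNR from detected threshold
# crossings, and the chronic normalized signal-strength series.

#' Signal-to-noise ratio in decibels
#'
#' `20 * log10(signal / noise)`, the SNR convention for spike recordings
#' where `signal` is a mean peak-to-peak amplitude and `noise` a mean RMS.
#'
#' @param signal Signal amplitude(s), uV.
#' @param noise Noise RMS value(s), uV.
#' @return SNR in dB.
#' @examples
#' snr_db(100, 10) # 20 dB
#' @export
snr_db <- function(signal, noise) 20 * log10(signal / noise)

#' Windowed SNR summary of a recording
#'
#' Splits each channel into 2 s windows. Within a window, `signal` is the
#' mean peak-to-peak amplitude of the threshold crossings detected there and
#' `noise` is the mean RMS of the high-passed trace over the 100 disjoint
#' 20 ms sub-windows; `snr = 20 log10(signal / noise)`. Windows with no
#' detected events carry an undefined signal and are excluded from the
#' recording-level means (rather than contributing -Inf dB).
#'
#' @param recording A [raw_recording()].
#' @param events Optional [detect_threshold_crossings()] result (computed
#'   here when absent).
#' @param config A [feature_config()] (high-pass settings).
#' @param window SNR window, s (default 2).
#' @param noise_subwindow Noise RMS sub-window, s (default 0.02); must
#'   divide `window`.
#' @return An object of class `snr_summary`: data frame `windows` with
#'   columns `channel`, `t_start_s`, `signal_uv`, `noise_uv`, `snr_db`, and
#'   `means` (recording-level mean `snr_db`, `p2p_uv`, `rms_noise_uv`).
#' @export
snr_summary <- function(recording, events = NULL, config = feature_config(),
                        window = 2, noise_subwindow = 0.02) {
  ratio <- window / noise_subwindow
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("window must be an integer multiple of noise_subwindow")
  if (recording_duration(recording) < window)
    stop("recording shorter than one SNR window")
  if (is.null(events)) events <- detect_threshold_crossings(recording, config)
  fs <- recording$fs
  filtered <- .hp_filter(recording, config)
  wlen <- round(window * fs)
  slen <- round(noise_subwindow * fs)
  n <- nrow(filtered)
  nwin <- floor(n / wlen)
  rows <- list()
  for (ch in seq_len(ncol(filtered))) {
    ev <- events$events[[ch]]
    for (wi in seq_len(nwin)) {
      i0 <- (wi - 1) * wlen
      seg <- filtered[(i0 + 1):(i0 + wlen), ch]
      sub <- matrix(seg, nrow = slen)
      noise <- mean(sqrt(colMeans(sub^2)))
      t0 <- i0 / fs
      in_win <- ev$time_s >= t0 & ev$time_s < t0 + window
      sig <- if (any(in_win)) mean(ev$p2p_uv[in_win]) else NA_real_
      rows[[length(rows) + 1]] <- data.frame(
        channel = recording$channel_ids[ch], t_start_s = t0,
        signal_uv = sig, noise_uv = noise,
        snr_db = if (is.na(sig)) NA_real_ else snr_db(sig, noise))
    }
  }
  windows <- do.call(rbind, rows)
  structure(list(windows = windows,
                 means = list(snr_db = mean(windows$snr_db, na.rm = TRUE),
                              p2p_uv = mean(windows$signal_uv, na.rm = TRUE),
                              rms_noise_uv = mean(windows$noise_uv))),
            class = "snr_summary")
}

#' @export
print.snr_summary <- function(x, ...) {
  cat(sprintf("<snr_summary> %d channel-windows: SNR %.2f dB, p2p %.1f uV, noise RMS %.1f uV\n",
              nrow(x$windows), x$means$snr_db, x$means$p2p_uv,
              x$means$rms_noise_uv))
  invisible(x)
}

#' Chronic normalized signal-strength series
#'
#' The stability metric for a feature kind across days: for each day, the
#' mean absolute binned-stage feature value is averaged over bins, channels
#' and blocks, and the resulting daily series is normalized to its first
#' entry (day one is exactly 1).
#'
#' @param blocks_by_day List with one element per day; each element is a
#'   list of binned-stage [feature_series()] (or plain matrices), the
#'   blocks recorded that day.
#' @param days Optional numeric day indices (defaults to 1, 2, ...).
#' @return An object of class `signal_strength_series`: data frame with
#'   columns `day`, `strength` (raw mean absolute value) and `normalized`.
#' @export
signal_strength <- function(blocks_by_day, days = NULL) {
  if (length(blocks_by_day) == 0) stop("no days supplied")
  day_value <- function(blocks) {
    if (length(blocks) == 0) stop("a day with no blocks was supplied")
    mean(vapply(blocks, function(b) {
      v <- if (inherits(b, "feature_series")) b$values else b
      mean(abs(v))
    }, numeric(1)))
  }
  strength <- vapply(blocks_by_day, day_value, numeric(1))
  if (is.null(days)) days <- seq_along(strength)
  structure(data.frame(day = days, strength = strength,
                       normalized = strength / strength[1]),
            class = c("signal_strength_series", "data.frame"))
}

#' Rolling-mean trend of a signal-strength series
#'
#' A simple centred rolling mean over `k` days, as a lightweight trend
#' summary of the chronic series.
#'
#' @param series A [signal_strength()] result.
#' @param k Window length in days (odd; default 5).
#' @return The series with an added `trend` column.
#' @export
strength_trend <- function(series, k = 5) {
  x <- series$normalized
  half <- k %/% 2
  n <- length(x)
  series$trend <- vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
  series
}
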