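# Feature extraction: MWP (wavelet), threshold crossings, LFP, MUA, plus the
# shared post-processing chain of the 100 ms pipeline:
#   binned -> smoothed (1 s causal moving average)
#          -> baselined (15 s windowed mean subtraction)
#          -> standardized (train-block mean/sd).

.stages <- c("binned", "smoothed", "baselined", "standardized")

#' Binned feature time series
#'
#' A bins x channels matrix (or bins x channels x scales array for raw
#' wavelet scales) of feature values at a fixed bin width, tagged with the
#' processing stage it has reached. Stages only advance in the order
#' binned, smoothed, baselined, standardized.
#'
#' @param values Matrix `n_bins x n_channels` or array
#'   `n_bins x n_channels x n_scales`.
#' @param bin_width Bin width in seconds (default 0.1).
#' @param feature_kind One of `"lf_mwp"`, `"mf_mwp"`, `"hf_mwp"`, `"tc"`,
#'   `"lfp"`, `"mua"`, `"raw_scales"`.
#' @param stage Processing stage.
#' @param channel_ids Channel identifiers (second dimension).
#' @return An object of class `feature_series`.
#' @export
feature_series <- function(values, bin_width = 0.1, feature_kind = "raw_scales",
                           stage = "binned", channel_ids = NULL) {
  stage <- match.arg(stage, .stages)
  feature_kind <- match.arg(feature_kind,
    c("lf_mwp", "mf_mwp", "hf_mwp", "tc", "lfp", "mua", "raw_scales"))
  if (is.null(dim(values))) values <- matrix(values, ncol = 1)
  if (!length(dim(values)) %in% c(2, 3))
    stop("values must be a matrix or a 3-d array")
  if (is.null(channel_ids))
    channel_ids <- sprintf("ch%03d", seq_len(dim(values)[2]))
  structure(list(values = values, bin_width = bin_width,
                 feature_kind = feature_kind, stage = stage,
                 channel_ids = as.character(channel_ids)),
            class = "feature_series")
}

#' @export
print.feature_series <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_series> %s [%s]: %d bins x %d channels%s @ %g s\n",
              x$feature_kind, x$stage, d[1], d[2],
              if (length(d) == 3) sprintf(" x %d scales", d[3]) else "",
              x$bin_width))
  invisible(x)
}

n_bins <- function(series) dim(series$values)[1]

.check_stage <- function(series, required, what) {
  if (!identical(series$stage, required))
    stop(what, " expects a series at stage '", required,
         "', got '", series$stage, "'")
}

# apply f column-wise, treating a 3-d array as bins x (channels*scales)
.apply_cols <- function(values, f) {
  d <- dim(values)
  m <- if (length(d) == 3) {v <- values; dim(v) <- c(d[1], d[2] * d[3]); v} else values
  out <- f(m)
  dim(out) <- d
  dimnames(out) <- dimnames(values)
  out
}

#' Extraction and post-processing configuration
#'
#' Collects the tunable parameters of all extractors: the 100 ms bin width,
#' the 1 s causal smoothing window, the 15 s baseline-subtraction window and
#' per-feature filter settings (250 Hz high-pass and -4.5 x RMS threshold
#' for TC detection, 3rd-order 100 Hz low-pass for LFP, 300-6000 Hz
#' band-pass for MUA, 11 'db4' scales for MWP).
#'
#' @param bin_width Bin width, s (default 0.1).
#' @param smooth_window Causal moving-average window, s (default 1).
#' @param baseline_window Baseline-subtraction window, s (default 15).
#' @param n_scales Wavelet decomposition levels (default 11).
#' @param mwp_mode Wavelet boundary mode (default `"symmetric"`).
#' @param tc List: `hp_cutoff` (Hz, 250), `multiplier` (-4.5), `dead_time`
#'   (s, 0.001), `rms_window` (s, 2), `snippet_pre`/`snippet_post` (s).
#' @param lfp List: `cutoff` (Hz, 100), `order` (3).
#' @param mua List: `band` (Hz, `c(300, 6000)`), `order` (4).
#' @param zero_phase Use zero-phase (forward-backward) filtering instead of
#'   the causal, real-time-compatible default.
#' @return An object of class `feature_config`.
#' @export
feature_config <- function(bin_width = 0.1, smooth_window = 1,
                           baseline_window = 15, n_scales = 11,
                           mwp_mode = "symmetric",
                           tc = list(), lfp = list(), mua = list(),
                           zero_phase = FALSE) {
  if (!(bin_width > 0 && bin_width <= smooth_window &&
        smooth_window <= baseline_window))
    stop("need 0 < bin_width <= smooth_window <= baseline_window")
  tc <- utils::modifyList(list(hp_cutoff = 250, hp_order = 2,
                               multiplier = -4.5,
                               dead_time = 0.001, rms_window = 2,
                               snippet_pre = 0.0006, snippet_post = 0.001), tc)
  lfp <- utils::modifyList(list(cutoff = 100, order = 3), lfp)
  mua <- utils::modifyList(list(band = c(300, 6000), order = 4), mua)
  structure(list(bin_width = bin_width, smooth_window = smooth_window,
                 baseline_window = baseline_window, n_scales = n_scales,
                 mwp_mode = mwp_mode, tc = tc, lfp = lfp, mua = mua,
                 zero_phase = zero_phase),
            class = "feature_config")
}

# filter every channel (column) of a samples x channels matrix
.filter_channels <- function(samples, filt, zero_phase = FALSE) {
  if (!zero_phase) {
    out <- .iir_filter_cols_cpp(filt$b, filt$a, samples)
    dimnames(out) <- dimnames(samples)
    return(out)
  }
  out <- samples
  for (i in seq_len(ncol(samples)))
    out[, i] <- signal::filtfilt(filt, samples[, i])
  out
}

# spike-band front end: causal 2nd-order Butterworth high-pass. A low
# filter order preserves the negative spike peak (higher orders sag a
# sub-millisecond trough appreciably when run causally).
.hp_filter <- function(recording, config) {
  filt <- signal::butter(config$tc$hp_order,
                         config$tc$hp_cutoff / (recording$fs / 2),
                         type = "high")
  .filter_channels(recording$samples, filt, config$zero_phase)
}

#' Bin a recording into a feature time series
#'
#' Splits each channel into consecutive half-open bins
#' `[k * bin_width, (k + 1) * bin_width)` and reduces each bin with
#' `extractor`; a trailing partial bin is discarded.
#'
#' @param recording A [raw_recording()] (or a channels x samples matrix plus
#'   `fs`).
#' @param extractor `"mean"`, `"rms"`, or a function of one numeric vector.
#' @param bin_width Bin width in seconds (default 0.1).
#' @param feature_kind Label stored on the result.
#' @return A [feature_series()] at stage `"binned"`.
#' @export
bin_series <- function(recording, extractor = "mean", bin_width = 0.1,
                       feature_kind = "raw_scales") {
  samples <- recording$samples
  fs <- recording$fs
  bl <- round(bin_width * fs)
  nb <- floor(nrow(samples) / bl)
  if (nb < 1) stop("recording shorter than one bin")
  nch <- ncol(samples)
  if (identical(extractor, "mean") || identical(extractor, "rms")) {
    out <- .bin_reduce_cpp(samples, bl, nb,
                           if (identical(extractor, "mean")) 0L else 1L)
  } else {
    out <- matrix(0, nb, nch)
    for (ch in seq_len(nch)) {
      m <- matrix(samples[seq_len(nb * bl), ch], nrow = bl)
      out[, ch] <- apply(m, 2, extractor)
    }
  }
  feature_series(out, bin_width, feature_kind, "binned",
                 recording$channel_ids)
}

#' Causal moving average
#'
#' Smooths each channel (and scale) with an expanding-then-sliding causal
#' mean: bin `k` becomes the mean of bins `max(1, k - w + 1) .. k`, where
#' `w = window / bin_width`. No future bin ever influences the output.
#'
#' @param series A [feature_series()] at stage `"binned"`.
#' @param window Window length in seconds (default 1).
#' @return The smoothed series at stage `"smoothed"`.
#' @export
causal_moving_average <- function(series, window = 1) {
  .check_stage(series, "binned", "causal_moving_average")
  w <- round(window / series$bin_width)
  if (w < 1) stop("window shorter than one bin")
  smooth_col <- function(m) {
    cs <- apply(m, 2, cumsum)
    if (is.null(dim(cs))) cs <- matrix(cs, nrow = nrow(m))
    nb <- nrow(m)
    denom <- pmin(seq_len(nb), w)
    lagged <- rbind(matrix(0, min(w, nb), ncol(m)),
                    cs[seq_len(max(0, nb - w)), , drop = FALSE])
    (cs - lagged) / denom
  }
  out <- series
  out$values <- .apply_cols(series$values, smooth_col)
  out$stage <- "smoothed"
  out
}

#' Windowed baseline subtraction
#'
#' Removes slow drift by partitioning the series into consecutive
#' non-overlapping windows (15 s by default) and subtracting each window's
#' own per-channel (per-scale) mean; a final partial window is demeaned with
#' its own mean.
#'
#' @param series A [feature_series()] at stage `"smoothed"`.
#' @param window Window length in seconds (default 15).
#' @return The baselined series at stage `"baselined"`.
#' @export
baseline_subtract <- function(series, window = 15) {
  .check_stage(series, "smoothed", "baseline_subtract")
  wb <- round(window / series$bin_width)
  if (wb < 1) stop("window shorter than one bin")
  nb <- n_bins(series)
  grp <- (seq_len(nb) - 1) %/% wb
  demean <- function(m) {
    mu <- rowsum(m, grp) / as.vector(table(grp))
    m - mu[grp + 1, , drop = FALSE]
  }
  out <- series
  out$values <- .apply_cols(series$values, demean)
  out$stage <- "baselined"
  out
}

#' Fit standardization statistics on a training block
#'
#' Computes the per-channel (per-scale) mean and population standard
#' deviation of a baselined training-block series. Channels with zero
#' variance are flagged degenerate.
#'
#' @param series A [feature_series()] at stage `"baselined"` with >= 2 bins.
#' @param source_block Optional identifier of the training block.
#' @return An object of class `normalization_stats` with fields `mean`,
#'   `std` (shaped channels or channels x scales), `degenerate`,
#'   `source_block`.
#' @export
fit_standardizer <- function(series, source_block = NULL) {
  .check_stage(series, "baselined", "fit_standardizer")
  if (n_bins(series) < 2) stop("need at least 2 bins to fit a standardizer")
  d <- dim(series$values)
  m <- series$values
  dim(m) <- c(d[1], prod(d[-1]))
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(m^2) - mu^2) # population convention
  sdev[sdev < 0] <- 0
  shape <- if (length(d) == 3) c(d[2], d[3]) else d[2]
  dim(mu) <- shape; dim(sdev) <- shape
  structure(list(mean = mu, std = sdev, degenerate = sdev == 0,
                 source_block = source_block),
            class = "normalization_stats")
}

#' Apply standardization statistics
#'
#' Standardizes a baselined series with statistics fitted on a (possibly
#' different) training block: `(x - mean) / std` elementwise; entries with
#' degenerate (zero) training std map to 0.
#'
#' @param series A [feature_series()] at stage `"baselined"`.
#' @param stats A [fit_standardizer()] result of matching shape.
#' @return The standardized series at stage `"standardized"`.
#' @export
apply_standardizer <- function(series, stats) {
  .check_stage(series, "baselined", "apply_standardizer")
  stopifnot(inherits(stats, "normalization_stats"))
  d <- dim(series$values)
  if (prod(d[-1]) != length(stats$mean))
    stop("standardizer shape does not match the series")
  m <- series$values
  dim(m) <- c(d[1], prod(d[-1]))
  std <- as.vector(stats$std)
  std_safe <- ifelse(std == 0, 1, std)
  z <- sweep(sweep(m, 2, as.vector(stats$mean)), 2, std_safe, "/")
  z[, std == 0] <- 0
  dim(z) <- d
  out <- series
  out$values <- z
  out$stage <- "standardized"
  out
}

#' Average selected wavelet scales into per-channel features
#'
#' Reduces a bins x channels x scales series to bins x channels by an
#' unweighted mean over the selected scales. The presets follow the MWP
#' band grouping: `lf` = scales 7-11, `mf` = scales 3-6, `hf` = scales 1-2.
#'
#' @param series A [feature_series()] with a 3-d values array.
#' @param scale_set Integer scales to average, or one of `"lf"`, `"mf"`,
#'   `"hf"`.
#' @param map A [scale_band_map()] supplying the presets.
#' @return A bins x channels [feature_series()] at the same stage.
#' @export
combine_scales <- function(series, scale_set, map = scale_band_map()) {
  d <- dim(series$values)
  if (length(d) != 3) stop("combine_scales needs a bins x channels x scales series")
  kind <- series$feature_kind
  if (is.character(scale_set)) {
    band <- match.arg(scale_set, c("lf", "mf", "hf"))
    scale_set <- map$groups[[band]]
    kind <- paste0(band, "_mwp")
  }
  scale_set <- as.integer(scale_set)
  if (length(scale_set) == 0 || any(scale_set < 1 | scale_set > d[3]))
    stop("scale_set must be a non-empty subset of 1..", d[3])
  v <- series$values[, , scale_set, drop = FALSE]
  out <- series
  out$values <- rowMeans(v, dims = 2)
  dim(out$values) <- d[1:2]
  out$feature_kind <- kind
  out
}

#' Raw mean-wavelet-coefficient scale series
#'
#' Runs the per-bin multilevel db4 decomposition over a whole recording:
#' every 100 ms bin of every channel is decomposed into `config$n_scales`
#' levels and reduced to the mean absolute coefficient per scale.
#'
#' @param recording A [raw_recording()].
#' @param config A [feature_config()].
#' @return A bins x channels x scales [feature_series()] at stage
#'   `"binned"`, kind `"raw_scales"`.
#' @export
mwp_scale_series <- function(recording, config = feature_config()) {
  f <- db4_filters()
  bl <- round(config$bin_width * recording$fs)
  nb <- floor(nrow(recording$samples) / bl)
  if (nb < 1) stop("recording shorter than one bin")
  nch <- ncol(recording$samples)
  out <- array(0, c(nb, nch, config$n_scales))
  for (ch in seq_len(nch)) {
    out[, ch, ] <- .mwp_bins_cpp(recording$samples[, ch], bl, f$lo, f$hi,
                                 as.integer(config$n_scales), config$mwp_mode)
  }
  feature_series(out, config$bin_width, "raw_scales", "binned",
                 recording$channel_ids)
}

# shared smoothing -> baseline -> standardization chain
.postprocess <- function(binned, config, stats = NULL, source_block = NULL) {
  sm <- causal_moving_average(binned, config$smooth_window)
  bl <- baseline_subtract(sm, config$baseline_window)
  if (is.null(stats)) stats <- fit_standardizer(bl, source_block)
  list(series = apply_standardizer(bl, stats), stats = stats)
}

.feature_extract <- function(series, stats, binned, kind) {
  series$feature_kind <- kind
  binned$feature_kind <- kind
  structure(list(series = series, stats = stats, binned = binned),
            class = "feature_extract")
}

#' @export
print.feature_extract <- function(x, ...) {
  cat("<feature_extract>\n  "); print(x$series)
  invisible(x)
}

#' Extract mean wavelet power (MWP) features
#'
#' The full MWP pipeline: per-bin db4 decomposition to mean absolute
#' coefficients per scale, 1 s causal smoothing, 15 s baseline subtraction,
#' standardization (fitted here when `stats` is `NULL` -- the training
#' block -- or applied from a training block otherwise), then averaging of
#' the selected scale band into one feature per channel per bin.
#'
#' @param recording A [raw_recording()].
#' @param config A [feature_config()].
#' @param band `"mf"` (scales 3-6, 234 Hz-3.75 kHz), `"lf"` (7-11) or
#'   `"hf"` (1-2).
#' @param stats Optional [fit_standardizer()] statistics from the training
#'   block; when supplied they are applied unchanged (no re-fitting).
#' @return A `feature_extract`: list with `series` (standardized bins x
#'   channels [feature_series()]), `stats` (the statistics used) and
#'   `binned` (the binned-stage band series, used for signal-strength
#'   tracking).
#' @export
extract_mwp <- function(recording, config = feature_config(),
                        band = c("mf", "lf", "hf"), stats = NULL) {
  band <- match.arg(band)
  map <- scale_band_map(recording$fs, config$n_scales)
  scales <- mwp_scale_series(recording, config)
  post <- .postprocess(scales, config, stats)
  series <- combine_scales(post$series, band, map)
  binned <- combine_scales(scales, band, map)
  .feature_extract(series, post$stats, binned, paste0(band, "_mwp"))
}

#' Detect threshold crossings
#'
#' Per channel: high-pass filters the raw voltage at 250 Hz (4th-order
#' Butterworth, causal), sets the detection threshold at
#' `multiplier x RMS` of the filtered trace within each 2 s window
#' (multiplier -4.5), and records every negative-going threshold crossing,
#' enforcing a dead time between events. A waveform snippet and its
#' peak-to-peak amplitude are kept per event.
#'
#' @param recording A [raw_recording()].
#' @param config A [feature_config()]; see its `tc` entry.
#' @return An object of class `tc_events`: per-channel event tables
#'   (`time_s`, `p2p_uv`), snippet matrices, per-window thresholds (uV),
#'   the multiplier, `fs` and recording duration.
#' @export
detect_threshold_crossings <- function(recording, config = feature_config()) {
  fs <- recording$fs
  filtered <- .hp_filter(recording, config)
  nch <- ncol(filtered); n <- nrow(filtered)
  wlen <- round(config$tc$rms_window * fs)
  dead <- round(config$tc$dead_time * fs)
  pre <- round(config$tc$snippet_pre * fs)
  post <- round(config$tc$snippet_post * fs)
  if (n < pre + post + 1) stop("recording shorter than the snippet window")
  starts <- seq(1, n, by = wlen)
  events <- vector("list", nch); snippets <- vector("list", nch)
  thresholds <- matrix(NA_real_, nch, length(starts))
  offs <- (-pre):post
  for (ch in seq_len(nch)) {
    x <- filtered[, ch]
    det <- .detect_crossings_cpp(x, wlen, config$tc$multiplier, dead)
    thresholds[ch, ] <- det$thr
    times <- det$idx
    times <- times[times > pre & times + post <= n]
    if (length(times)) {
      snip <- matrix(x[outer(times, offs, "+")], nrow = length(times))
      cols <- as.data.frame(snip)
      p2p <- do.call(pmax, cols) - do.call(pmin, cols)
    } else {
      snip <- matrix(numeric(0), 0, pre + post + 1)
      p2p <- numeric(0)
    }
    events[[ch]] <- data.frame(time_s = (times - 1) / fs, p2p_uv = p2p)
    snippets[[ch]] <- snip
  }
  structure(list(channel_ids = recording$channel_ids, fs = fs,
                 duration = n / fs, multiplier = config$tc$multiplier,
                 events = events, snippets = snippets,
                 thresholds = thresholds,
                 window_starts_s = (starts - 1) / fs,
                 rms_window = config$tc$rms_window),
            class = "tc_events")
}

#' @export
print.tc_events <- function(x, ...) {
  n <- vapply(x$events, nrow, 0L)
  cat(sprintf("<tc_events> %d channels, %.1f s, %d events (%.2f Hz/channel), threshold %.1f x RMS\n",
              length(n), x$duration, sum(n),
              mean(n) / x$duration, x$multiplier))
  invisible(x)
}

#' Threshold-crossing count features
#'
#' Counts detected events per 100 ms bin and channel, then runs the shared
#' smoothing / baseline-subtraction / standardization chain (identical
#' train/test contract to the other extractors).
#'
#' @param events A [detect_threshold_crossings()] result.
#' @param config A [feature_config()].
#' @param stats Optional training-block [fit_standardizer()] statistics.
#' @param duration Recording duration in s (default: from `events`).
#' @return A `feature_extract` (see [extract_mwp()]).
#' @export
tc_feature_series <- function(events, config = feature_config(),
                              stats = NULL, duration = NULL) {
  stopifnot(inherits(events, "tc_events"))
  if (is.null(duration)) duration <- events$duration
  nb <- floor(duration / config$bin_width)
  counts <- vapply(events$events, function(e) {
    idx <- floor(e$time_s / config$bin_width) + 1
    tabulate(idx[idx <= nb], nbins = nb)
  }, numeric(nb))
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = nb)
  binned <- feature_series(counts, config$bin_width, "tc", "binned",
                           events$channel_ids)
  post <- .postprocess(binned, config, stats)
  .feature_extract(post$series, post$stats, binned, "tc")
}

#' Extract local field potential (LFP) features
#'
#' Applies a causal 3rd-order Butterworth low-pass at 100 Hz per channel,
#' averages the filtered signal in each 100 ms bin, then runs the shared
#' post-processing chain.
#'
#' @inheritParams extract_mwp
#' @return A `feature_extract` (see [extract_mwp()]).
#' @export
extract_lfp <- function(recording, config = feature_config(), stats = NULL) {
  if (recording$fs <= 2 * config$lfp$cutoff)
    stop("sampling rate must exceed twice the low-pass cutoff")
  filt <- signal::butter(config$lfp$order,
                         config$lfp$cutoff / (recording$fs / 2), type = "low")
  rec <- recording
  rec$samples <- .filter_channels(recording$samples, filt, config$zero_phase)
  binned <- bin_series(rec, "mean", config$bin_width, "lfp")
  post <- .postprocess(binned, config, stats)
  .feature_extract(post$series, post$stats, binned, "lfp")
}

#' Extract multi-unit activity (MUA) features
#'
#' Band-pass filters each channel from 300 to 6000 Hz (causal Butterworth),
#' takes the RMS of the filtered signal in each 100 ms bin, then runs the
#' shared post-processing chain. MUA aggregates nearby spiking power
#' without detecting individual spikes.
#'
#' @inheritParams extract_mwp
#' @return A `feature_extract` (see [extract_mwp()]).
#' @export
extract_mua <- function(recording, config = feature_config(), stats = NULL) {
  if (recording$fs <= 2 * max(config$mua$band))
    stop("sampling rate must exceed twice the upper band edge")
  filt <- signal::butter(config$mua$order,
                         config$mua$band / (recording$fs / 2), type = "pass")
  rec <- recording
  rec$samples <- .filter_channels(recording$samples, filt, config$zero_phase)
  binned <- bin_series(rec, "rms", config$bin_width, "mua")
  post <- .postprocess(binned, config, stats)
  .feature_extract(post$series, post$stats, binned, "mua")
}
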