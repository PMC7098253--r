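# Shared fixtures, built in code. Heavier simulated objects are cached so
# several test files can reuse one simulation.

.fixture_cache <- new.env(parent = emptyenv())

# pure-rest schedule of a given length (no cues)
rest_schedule <- function(duration = 10, task_id = "Task1") {
  cue_schedule(task_id, 0,
               events = data.frame(movement = character(0),
                                   onset_s = numeric(0),
                                   duration_s = numeric(0)),
               block_duration = duration)
}

# sinusoidal single-channel recording
sine_recording <- function(freq, duration = 1, fs = 30000, amp = 1) {
  t <- seq_len(round(duration * fs)) / fs
  raw_recording(matrix(amp * sin(2 * pi * freq * t), ncol = 1), fs = fs)
}

# small two-block Task2 session shared across correlation / feature tests
shared_session <- function() {
  if (is.null(.fixture_cache$session)) {
    params <- simulation_params(n_channels = 12, seed = 4)
    .fixture_cache$session <- simulate_session("Task2", 2, 0, params)
    .fixture_cache$geometry <- grid_geometry(12, n_cols = 4)
  }
  list(session = .fixture_cache$session, geometry = .fixture_cache$geometry)
}

# deterministic binned feature series for post-processing tests
toy_series <- function(values, bin_width = 0.1, stage = "binned",
                       kind = "mua") {
  feature_series(as.matrix(values), bin_width, kind, stage)
}

# FFT band-power oracle: fraction of spectral power of `x` (sampled at fs)
# that falls inside [f_lo, f_hi]
fft_band_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2
  freqs <- (seq_len(n) - 1) * fs / n
  half <- freqs <= fs / 2
  keep <- half & freqs >= f_lo & freqs < f_hi
  sum(p[keep]) / sum(p[half])
}
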