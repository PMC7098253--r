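# SNR summaries and the chronic signal-strength series.

test_that("snr_db matches the closed form", {
  expect_equal(snr_db(100, 10), 20)
  expect_equal(snr_db(10, 10), 0)
  expect_equal(snr_db(50, 5), 20)
  expect_equal(snr_db(1, 10), -20)
})

test_that("snr_summary recovers simulated amplitudes", {
  # a sparsely firing unit, so spike energy barely contaminates the
  # noise-RMS estimate
  sched <- rest_schedule(40)
  p <- simulation_params(n_channels = 4, baseline_rate = 4, mua_rate = 0,
                         spike_amp_uv = 150, noise_rms = 8,
                         lfp_components = list(), seed = 5)
  rec <- simulate_recording(sched, params = p)
  # zero-phase filtering preserves waveform amplitude for offline analysis
  cfg <- feature_config(zero_phase = TRUE)
  s <- snr_summary(rec, config = cfg)
  p2p_true <- 150 * mwpneuro:::.spike_template(rec$fs)$p2p
  expect_lt(abs(s$means$p2p_uv - p2p_true) / p2p_true, 0.10)
  expect_lt(abs(s$means$rms_noise_uv - 8) / 8, 0.10)
  expect_lt(abs(s$means$snr_db - snr_db(p2p_true, 8)), 1)
  expect_error(snr_summary(rec, window = 2, noise_subwindow = 0.03),
               "multiple")
})

test_that("SNR is invariant to rescaling the recording", {
  p <- simulation_params(n_channels = 2, baseline_rate = 15, mua_rate = 0,
                         spike_amp_uv = 120, noise_rms = 10,
                         lfp_components = list(), seed = 7)
  rec <- simulate_recording(rest_schedule(10), params = p)
  s1 <- snr_summary(rec)
  rec2 <- rec; rec2$samples <- rec$samples * 3
  s2 <- snr_summary(rec2)
  expect_equal(s2$means$snr_db, s1$means$snr_db, tolerance = 1e-6)
  expect_equal(s2$means$p2p_uv, 3 * s1$means$p2p_uv, tolerance = 1e-6)
})

test_that("windows without detected events carry NA and are excluded from means", {
  set.seed(12)
  x <- rnorm(10 * 30000, sd = 5)
  tpl <- mwpneuro:::.spike_template(30000)
  x[30000 + seq_along(tpl$w)] <- x[30000 + seq_along(tpl$w)] + 200 * tpl$w
  rec <- raw_recording(matrix(x, ncol = 1))
  # a strict threshold leaves the one injected spike as the only event
  cfg <- feature_config(tc = list(multiplier = -6))
  ev <- detect_threshold_crossings(rec, cfg)
  s <- snr_summary(rec, ev, cfg)
  # NA signal exactly in the windows where detection found no events
  n_in_win <- vapply(s$windows$t_start_s, function(t0)
    sum(ev$events[[1]]$time_s >= t0 & ev$events[[1]]$time_s < t0 + 2), 0)
  expect_identical(is.na(s$windows$signal_uv), n_in_win == 0)
  expect_true(any(n_in_win == 0)) # at least one empty window exists
  expect_false(is.na(s$means$snr_db)) # means skip the empty windows
})

test_that("signal strength normalizes to day one and tracks decay", {
  b <- matrix(c(1, -3, 2, -2), 2, 2)
  flat <- signal_strength(list(list(b, b), list(b, b), list(b, b)))
  expect_equal(flat$normalized, rep(1, 3))
  expect_equal(flat$strength[1], mean(abs(b)))
  # doubling all voltages on one day doubles that day's raw value
  dbl <- signal_strength(list(list(b), list(2 * b)))
  expect_equal(dbl$strength[2], 2 * dbl$strength[1])
  # normalization idempotence
  renorm <- signal_strength(list(list(matrix(flat$normalized[1])),
                                 list(matrix(flat$normalized[2]))))
  expect_equal(renorm$normalized, c(1, 1))
  expect_error(signal_strength(list()), "no days")
  expect_error(signal_strength(list(list())), "no blocks")
})

test_that("amplitude decay produces a declining strength trend", {
  sched <- rest_schedule(15)
  days <- c(0, 150, 300, 450)
  strengths <- lapply(days, function(d) {
    p <- simulation_params(n_channels = 3, baseline_rate = 20,
                           mua_rate = 60, amplitude_decay = 0.997,
                           day_index = d, lfp_components = list(), seed = 31)
    rec <- simulate_recording(sched, params = p)
    list(extract_mua(rec)$binned)
  })
  ss <- signal_strength(strengths, days = days)
  expect_equal(ss$normalized[1], 1)
  expect_lt(cor(ss$day, ss$normalized, method = "spearman"), 0)
  tr <- strength_trend(ss, k = 3)
  expect_true(all(is.finite(tr$trend)))
})
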