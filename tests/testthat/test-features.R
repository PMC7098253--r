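# Feature extractors and the shared post-processing chain.

test_that("bin_series follows the floor rule and half-open bins", {
  rec <- raw_recording(matrix(3, 30000, 2))
  expect_equal(n_bins(bin_series(rec)), 10)             # 1.0 s -> 10 bins
  rec2 <- raw_recording(matrix(3, 28500, 1))
  expect_equal(n_bins(bin_series(rec2)), 9)             # 0.95 s -> 9 bins
  expect_equal(unname(bin_series(rec)$values), matrix(3, 10, 2)) # mean of c
  expect_equal(unname(bin_series(rec, "rms")$values), matrix(3, 10, 2))
  expect_error(bin_series(raw_recording(matrix(0, 10, 1))), "one bin")
})

test_that("causal moving average has the expanding-window closed form", {
  const <- causal_moving_average(toy_series(rep(5, 30)))
  expect_equal(unname(const$values), matrix(5, 30, 1))
  imp <- toy_series(c(1, rep(0, 19)))
  sm <- causal_moving_average(imp, window = 1) # w = 10 bins
  expect_equal(sm$values[1:10, 1], 1 / (1:10))
  expect_equal(sm$values[11:20, 1], rep(0, 10))
  # causality: perturbing future bins never changes earlier output
  x <- toy_series(rnorm(50))
  y <- causal_moving_average(x)
  x2 <- x; x2$values[40:50, 1] <- 99
  y2 <- causal_moving_average(x2)
  expect_equal(y$values[1:39, ], y2$values[1:39, ])
  expect_error(causal_moving_average(toy_series(1:5), window = 0.01),
               "window")
  expect_error(causal_moving_average(y), "stage")
})

test_that("baseline subtraction demeans each 15 s window", {
  sm <- function(v) causal_moving_average(toy_series(v))
  z <- baseline_subtract(sm(rep(4, 300)))
  expect_equal(unname(z$values), matrix(0, 300, 1))
  # every window of the output has mean 0 (final partial uses its own mean)
  set.seed(3)
  z2 <- baseline_subtract(sm(rnorm(400)))
  grp <- (seq_len(400) - 1) %/% 150
  expect_true(all(abs(tapply(z2$values[, 1], grp, mean)) < 1e-9))
  # a step aligned with the windows vanishes entirely
  stepv <- toy_series(rep(c(0, 10), each = 150), stage = "smoothed")
  z3 <- baseline_subtract(stepv)
  expect_equal(unname(z3$values), matrix(0, 300, 1))
  expect_error(baseline_subtract(z3), "stage")
})

test_that("standardization follows the train-block contract", {
  alt <- toy_series(rep(c(-1, 1), 50), stage = "baselined")
  st <- fit_standardizer(alt)
  expect_equal(as.vector(st$mean), 0)
  expect_equal(as.vector(st$std), 1) # population convention
  expect_false(any(st$degenerate))

  const <- toy_series(rep(2, 10), stage = "baselined")
  stc <- fit_standardizer(const)
  expect_true(all(stc$degenerate))
  expect_equal(unname(apply_standardizer(const, stc)$values),
               matrix(0, 10, 1)) # degenerate maps to 0

  # (4 - 2) / 2 = 1
  st2 <- structure(list(mean = 2, std = 2, degenerate = FALSE,
                        source_block = NULL), class = "normalization_stats")
  got <- apply_standardizer(toy_series(4, stage = "baselined"), st2)
  expect_equal(as.vector(got$values), 1)

  # self-standardization gives mean 0, sd 1; train stats on a test block
  # generally do not
  set.seed(9)
  train <- toy_series(rnorm(200, 5, 2), stage = "baselined")
  test <- toy_series(rnorm(200, 7, 2), stage = "baselined")
  stt <- fit_standardizer(train)
  self <- apply_standardizer(train, stt)
  expect_equal(mean(self$values), 0, tolerance = 1e-12)
  expect_equal(sqrt(mean(self$values^2)), 1, tolerance = 1e-12)
  other <- apply_standardizer(test, stt)
  expect_gt(abs(mean(other$values)), 0.1)

  expect_error(fit_standardizer(toy_series(1, stage = "baselined")), "2 bins")
  bad <- structure(list(mean = c(0, 0), std = c(1, 1),
                        degenerate = c(FALSE, FALSE), source_block = NULL),
                   class = "normalization_stats")
  expect_error(apply_standardizer(train, bad), "shape")
})

test_that("combine_scales averages the selected band", {
  v <- array(0, c(4, 2, 11))
  for (k in 1:11) v[, , k] <- k
  s <- feature_series(v, feature_kind = "raw_scales", stage = "binned")
  mf <- combine_scales(s, "mf")
  expect_equal(unname(mf$values), matrix(mean(3:6), 4, 2))
  expect_identical(mf$feature_kind, "mf_mwp")
  one <- combine_scales(s, 7)
  expect_equal(unname(one$values), matrix(7, 4, 2))
  allsame <- array(2.5, c(3, 2, 11))
  s2 <- feature_series(allsame, stage = "binned")
  expect_equal(unname(combine_scales(s2, 1:11)$values), matrix(2.5, 3, 2))
  expect_error(combine_scales(s, integer(0)), "scale_set")
  expect_error(combine_scales(s, 12), "scale_set")
})

test_that("MWP extraction has the stated shape and bin budget", {
  set.seed(4)
  rec <- raw_recording(matrix(rnorm(30000 * 96), 30000, 96))
  # one 100 ms bin consumes 96 x 3000 = 288000 raw samples
  expect_equal(96 * round(0.1 * rec$fs), 288000)
  fx <- extract_mwp(rec, band = "mf")
  expect_equal(dim(fx$series$values), c(10, 96)) # 960 values per second
  expect_identical(fx$series$stage, "standardized")
  expect_identical(fx$series$feature_kind, "mf_mwp")
  # applying block-1 stats to a second block reuses them verbatim
  rec2 <- raw_recording(matrix(rnorm(30000 * 96), 30000, 96))
  fx2 <- extract_mwp(rec2, band = "mf", stats = fx$stats)
  expect_identical(fx2$stats, fx$stats)
})

test_that("threshold crossings detect injected spikes and ignore silence", {
  zero <- raw_recording(matrix(0, 30000, 1))
  expect_equal(nrow(detect_threshold_crossings(zero)$events[[1]]), 0)

  p <- simulation_params(n_channels = 2, baseline_rate = 20, mua_rate = 0,
                         spike_amp_uv = 100, noise_rms = 10,
                         lfp_components = list(), seed = 21)
  rec <- simulate_recording(rest_schedule(20), params = p)
  ev <- detect_threshold_crossings(rec)
  led <- attr(rec, "spikes")$foreground
  for (ch in 1:2) {
    hit <- vapply(led[[ch]],
                  function(t) any(abs(ev$events[[ch]]$time_s - t) <= 5e-4),
                  logical(1))
    expect_gt(mean(hit), 0.95)
  }
  # event times increase and respect the dead time
  dts <- diff(ev$events[[1]]$time_s)
  expect_true(all(dts >= 0.001))
})

test_that("TC count features conserve events and share the chain", {
  p <- simulation_params(n_channels = 2, baseline_rate = 15, mua_rate = 0,
                         spike_amp_uv = 120, noise_rms = 8,
                         lfp_components = list(), seed = 22)
  rec <- simulate_recording(rest_schedule(20), params = p)
  ev <- detect_threshold_crossings(rec)
  fx <- tc_feature_series(ev)
  expect_equal(colSums(fx$binned$values),
               vapply(ev$events, nrow, 0L),
               ignore_attr = TRUE) # counts conserved
  expect_identical(fx$series$stage, "standardized")
  # no events -> all-zero binned series
  zero_ev <- detect_threshold_crossings(raw_recording(matrix(0, 60000, 1)))
  expect_equal(unname(tc_feature_series(zero_ev)$binned$values),
               matrix(0, 20, 1))
  # doubling counts doubles the binned stage (linearity pre-standardization)
  ev2 <- ev
  ev2$events <- lapply(ev$events, function(e) rbind(e, e))
  fx2 <- tc_feature_series(ev2)
  expect_equal(fx2$binned$values, 2 * fx$binned$values)
})

test_that("LFP filter has unit DC gain and rejects the kilohertz band", {
  cfg <- feature_config()
  dc <- raw_recording(matrix(50, 60000, 1))
  fx <- extract_lfp(dc, cfg)
  expect_equal(unname(fx$binned$values[15:20, 1]), rep(50, 6),
               tolerance = 1e-3) # after settling
  # magnitude response: < 1 dB at 10 Hz, >= 60 dB down at 1 kHz
  filt <- signal::butter(3, 100 / 15000, type = "low")
  gain_at <- function(f) {
    t <- seq_len(90000) / 30000
    y <- mwpneuro:::.filter_channels(matrix(sin(2 * pi * f * t), ncol = 1),
                                     filt)
    max(abs(y[30001:90000, 1]))
  }
  expect_gt(gain_at(10), 10^(-1 / 20))
  expect_lt(gain_at(1000), 10^(-60 / 20))
})

test_that("MUA RMS recovers in-band amplitude and rejects low frequencies", {
  cfg <- feature_config()
  zero <- raw_recording(matrix(0, 30000, 1))
  expect_equal(unname(extract_mua(zero, cfg)$binned$values),
               matrix(0, 10, 1))
  s1k <- sine_recording(1000, duration = 2, amp = 6)
  fx <- extract_mua(s1k, cfg)
  # steady-state bins approach A / sqrt(2)
  expect_equal(mean(fx$binned$values[10:20, 1]), 6 / sqrt(2),
               tolerance = 0.02)
  s50 <- sine_recording(50, duration = 2, amp = 6)
  fx50 <- extract_mua(s50, cfg)
  ratio <- mean(fx50$binned$values[10:20, 1]) / mean(fx$binned$values[10:20, 1])
  expect_lt(ratio, 10^(-40 / 20))
})

test_that("post-processing commutes with channel permutation but is not idempotent", {
  set.seed(11)
  v <- matrix(rnorm(900), 300, 3)
  s <- toy_series(v)
  perm <- c(3, 1, 2)
  sm <- causal_moving_average(s)
  smp <- causal_moving_average(toy_series(v[, perm]))
  expect_equal(smp$values, sm$values[, perm])
  bl <- baseline_subtract(sm)
  blp <- baseline_subtract(smp)
  expect_equal(blp$values, bl$values[, perm])
  # smoothing twice differs from once; block-wise baseline subtraction is
  # idempotent (each aligned window is already mean-zero)
  sm2 <- causal_moving_average(toy_series(sm$values))
  expect_gt(max(abs(sm2$values - sm$values)), 1e-6)
  bl2 <- baseline_subtract(toy_series(bl$values, stage = "smoothed"))
  expect_equal(bl2$values, bl$values, tolerance = 1e-12)
})
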