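# Multilevel db4 DWT and the scale/frequency band map.

test_that("single-level DWT reproduces reference coefficients", {
  # expected values computed with an independent reference DWT
  # implementation (PyWavelets 1.9, db4) and frozen here
  x <- as.numeric(1:16)
  s <- dwt_step(x, "symmetric")
  expect_equal(s$a,
    c(7.064531462580935, 4.230736111149599, 1.4136071660758236,
      2.8360542803424087, 5.6644814050885985, 8.49290852983479,
      11.32133565458098, 14.14976277932717, 16.97709909776168,
      19.810894449193015, 22.62802339426679), tolerance = 1e-12)
  # db4 has 4 vanishing moments: interior details of a linear ramp vanish
  expect_lt(max(abs(s$d[4:8])), 1e-12)

  p <- dwt_step(x, "periodization")
  expect_equal(p$a,
    c(23.811096021889863, 5.107885730911658, 4.250267842715504,
      7.0786949674616935, 9.907122092207885, 12.735549216954073,
      15.733534770261368, 17.542371598968423), tolerance = 1e-12)
  expect_equal(p$d[c(1, 2, 7, 8)],
    c(-0.2022245058622954, -0.1695584285611042,
      3.6860450129423445, 2.3425921709734365), tolerance = 1e-12)

  # odd length, periodization (reference: PyWavelets, frozen)
  w <- dwt_step(sin(1:17 / 3), "periodization")
  expect_equal(w$a[1:3],
    c(-1.042919413119, 0.338411187335, 1.195074684031), tolerance = 1e-9)
  expect_equal(length(w$a), 9)
})

test_that("periodization-mode decomposition conserves energy", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(4096)
    wd <- wavedec(x, 11, "periodization")
    e <- sum(unlist(wd$d)^2) + sum(wd$a^2)
    expect_equal(e, sum(x^2), tolerance = 1e-10)
  }
})

test_that("scale band map follows the dyadic partition", {
  m <- scale_band_map(30000, 11)
  expect_equal(m$bands$f_high, 30000 / 2^(1:11))
  expect_equal(m$bands$f_low[1:10], 30000 / 2^(2:11))
  expect_identical(m$bands$f_low[11], 0) # deepest scale reaches 0 Hz
  # contiguous, non-overlapping, covering (0, fs/2]
  expect_equal(m$bands$f_low[1:10], m$bands$f_high[2:11])
  expect_equal(m$bands$f_high[1], 15000)
  # the three MWP sub-bands
  expect_identical(m$groups, list(lf = 7:11, mf = 3:6, hf = 1:2))
  expect_equal(floor(m$bands$f_low[6]), 234)   # mf lower edge
  expect_equal(m$bands$f_high[3], 3750)        # mf upper edge
  expect_error(scale_band_map(wavelet = "haar"), "db4")
})

test_that("wavelet_mean_abs assigns sinusoids to their dyadic band", {
  map <- scale_band_map()
  t <- seq_len(3000) / 30000
  expect_equal(wavelet_mean_abs(rep(0, 3000), map), rep(0, 11))
  # 1326 Hz is the geometric centre of scale 4 (938-1875 Hz); cross-check
  # with the FFT oracle. The peak is taken over the detail scales: the
  # pooled deepest scale is boundary-dominated under symmetric extension
  # at this depth.
  x <- sin(2 * pi * 1326 * t)
  expect_gt(fft_band_fraction(x, 30000, 30000 / 2^5, 30000 / 2^4), 0.8)
  expect_equal(which.max(wavelet_mean_abs(x, map)[1:10]), 4)
  # a 1 kHz tone sits close to the 938 Hz band edge: within db4's wide
  # transition band its energy splits between scales 4 and 5
  x1k <- sin(2 * pi * 1000 * t)
  expect_true(which.max(wavelet_mean_abs(x1k, map)[1:10]) %in% c(4, 5))
  # 20 Hz lies below 29 Hz: scales 10-11
  x20 <- sin(2 * pi * 20 * t)
  expect_gt(fft_band_fraction(x20, 30000, 0, 30000 / 2^10), 0.8)
  expect_true(which.max(wavelet_mean_abs(x20, map)) %in% c(10, 11))
  expect_error(wavelet_mean_abs(rep(0, 4), map), "filter length")
})

test_that("mean absolute coefficients are non-negative and pool the deepest scale", {
  set.seed(1)
  x <- rnorm(3000)
  v <- wavelet_mean_abs(x, scale_band_map())
  expect_true(all(v >= 0))
  # deepest scale pools detail + approximation: recompute by hand
  wd <- wavedec(x, 11, "symmetric")
  expect_equal(v[11], mean(abs(c(wd$d[[11]], wd$a))))
  expect_equal(v[3], mean(abs(wd$d[[3]])))
})
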