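test_that("Welch estimate equals a hand-enumerated periodogram average", {
  set.seed(7)
  tr <- lfp_trace(rnorm(10000) + sin(2 * pi * 8 * (1:10000) / 1000),
                  fs = 1000)
  params <- welch_params(nperseg = 2048, noverlap = 1024)
  got <- welch_psd(tr, params)

  # independent oracle: explicit segment enumeration and taper algebra
  n <- 2048L
  fs <- 1000
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / n))
  starts <- seq(1L, length(tr$samples) - n + 1L, by = n - 1024L)
  acc <- 0
  for (s in starts) {
    seg <- tr$samples[s:(s + n - 1L)]
    seg <- seg - mean(seg)
    sp <- Mod(stats::fft(seg * w))^2 / (fs * sum(w^2))
    one_sided <- sp[1:(n / 2 + 1)]
    one_sided[2:(n / 2)] <- 2 * one_sided[2:(n / 2)]
    acc <- acc + one_sided
  }
  oracle <- acc / length(starts)
  expect_equal(got$power, oracle, tolerance = 1e-10)
  expect_equal(got$freqs, (0:1024) * 1000 / 2048)
})

test_that("Welch localizes a sinusoid and conserves white-noise variance", {
  tr <- sine_trace(8, dur = 60)
  p <- welch_psd(tr)
  expect_lt(abs(p$freqs[which.max(p$power)] - 8), 0.5)

  set.seed(13)
  sigma <- 2.5
  wn <- lfp_trace(rnorm(60000, sd = sigma), fs = 1000)
  pw <- welch_psd(wn)
  total <- sum(pw$power) * diff(pw$freqs[1:2]) # Parseval
  expect_equal(total, sigma^2, tolerance = 0.1 * sigma^2)

  z <- welch_psd(lfp_trace(numeric(4096), fs = 1000))
  expect_true(all(z$power == 0))

  expect_error(welch_psd(lfp_trace(numeric(100), fs = 1000)),
               "too short")
})

test_that("whole-spectrum normalization forces unit mean over 1-120 Hz", {
  set.seed(3)
  tr <- lfp_trace(rnorm(30000), fs = 1000)
  p <- welch_psd(tr)
  np <- normalize_whole_spectrum(p)
  sel <- np$freqs >= 1 & np$freqs <= 120
  expect_equal(mean(np$power[sel]), 1, tolerance = 1e-9)
  expect_error(normalize_whole_spectrum(np), "already normalized")

  # flat spectrum maps to all ones; a single hot bin maps to the bin count
  flat <- thetagamma:::psd_result(0:120, rep(3.7, 121), welch_params())
  nf <- normalize_whole_spectrum(flat)
  expect_equal(nf$power[nf$freqs >= 1 & nf$freqs <= 120],
               rep(1, 120))
  hot <- rep(0, 121); hot[9] <- 5 # power only at 8 Hz
  nh <- normalize_whole_spectrum(thetagamma:::psd_result(0:120, hot,
                                                         welch_params()))
  expect_equal(nh$power[9], 120) # number of bins in [1,120]
})

test_that("baseline normalization divides by the baseline mean", {
  set.seed(5)
  tr <- lfp_trace(rnorm(30000), fs = 1000)
  base <- welch_psd(tr)
  self <- normalize_to_baseline(base, base)
  sel <- self$freqs >= 0 & self$freqs <= 120
  expect_equal(mean(self$power[sel]), 1, tolerance = 1e-9)

  doubled <- thetagamma:::psd_result(base$freqs, 2 * base$power, base$params)
  nd <- normalize_to_baseline(doubled, base)
  expect_equal(mean(nd$power[sel]), 2, tolerance = 1e-9)

  zero <- thetagamma:::psd_result(base$freqs, rep(0, length(base$freqs)),
                                  base$params)
  expect_error(normalize_to_baseline(base, zero), "zero")
  other <- thetagamma:::psd_result(base$freqs[-1], base$power[-1],
                                   base$params)
  expect_error(normalize_to_baseline(base, other), "mismatched")
})

test_that("normalized band powers are scale invariant", {
  set.seed(9)
  x <- rnorm(30000) + sin(2 * pi * 40 * (1:30000) / 1000)
  bp <- function(scale) {
    p <- normalize_whole_spectrum(welch_psd(lfp_trace(scale * x, fs = 1000)))
    vapply(names(band_registry()), function(b) band_power(p, b), 1)
  }
  expect_equal(bp(1), bp(37.5), tolerance = 1e-9)
})

test_that("band power follows the registry band definitions", {
  flat <- thetagamma:::psd_result(0:200, rep(1, 201), welch_params(),
                                  normalization = "whole_spectrum")
  for (b in names(band_registry())) {
    expect_equal(band_power(flat, b), 1)
  }
  # a 40 Hz line raises low_gamma but not high_gamma
  hot <- rep(1, 201); hot[41] <- 100
  p <- thetagamma:::psd_result(0:200, hot, welch_params())
  expect_gt(band_power(p, "low_gamma"), band_power(p, "high_gamma"))
  # inclusive edges: 45 Hz belongs to low gamma, 30 Hz to both gammas
  reg <- band_registry()
  expect_equal(reg$low_gamma$high, 45)
  expect_equal(reg$high_gamma$low, 55)
  narrow <- thetagamma:::psd_result(c(44, 45, 46), c(1, 10, 1),
                                    welch_params())
  expect_equal(band_power(narrow, frequency_band("edge", 45, 46)), 5.5)
  expect_error(band_power(p, frequency_band("out", 300, 400)), "no PSD bins")
  # integral reducer
  expect_equal(band_power(flat, "theta", method = "integral"), 8)
})

test_that("spectrogram tracks nonstationary content and averages to Welch", {
  fs <- 1000
  t1 <- (1:30000) / fs
  tr <- lfp_trace(c(sin(2 * pi * 8 * t1), sin(2 * pi * 40 * t1)), fs = fs)
  sp <- lfp_spectrogram(tr, step_s = 1)
  am <- apply(sp$power, 2, which.max)
  # argmax switches exactly once, at the midpoint +/- one window
  expect_equal(sort(unique(am)), sort(unique(c(am[1], am[length(am)]))))
  switch_time <- sp$times[min(which(am == am[length(am)]))]
  expect_lt(abs(switch_time - 30), 2.5)

  # stationary trace: constant argmax
  st <- sine_trace(8, dur = 20)
  sps <- lfp_spectrogram(st, step_s = 0.5)
  expect_length(unique(apply(sps$power, 2, which.max)), 1L)

  # time-averaged spectrogram is consistent with the Welch estimate: with
  # the window step equal to the Welch hop the two enumerate the same
  # segments, and with a misaligned step they still estimate the same
  # spectrum
  set.seed(11)
  wn <- lfp_trace(rnorm(60000), fs = fs)
  pw <- welch_psd(wn)
  aligned <- rowMeans(lfp_spectrogram(wn, step_s = 1.024)$power)
  expect_lt(max(abs(aligned[-1] / pw$power[-1] - 1)), 0.15)
  offgrid <- rowMeans(lfp_spectrogram(wn, step_s = 0.7)$power)
  expect_lt(stats::median(abs(offgrid[-1] / pw$power[-1] - 1)), 0.05)

  expect_error(lfp_spectrogram(st, step_s = 0), "step_s")
})

test_that("per-label PSDs average across same-label intervals", {
  sched <- generate_schedule(session_design(baseline_s = 10, n_tones = 3,
                                            tone_s = 10, iti_s = 5))
  cfg <- sim_config(sampling_rate_hz = 1000, seed = 8)
  tr <- generate_lfp(cfg, sched)$trace
  pa <- psd_by_label(tr, sched, "tone_*")
  pc <- psd_by_label(tr, sched, "tone_*", mode = "concatenate")
  expect_equal(pa$freqs, pc$freqs)
  # both see the same oscillations; estimates agree to leading order
  expect_equal(band_power(pa, "theta") / band_power(pc, "theta"), 1,
               tolerance = 0.2)
  expect_error(psd_by_label(tr, sched, "nope_*"), "no intervals")
})
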