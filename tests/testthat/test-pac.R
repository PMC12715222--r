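test_that("phase extraction recovers frequency and cosine convention", {
  fs <- 1000
  t <- seq(1 / fs, 20, by = 1 / fs)
  tr <- lfp_trace(cos(2 * pi * 8 * t), fs = fs)
  ph <- extract_phase(tr, "theta")
  n <- length(ph$phase)
  interior <- round(0.05 * n):round(0.95 * n)
  inst_freq <- diff(signal::unwrap(ph$phase[interior])) * fs / (2 * pi)
  expect_lt(abs(mean(inst_freq) - 8), 0.05)

  # cosine convention: phase ~ 0 at signal peaks
  peaks <- which(diff(sign(diff(tr$samples))) == -2) + 1L
  peaks <- peaks[peaks > 0.05 * n & peaks < 0.95 * n]
  expect_lt(max(abs(ph$phase[peaks])), 0.05)
})

test_that("white-noise theta phase is uniformly distributed", {
  set.seed(17)
  tr <- lfp_trace(rnorm(60000), fs = 1000)
  ph <- extract_phase(tr, "theta")
  counts <- table(cut(ph$phase, breaks = seq(-pi, pi, length.out = 19)))
  # chi-square uniformity on 18 bins; phases are autocorrelated, so test on
  # a thinned subsample (~1 theta cycle apart)
  thin <- ph$phase[seq(1, length(ph$phase), by = 125)]
  ct <- table(cut(thin, breaks = seq(-pi, pi, length.out = 19)))
  expect_gt(stats::chisq.test(as.vector(ct))$p.value, 0.001)
  expect_true(all(counts > 0))
})

test_that("amplitude extraction recovers known envelopes", {
  fs <- 1000
  t <- seq(1 / fs, 20, by = 1 / fs)
  tr40 <- lfp_trace(cos(2 * pi * 40 * t), fs = fs)
  am <- extract_amplitude(tr40, "low_gamma")
  n <- length(t)
  interior <- round(0.05 * n):round(0.95 * n)
  expect_equal(mean(am$amplitude[interior]), 1, tolerance = 0.02)
  expect_lt(max(abs(am$amplitude[interior] - 1)), 0.05)

  env_true <- 1 + 0.5 * cos(2 * pi * 8 * t)
  am2 <- extract_amplitude(lfp_trace(env_true * cos(2 * pi * 40 * t),
                                     fs = fs), "low_gamma")
  expect_gt(stats::cor(am2$amplitude[interior], env_true[interior]), 0.99)

  z <- extract_amplitude(lfp_trace(numeric(5000), fs = fs), "low_gamma")
  expect_equal(max(z$amplitude), 0, tolerance = 1e-12)

  expect_error(extract_amplitude(lfp_trace(rnorm(1000), fs = 100),
                                 "high_gamma"), "Nyquist")
})

test_that("modulation index is zero for uniform profiles and bounded", {
  set.seed(19)
  ph <- runif(10000, -pi, pi)
  expect_lt(modulation_index(ph, rep(2, 10000))$mi, 1e-3)
  # all amplitude in one bin approaches the upper bound
  ph1 <- runif(10000, -pi, -pi + 2 * pi / 18)
  expect_warning(mi1 <- modulation_index(ph1, rep(1, 10000)),
                 "bins empty")
  expect_gte(mi1$mi, 0)
  expect_lte(mi1$mi, 1)
  expect_error(modulation_index(numeric(0), numeric(0)), "empty")
})

test_that("modulation index is exactly amplitude-scale invariant", {
  set.seed(23)
  ph <- runif(5000, -pi, pi)
  am <- rexp(5000) * (1 + cos(ph))
  m1 <- modulation_index(ph, am)
  m2 <- modulation_index(ph, 1000 * am)
  expect_equal(m1$mi, m2$mi, tolerance = 1e-12)
})

test_that("simulated coupling is detected and its phase recovered", {
  sched <- short_schedule(60)
  mk <- function(m, seed) {
    cfg <- sim_config(sampling_rate_hz = 1000, pac_depth = m,
                      pac_preferred_phase = pi / 3, noise_sd = 5,
                      aperiodic_sd = 10, seed = seed)
    tr <- generate_lfp(cfg, sched)$trace
    modulation_index(extract_phase(tr, "theta"),
                     extract_amplitude(tr, "low_gamma"))
  }
  hi <- mk(1, 31); lo <- mk(0, 31)
  expect_gt(hi$mi, 10 * lo$mi)
  # preferred phase within 20 degrees at strong coupling
  err <- abs(Arg(exp(1i * (hi$preferred_phase - pi / 3))))
  expect_lt(err, 20 * pi / 180)
})

test_that("surrogate shifting destroys coupling", {
  sched <- short_schedule(60)
  cfg0 <- sim_config(sampling_rate_hz = 1000, pac_depth = 0, noise_sd = 5,
                     aperiodic_sd = 10, seed = 37)
  tr0 <- generate_lfp(cfg0, sched)$trace
  ph <- extract_phase(tr0, "theta")
  am <- extract_amplitude(tr0, "low_gamma")
  true_mi <- modulation_index(ph, am)$mi
  set.seed(41)
  surro <- replicate(100, {
    k <- sample(2000:58000, 1) # shift by >= several theta cycles
    shifted <- c(am$amplitude[(k + 1):length(am$amplitude)],
                 am$amplitude[1:k])
    modulation_index(ph$phase, shifted)$mi
  })
  # under no true coupling the observed MI sits inside the surrogate bulk
  expect_lt(true_mi, stats::quantile(surro, 0.95) * 3)
  expect_gt(mean(surro), 0)
})

test_that("coupling ratio compares matched PAC results", {
  set.seed(43)
  ph <- runif(8000, -pi, pi)
  am <- 1 + 0.5 * cos(ph)
  a <- modulation_index(ph, am)
  expect_equal(coupling_ratio(a, a), 1)
  b <- modulation_index(ph, am, n_bins = 12)
  expect_error(coupling_ratio(a, b), "same band pair|bin count")
  zero <- modulation_index(ph, rep(1, 8000))
  # uniform amplitude gives mi == 0 -> undefined ratio
  expect_error(coupling_ratio(a, zero), "undefined")
})

test_that("tone/ITI coupling pools same-label intervals", {
  design <- session_design(baseline_s = 20, n_tones = 6, tone_s = 20,
                           iti_s = 5)
  sched <- generate_schedule(design)
  cmap <- stats::setNames(
    ifelse(grepl("^tone_", sched$label), "tone",
           ifelse(grepl("^iti_", sched$label), "iti", "baseline")),
    sched$label)
  cfg <- sim_config(sampling_rate_hz = 1000,
                    pac_depth = c(tone = 0.8, iti = 0.2, baseline = 0.2),
                    noise_sd = 5, aperiodic_sd = 10, seed = 47)
  tr <- generate_lfp(cfg, sched, condition_map = cmap)$trace
  pac_tone <- pac_by_label(tr, sched, "tone_*")
  pac_iti <- pac_by_label(tr, sched, "iti_*")
  expect_gt(coupling_ratio(pac_tone, pac_iti), 1)
})
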