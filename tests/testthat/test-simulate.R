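test_that("schedule generation reproduces the session arithmetic", {
  sched <- generate_schedule(session_design())
  expect_equal(max(sched$end_s), 180 + 40 * 30 + 39 * 5) # 1575 s
  expect_equal(sum(grepl("^tone_", sched$label)), 40L)
  expect_equal(sum(grepl("^iti_", sched$label)), 39L)
  expect_equal(sched$label[1], "baseline")
  # contiguous, ordered, non-overlapping
  expect_equal(sched$start_s[-1], sched$end_s[-nrow(sched)])
  # sum of interval durations equals the schedule span
  expect_equal(sum(sched$end_s - sched$start_s), schedule_duration(sched))

  one <- generate_schedule(session_design(180, 1, 30, 5))
  expect_equal(nrow(one), 2L)
  expect_equal(one$label, c("baseline", "tone_1"))

  trailing <- generate_schedule(session_design(trailing_iti = TRUE))
  expect_equal(sum(grepl("^iti_", trailing$label)), 40L)

  expect_error(session_design(baseline_s = -1), "positive")
  expect_error(session_design(n_tones = 0), "n_tones")
})

test_that("seeded LFP generation is bit-reproducible", {
  sched <- generate_schedule(session_design(baseline_s = 5, n_tones = 2,
                                            tone_s = 5, iti_s = 5))
  cfg <- sim_config(sampling_rate_hz = 1000, seed = 11)
  a <- generate_lfp(cfg, sched)
  b <- generate_lfp(cfg, sched)
  expect_identical(a$trace$samples, b$trace$samples)
  cfg2 <- sim_config(sampling_rate_hz = 1000, seed = 12)
  expect_false(identical(generate_lfp(cfg2, sched)$trace$samples,
                         a$trace$samples))
  # trace duration matches the schedule span
  expect_equal(duration(a$trace), schedule_duration(sched))
})

test_that("gamma envelope is constant without coupling and phase-locked with it", {
  sched <- short_schedule(30)
  g0 <- generate_lfp(pure_gamma_config(m = 0), sched)
  env <- Mod(thetagamma:::hilbert_analytic(g0$trace$samples))
  interior <- env[1000:29000]
  expect_lt(stats::sd(interior) / mean(interior), 0.01)

  # with coupling, envelope binned by true theta phase peaks at the
  # configured preferred phase
  cfg <- sim_config(sampling_rate_hz = 1000, aperiodic_sd = 0,
                    line_noise_amp = 0, noise_sd = 0, theta_amp = 0,
                    pac_depth = 1, pac_preferred_phase = pi / 2, seed = 2,
                    gamma_bands = list(low_gamma = list(carrier_hz = 40,
                                                        base_amp = 10)))
  g1 <- generate_lfp(cfg, sched)
  env1 <- Mod(thetagamma:::hilbert_analytic(g1$trace$samples))
  t <- (seq_along(env1) - 1) / 1000
  theta_phase <- ((2 * pi * 8 * t + pi) %% (2 * pi)) - pi
  bins <- floor((theta_phase + pi) / (2 * pi) * 18) + 1
  prof <- tapply(env1, bins, mean)
  peak_bin <- as.integer(names(prof)[which.max(prof)])
  expect_equal(peak_bin, floor((pi / 2 + pi) / (2 * pi) * 18) + 1)
})

test_that("group gain scales gamma variance quadratically", {
  sched <- short_schedule(30)
  vA <- stats::var(generate_lfp(pure_gamma_config(), sched,
                                condition_map = "default")$trace$samples)
  vB <- stats::var(generate_lfp(pure_gamma_config(gain = 0.7), sched,
                                condition_map = "default")$trace$samples)
  expect_equal(vB / vA, 0.49, tolerance = 1e-3)
})

test_that("aperiodic background recovers the configured 1/f exponent", {
  sched <- short_schedule(60)
  for (alpha in c(1, 2)) {
    cfg <- sim_config(sampling_rate_hz = 1000, aperiodic_exponent = alpha,
                      aperiodic_sd = 30, theta_amp = 0, line_noise_amp = 0,
                      noise_sd = 0, gamma_bands = list(), seed = 5)
    tr <- generate_lfp(cfg, sched)$trace
    p <- welch_psd(tr)
    sel <- p$freqs >= 5 & p$freqs <= 100
    slope <- stats::coef(stats::lm(log(p$power[sel]) ~
                                     log(p$freqs[sel])))[2]
    expect_lt(abs(slope + alpha), 0.3)
  }
})

test_that("scripted motion traces reproduce target freezing fractions", {
  sched <- short_schedule(30)
  all_frozen <- generate_motion_trace(sched, 1, seed = 3)
  expect_true(all(all_frozen$motion$motion_index < 18))

  half <- generate_motion_trace(sched, 0.5, seed = 3)
  sc <- score_freezing(half$motion, freezing_params(), sched)
  expect_equal(sc$freezing_pct, 50)
  expect_equal(half$truth$achieved, 0.5)

  none <- generate_motion_trace(sched, 0, seed = 3)
  expect_equal(score_freezing(none$motion, freezing_params(),
                              sched)$freezing_pct, 0)

  # a target below the representable minimum collapses to zero
  tiny <- generate_motion_trace(sched, 0.02, seed = 3) # 18 frames < 30
  expect_equal(tiny$truth$achieved, 0)

  expect_error(generate_motion_trace(sched, 0.5, frame_rate = 0), "frame_rate")
  expect_error(generate_motion_trace(sched, 1.5), "\\[0, 1\\]")
})

test_that("cohort generation is deterministic with per-animal streams", {
  design <- session_design(baseline_s = 5, n_tones = 2, tone_s = 5, iti_s = 5)
  specs <- list(control = list(),
                attenuated = list(group_gain = list(
                  default = c(low_gamma = 0.7))))
  cfg <- sim_config(sampling_rate_hz = 1000, animal_cv = 0)
  co <- generate_cohort(5, specs, design, master_seed = 9, config = cfg)
  expect_length(co, 10L)
  expect_equal(sum(vapply(co, `[[`, "", "group") == "control"), 5L)

  co2 <- generate_cohort(5, specs, design, master_seed = 9, config = cfg)
  expect_identical(co[[3]]$trace$samples, co2[[3]]$trace$samples)
  # animals within a cohort are distinct streams
  expect_false(identical(co[[1]]$trace$samples, co[[2]]$trace$samples))

  # ground-truth bookkeeping: true low-gamma amplitude ratio equals the gain
  amp <- function(an) mean(an$truth$low_gamma_amp)
  ratio <- mean(vapply(co[6:10], amp, 1)) / mean(vapply(co[1:5], amp, 1))
  expect_equal(ratio, 0.7, tolerance = 1e-12)

  # with between-animal variability the ratio holds in expectation only
  cfg_v <- sim_config(sampling_rate_hz = 1000, animal_cv = 0.15)
  co_v <- generate_cohort(5, specs, design, master_seed = 9, config = cfg_v)
  ratio_v <- mean(vapply(co_v[6:10], amp, 1)) /
    mean(vapply(co_v[1:5], amp, 1))
  expect_equal(ratio_v, 0.7, tolerance = 0.25)
  # and per-animal amplitudes actually differ
  expect_gt(stats::sd(vapply(co_v[1:5], amp, 1)), 0)

  expect_error(generate_cohort(5, list(g = list(nope = 1)), design, 1,
                               config = cfg), "unknown sim_config fields")
  expect_error(generate_cohort(0, specs, design, 1, config = cfg),
               "n_per_group")
})

test_that("carriers above Nyquist are rejected", {
  expect_error(sim_config(sampling_rate_hz = 100,
                          gamma_bands = list(hg = list(carrier_hz = 70,
                                                       base_amp = 1))),
               "Nyquist|twice")
  expect_error(sim_config(pac_depth = 1.2), "pac_depth")
})
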