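test_that("freezing scorer applies threshold and minimum-duration rules", {
  sched <- short_schedule(30) # 900 frames at 30 fps
  p <- freezing_params()

  all_low <- motion_trace(rep(5, 900))
  expect_equal(score_freezing(all_low, p, sched)$freezing_pct, 100)

  # a 29-frame bout is below the minimum and never counts
  m <- rep(30, 900); m[100:128] <- 5
  expect_equal(score_freezing(motion_trace(m), p, sched)$freezing_pct, 0)
  # one frame longer and it counts
  m[100:129] <- 5
  expect_equal(score_freezing(motion_trace(m), p, sched)$freezing_pct,
               100 * 30 / 900)

  # bouts of 45 + 405 frames in a 900-frame trial give exactly 50%
  m2 <- rep(30, 900); m2[10:54] <- 5; m2[300:704] <- 5
  expect_equal(score_freezing(motion_trace(m2), p, sched)$freezing_pct, 50)

  # a frame exactly at threshold counts as motion (strict comparison)
  m3 <- rep(5, 900); m3[450] <- 18
  sc <- score_freezing(motion_trace(m3), p, sched)
  expect_equal(sc$freezing_pct, 100 * 899 / 900)
})

test_that("bouts spanning interval boundaries keep their full length", {
  sched <- event_schedule(data.frame(label = c("tone_1", "iti_1"),
                                     start_s = c(0, 30), end_s = c(30, 35)))
  # 20 frames at the end of the tone + 15 at the start of the ITI: one
  # 35-frame bout, attributed frame-by-frame to each interval
  m <- rep(30, 1050); m[881:915] <- 5
  sc <- score_freezing(motion_trace(m), freezing_params(), sched)
  expect_equal(sc$freezing_pct[sc$label == "tone_1"], 100 * 20 / 900)
  expect_equal(sc$freezing_pct[sc$label == "iti_1"], 100 * 15 / 150)
})

test_that("scorer matches an independent run-length reference on random traces", {
  set.seed(101)
  for (rep_i in 1:1000) {
    n <- sample(50:400, 1)
    m <- ifelse(runif(n) < 0.5, 5, 30)
    min_frames <- sample(c(5L, 10L, 30L), 1)
    got <- thetagamma:::frozen_frames(m, 18, min_frames)
    ref <- freezing_reference(m, 18, min_frames)
    if (!identical(got, ref)) {
      fail(sprintf("mismatch at replicate %d", rep_i))
    }
  }
  succeed()
})

test_that("freezing is invariant to joint scaling of motion and threshold", {
  set.seed(59)
  sched <- short_schedule(30)
  m <- runif(900, 0, 40)
  a <- score_freezing(motion_trace(m), freezing_params(18, 30), sched)
  b <- score_freezing(motion_trace(3 * m), freezing_params(54, 30), sched)
  expect_equal(a$freezing_pct, b$freezing_pct)
})

test_that("block means average five consecutive trials", {
  per_trial <- rep(c(0, 0, 0, 0, 100), 8)
  bm <- block_means(per_trial)
  expect_length(bm, 8L)
  expect_equal(unname(bm), rep(20, 8))
  expect_equal(names(bm)[1], "block_1")

  expect_equal(unname(block_means(rep(60, 40))), rep(60, 8))
  expect_warning(pb <- block_means(1:7, 5), "not divisible")
  expect_equal(unname(pb), c(3, 6.5))
})

test_that("open-field metrics follow the arena geometry", {
  # wall-hugging path: zero center time
  wall <- trajectory(t = 0:99, x = rep(0.5, 100),
                     y = seq(0.5, 49.5, length.out = 100))
  mw <- openfield_metrics(wall)
  expect_equal(mw$time_in_center_frac, 0)
  expect_equal(mw$time_in_center_frac + mw$time_in_periphery_frac, 1)

  # stationary at the arena center
  still <- trajectory(t = seq(0, 600, by = 1), x = rep(25, 601),
                      y = rep(25, 601))
  ms <- openfield_metrics(still)
  expect_equal(ms$time_in_center_frac, 1)
  expect_equal(ms$distance_cm, 0)
  expect_equal(ms$immobility_s, 600)

  # a 10 cm square traversed once
  sq <- trajectory(t = 0:4, x = c(20, 30, 30, 20, 20),
                   y = c(20, 20, 30, 30, 20))
  expect_equal(openfield_metrics(sq)$distance_cm, 40)

  # crossing count: out -> in -> out -> in = 2 entries
  zig <- trajectory(t = 0:4, x = c(2, 25, 2, 25, 25),
                    y = c(2, 25, 2, 25, 25))
  expect_equal(openfield_metrics(zig)$center_crossings, 2)

  expect_error(trajectory(t = c(0, 1, 1), x = rep(1, 3), y = rep(1, 3)),
               "strictly increasing")
  expect_error(trajectory(t = 0:1, x = c(0, 60), y = c(0, 0)), "arena")
})

test_that("preference index follows its definition", {
  expect_equal(preference_index(30, 30), 0.5)
  expect_equal(preference_index(60, 0), 1.0)
  expect_equal(preference_index(45, 15), 0.75)
  expect_error(preference_index(0, 0), "undefined")
  expect_error(preference_index(-1, 5), "non-negative")
})

test_that("motion traces round-trip through CSV", {
  m <- motion_trace(c(1.5, 20, 3.25, 18), frame_rate = 30)
  path <- withr::local_tempfile(fileext = ".csv")
  write_motion(m, path)
  back <- read_motion(path)
  expect_equal(back$motion_index, m$motion_index)
})
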