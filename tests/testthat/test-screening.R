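# Screening: motion/light traces, threshold calibration, decisions.

test_that("a static video has identically zero motion and light traces", {
  v <- fixture_genuine()
  static <- v
  static$frames <- rep(v$frames[1], 60)
  static$roi_track <- v$roi_track[v$roi_track$frame < 60, ]
  static$roi_track$frame <- rep(0:59, times = 3)
  mt <- motion_trace(static)
  expect_lt(max(mt$displacement), 1e-6)
  lt <- light_trace(rep(150, 60))
  expect_equal(video_mean(lt), 0)
})

test_that("pure translation is recovered by the optical-flow tracker", {
  v0 <- generate_video(tiny_scene(seed = 5, micro_motion_sigma = 0))
  shifted <- v0
  w <- v0$width
  for (i in seq_along(v0$frames)) {
    dx <- 2L * min(i - 1L, 8L)
    fr <- v0$frames[[1]]
    out <- fr
    out[, , ] <- 128
    out[, (dx + 1):w, ] <- fr[, 1:(w - dx), ]
    shifted$frames[[i]] <- out
  }
  mt <- motion_trace(shifted)
  expect_true(all(abs(mt$displacement[1:8] - 2) < 0.2))
})

test_that("light trace is |dY| with a closed form on ramps", {
  lt <- light_trace(seq(100, 130, by = 1))
  expect_true(all(lt$dy == 1))
  expect_equal(video_mean(lt), 1)
  expect_error(light_trace(150), class = "pg_length_error")
})

test_that("threshold calibration is mean + k sd with a degenerate floor", {
  ones <- tibble::tibble(motion_mean = rep(1, 5), light_mean = rep(1, 5))
  thr <- calibrate_thresholds(ones, k = 6)
  expect_equal(thr$motion_threshold, 1)

  zeros <- tibble::tibble(motion_mean = rep(0, 5), light_mean = rep(0, 5))
  thr0 <- calibrate_thresholds(zeros, k = 6)
  expect_equal(thr0$motion_threshold, 0.1)  # raised to the floor
  expect_equal(thr0$light_threshold, 0.1)

  spread <- tibble::tibble(motion_mean = c(1, 2, 3, 4, 5),
                           light_mean = c(1, 1, 1, 1, 6))
  thr2 <- calibrate_thresholds(spread, k = 2)
  expect_equal(thr2$motion_threshold, 3 + 2 * sd(1:5))

  expect_error(calibrate_thresholds(ones[1:4, ]),
               class = "pg_calibration_error")
})

test_that("screening decision rule: equality passes, criteria recorded", {
  thr <- calibrate_thresholds(
    tibble::tibble(motion_mean = rep(1, 5), light_mean = rep(1, 5)), k = 6)
  expect_true(screen_video(1.0, 0.5, thr)$passed)   # boundary passes
  d <- screen_video(0.5, 1.5, thr)
  expect_false(d$passed)
  expect_equal(d$criterion, "light")
  d2 <- screen_video(1.5, 1.5, thr)
  expect_equal(d2$criterion, "both")
  expect_equal(screen_video(0.2, 0.2, thr)$criterion, "none")
})

test_that("shake attacks dominate genuine micro-motion by an order of magnitude", {
  g <- fixture_genuine()
  s <- fixture_shake()
  mg <- video_mean(motion_trace(g))
  ms <- video_mean(motion_trace(s))
  expect_gt(ms, 10 * mg)
})

test_that("motion mean increases strictly with shake magnitude", {
  means <- vapply(c(2, 4, 6), function(m) {
    v <- generate_video(tiny_scene(seed = 50), attack_spec("shake", m))
    video_mean(motion_trace(v))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("light-changing attacks exceed the genuine light trace", {
  g <- fixture_genuine_signals()
  yg <- g$y[g$region == "face"]
  lg <- video_mean(light_trace(yg))
  for (kind in c("bend_h", "bend_v", "light_sweep")) {
    v <- generate_video(tiny_scene(seed = 51), attack_spec(kind))
    raw <- region_mean_signals(v)
    la <- video_mean(light_trace(raw$mean_y[raw$region == "face"]))
    expect_gt(la, 2 * lg)
  }
})

test_that("screening traces are stable under a shifted start (edge effects aside)", {
  v <- fixture_genuine()
  tail_v <- v
  keep <- 31:length(v$frames)
  tail_v$frames <- v$frames[keep]
  tr <- v$roi_track[v$roi_track$frame >= 30, ]
  tr$frame <- tr$frame - 30L
  tail_v$roi_track <- tr
  m_full <- video_mean(motion_trace(v))
  m_tail <- video_mean(motion_trace(tail_v))
  expect_lt(abs(m_full - m_tail), 0.1)
})
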