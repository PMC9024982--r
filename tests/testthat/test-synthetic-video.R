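# The synthetic-video generator: determinism, pulse injection, suite design.

test_that("identical config and seed render identical pixels", {
  sc <- tiny_scene(seed = 9)
  v1 <- generate_video(sc)
  v2 <- generate_video(sc)
  expect_identical(v1$frames, v2$frames)
  expect_identical(v1$roi_track, v2$roi_track)
})

test_that("config invariants are enforced", {
  expect_error(scene_config(heart_rate = 30), class = "pg_config_error")
  expect_error(scene_config(heart_rate = 300), class = "pg_config_error")
  expect_error(scene_config(duration = 2), class = "pg_config_error")
  expect_error(scene_config(fps = 4, heart_rate = 150),
               class = "pg_config_error")
  expect_error(attack_spec("photobomb"))
})

test_that("genuine video with no noise recovers the exact heart rate", {
  v <- generate_video(scene_config(width = 64, height = 48, duration = 10,
                                   heart_rate = 72, noise_sigma = 0,
                                   micro_motion_sigma = 0, seed = 5))
  est <- video_bpm(extract_signals(v))
  # 1.2 Hz lies on the padded FFT grid to within one fine bin
  expect_lt(abs(est$bpm - 72), 0.5)
})

test_that("zero pulse amplitude leaves no dominant spectral peak", {
  sc_on <- scene_config(width = 96, height = 72, duration = 6,
                        heart_rate = 72, seed = 6)
  sc_off <- sc_on
  sc_off$pulse_amplitude <- 0
  peak_sharpness <- function(scene) {
    v <- generate_video(scene)
    raw <- region_mean_signals(v)
    d <- raw[raw$region == "face", ]
    pulse <- chrom_pulse(d$mean_r, d$mean_g, d$mean_b, v$fps)
    spec <- pulse_spectrum(pulse, v$fps)
    band <- spec[spec$frequency >= 0.7 & spec$frequency <= 4, ]
    max(band$power) / mean(band$power)
  }
  expect_gt(peak_sharpness(sc_on), 3 * peak_sharpness(sc_off))
})

test_that("attack labels and ground-truth BPM follow the attack kind", {
  g <- fixture_genuine()
  expect_equal(g$label, 1L)
  expect_equal(g$truth_bpm, 72)
  s <- fixture_shake()
  expect_equal(s$label, 0L)
  expect_true(is.na(s$truth_bpm))  # photo attacks render no pulse
  r <- generate_video(tiny_scene(seed = 8), attack_spec("replay"))
  expect_equal(r$label, 0L)
  expect_equal(r$truth_bpm, 72)   # replay depicts a live face
})

test_that("shake attack motion matches the configured magnitude", {
  v <- generate_video(tiny_scene(seed = 43, micro_motion_sigma = 0),
                      attack_spec("shake", magnitude = 5))
  mt <- motion_trace(v)
  expect_lt(abs(video_mean(mt) - 5), 0.3)
})

test_that("benchmark suite has the 6-case design and is deterministic", {
  suite <- generate_benchmark_suite(tiny_scene(), n_per_class = 3, seed = 7)
  expect_equal(nrow(suite), 18)                      # 3 classes x 2 profiles x 3
  expect_equal(sum(suite$label == 1), 6)             # genuine class is real
  expect_equal(length(unique(suite$video_id)), 18)
  expect_setequal(unique(suite$attack_kind),
                  c("genuine", "cutout_cheek_chin", "replay"))
  expect_setequal(unique(suite$profile), c("A", "B"))
  expect_true(all(suite$truth_bpm >= 48 & suite$truth_bpm <= 120))

  suite2 <- generate_benchmark_suite(tiny_scene(), n_per_class = 3, seed = 7)
  expect_identical(suite$seed, suite2$seed)
  v1 <- suite_video(suite, suite$video_id[4])
  v2 <- suite_video(suite2, suite$video_id[4])
  expect_identical(v1$frames, v2$frames)
})

test_that("cut-out attacks carry the pulse only in the live sub-regions", {
  sc <- scene_config(width = 96, height = 72, duration = 5, heart_rate = 90,
                     noise_sigma = 1, seed = 31)
  v <- generate_video(sc, attack_spec("cutout_cheek_chin"))
  raw <- region_mean_signals(v)
  amp_at <- function(region, f) {
    d <- raw[raw$region == region, ]
    g <- d$mean_g - mean(d$mean_g)
    n <- length(g)
    tt <- (seq_len(n) - 1) / v$fps
    sqrt(sum(g * sin(2 * pi * f * tt))^2 + sum(g * cos(2 * pi * f * tt))^2) / n
  }
  f <- 1.5  # 90 bpm
  expect_gt(amp_at("face", f), 3 * amp_at("eyes", f))
})
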