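# Clip segmentation, feature assembly and video-level splitting.

# A signal tibble built directly, with metadata attributes like
# extract_signals() produces.
make_signals <- function(T, video_id = "v1", label = 1L, seed = 1) {
  withr::with_seed(seed, {
    d <- dplyr::bind_rows(lapply(c("face", "nose", "eyes"), function(r) {
      tibble::tibble(frame = seq_len(T) - 1L, region = r,
                     rppg = rnorm(T), bpm = runif(T, 60, 90),
                     y = 150 + rnorm(T), cb = 150 + rnorm(T),
                     cr = 100 + rnorm(T))
    }))
    attr(d, "video_id") <- video_id
    attr(d, "label") <- label
    attr(d, "attack_kind") <- if (label == 1) "genuine" else "replay"
    attr(d, "profile") <- "A"
    attr(d, "fps") <- 30
    class(d) <- c("pg_signals", class(d))
    d
  })
}

test_that("clip count follows the sliding-window formula (enumeration oracle)", {
  # oracle: enumerate admissible starts directly
  oracle_count <- function(T, len = 90, stride = 10) {
    if (T < len) return(0L)
    length(seq(0L, T - len, by = stride))
  }
  formula_count <- function(T, len = 90, stride = 10) {
    if (T < len) return(0L)
    as.integer(floor((T - len) / stride) + 1L)
  }
  for (T in 0:500) expect_identical(oracle_count(T), formula_count(T))

  # the implementation agrees on representative lengths
  for (T in c(90, 91, 99, 100, 101, 150, 289, 290)) {
    clips <- segment_clips(make_signals(T))
    expect_equal(nrow(clips), oracle_count(T))
  }
  expect_equal(nrow(segment_clips(make_signals(2100))), 202)
  expect_warning(out <- segment_clips(make_signals(89)))
  expect_equal(nrow(out), 0)
  expect_error(segment_clips(make_signals(89), on_short = "error"),
               class = "pg_length_error")
})

test_that("clip tensors are 90 x 15, standardized, in fixed channel order", {
  sig <- make_signals(120)
  m <- assemble_features(sig, start = 10)
  expect_equal(dim(m), c(90, 15))
  expect_equal(colnames(m)[1:6],
               c("face_rppg", "face_bpm", "face_y", "face_cb", "face_cr",
                 "nose_rppg"))
  expect_lt(max(abs(colMeans(m))), 1e-9)
  expect_lt(max(abs(apply(m, 2, var) - 1)), 1e-6)

  # face-only configuration
  m5 <- assemble_features(sig, regions = "face")
  expect_equal(dim(m5), c(90, 5))

  # constant channels standardize to zero columns
  sig2 <- make_signals(90)
  sig2$y <- 150
  m2 <- assemble_features(sig2)
  expect_true(all(m2[, "face_y"] == 0))

  expect_error(assemble_features(sig, start = 100), class = "pg_assembly_error")
})

test_that("video-level split is stratified, leakage-free and deterministic", {
  clips <- dplyr::bind_rows(lapply(1:12, function(i) {
    segment_clips(make_signals(120, video_id = sprintf("v%02d", i),
                               label = as.integer(i <= 6), seed = i))
  }))
  class(clips) <- c("pg_clipset", class(clips))
  sp <- split_by_video(clips, test_fraction = 1 / 6, seed = 3)
  vids <- dplyr::distinct(sp[, c("video_id", "attack_kind", "split")])
  expect_equal(sum(vids$split == "test"), 2)  # 1 per 6-video stratum
  expect_length(intersect(sp$video_id[sp$split == "train"],
                          sp$video_id[sp$split == "test"]), 0)
  sp2 <- split_by_video(clips, test_fraction = 1 / 6, seed = 3)
  expect_identical(sp$split, sp2$split)

  one <- clips[clips$video_id == "v01", ]
  class(one) <- class(clips)
  expect_error(split_by_video(one), class = "pg_split_error")
})

test_that("clip sets round-trip through the CSV + manifest serialization", {
  clips <- split_by_video(local({
    d <- dplyr::bind_rows(lapply(1:4, function(i)
      segment_clips(make_signals(100, video_id = paste0("v", i),
                                 label = i %% 2L, seed = i))))
    class(d) <- c("pg_clipset", class(d))
    attr(d, "channels") <- pulsegate:::clip_channel_names()
    attr(d, "clip_len") <- 90L
    d
  }), seed = 1)
  dir <- withr::local_tempdir()
  write_clipset(clips, dir)
  back <- read_clipset(dir)
  expect_equal(nrow(back), nrow(clips))
  expect_equal(attr(back, "channels"), attr(clips, "channels"))
  expect_equal(back$label, clips$label)
  expect_equal(back$split, clips$split)
  expect_equal(back$tensor[[3]], clips$tensor[[3]], tolerance = 1e-12)
})

test_that("region subsetting slices the stored channels", {
  clips <- segment_clips(make_signals(100))
  face <- subset_regions(clips, "face")
  expect_equal(attr(face, "channels"), pulsegate:::clip_channel_names("face"))
  expect_equal(dim(face$tensor[[1]]), c(90, 5))
  expect_equal(face$tensor[[1]][, "face_rppg"],
               clips$tensor[[1]][, "face_rppg"])
})
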