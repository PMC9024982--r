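# Clip tensors: 90-frame windows (stride 10) of the 15 aligned channels
# (3 regions x [rPPG, BPM trace, Y', Cb, Cr]), standardized per clip.

.signal_channels <- c("rppg", "bpm", "y", "cb", "cr")

clip_channel_names <- function(regions = c("face", "nose", "eyes")) {
  as.vector(vapply(regions, function(r) paste(r, .signal_channels, sep = "_"),
                   character(5)))
}

#' Assemble one standardized clip tensor
#'
#' Builds the `clip_len x (5 * n_regions)` feature matrix for one window:
#' channels are stacked region-major in the fixed order face, nose, eyes x
#' (rPPG, BPM, Y', Cb, Cr) and standardized per clip to zero mean and unit
#' variance (constant channels map to zeros).
#'
#' @param signals A `pg_signals` tibble covering the window.
#' @param start 0-based start frame of the window.
#' @param clip_len Window length in frames (default 90).
#' @param regions Regions to include, in order; `"face"` alone gives the
#'   face-only 90 x 5 configuration.
#' @return A numeric `clip_len x (5 * length(regions))` matrix with channel
#'   names as column names.
#' @export
assemble_features <- function(signals, start = 0L, clip_len = 90L,
                              regions = c("face", "nose", "eyes")) {
  frames <- start + seq_len(clip_len) - 1L
  cols <- lapply(regions, function(r) {
    d <- signals[signals$region == r & signals$frame %in% frames, ]
    if (nrow(d) != clip_len) {
      stop_pg(sprintf(
        "Region '%s' does not cover frames [%d, %d].", r, start,
        start + clip_len - 1L), "pg_assembly_error")
    }
    d <- d[order(d$frame), ]
    as.matrix(d[, .signal_channels])
  })
  m <- do.call(cbind, cols)
  colnames(m) <- clip_channel_names(regions)
  # per-clip channel standardization
  mu <- colMeans(m)
  sdv <- apply(m, 2, sd)
  m <- sweep(m, 2, mu)
  keep <- sdv > 1e-12
  m[, keep] <- sweep(m[, keep, drop = FALSE], 2, sdv[keep], "/")
  m[, !keep] <- 0
  m
}

#' Segment a signal set into sliding-window clips
#'
#' Windows start at 0, `stride`, `2 * stride`, ...; for a series of length
#' `T >= clip_len` the clip count is `floor((T - clip_len) / stride) + 1`.
#'
#' @param signals A `pg_signals` tibble for one video.
#' @param clip_len Clip length in frames (default 90).
#' @param stride Sliding-window stride in frames (default 10).
#' @param regions Regions to include (see [assemble_features()]).
#' @param on_short `"warn"` (default) returns zero clips with a warning when
#'   the video is shorter than `clip_len`; `"error"` aborts.
#' @return A tibble of class `pg_clipset`: `video_id`, `label`,
#'   `attack_kind`, `profile`, `start`, `tensor` (list of matrices).
#' @export
segment_clips <- function(signals, clip_len = 90L, stride = 10L,
                          regions = c("face", "nose", "eyes"),
                          on_short = c("warn", "error")) {
  on_short <- match.arg(on_short)
  n <- max(signals$frame) + 1L
  if (n < clip_len) {
    msg <- sprintf("Series of %d frames yields no %d-frame clips.", n, clip_len)
    if (on_short == "error") stop_pg(msg, "pg_length_error")
    warn(msg)
    starts <- integer(0)
  } else {
    starts <- seq(0L, n - clip_len, by = stride)
  }
  out <- tibble(
    video_id = rep(attr(signals, "video_id") %||% NA_character_,
                   length(starts)),
    label = rep(attr(signals, "label") %||% NA_integer_, length(starts)),
    attack_kind = rep(attr(signals, "attack_kind") %||% NA_character_,
                      length(starts)),
    profile = rep(attr(signals, "profile") %||% NA_character_,
                  length(starts)),
    start = starts,
    tensor = lapply(starts, function(s) {
      assemble_features(signals, s, clip_len, regions)
    })
  )
  class(out) <- c("pg_clipset", class(out))
  attr(out, "channels") <- clip_channel_names(regions)
  attr(out, "clip_len") <- clip_len
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run extraction and clip segmentation over a benchmark suite
#'
#' Realizes each suite video in turn (so only one video's frames are in
#' memory at a time), extracts its signal set, segments it into clips and
#' binds the results.
#'
#' @param suite A suite tibble from [generate_benchmark_suite()].
#' @param clip_len,stride,regions Passed to [segment_clips()].
#' @param verbose Print one line per video.
#' @return A `pg_clipset` tibble covering the whole suite.
#' @export
suite_clips <- function(suite, clip_len = 90L, stride = 10L,
                        regions = c("face", "nose", "eyes"),
                        verbose = FALSE) {
  sets <- lapply(seq_len(nrow(suite)), function(i) {
    v <- suite_video(suite, suite$video_id[i])
    if (verbose) message("clips: ", suite$video_id[i])
    sig <- extract_signals(v)
    segment_clips(sig, clip_len = clip_len, stride = stride,
                  regions = regions)
  })
  out <- bind_rows(sets)
  class(out) <- c("pg_clipset", class(out))
  attr(out, "channels") <- clip_channel_names(regions)
  attr(out, "clip_len") <- clip_len
  out
}

#' Leakage-free video-level train/test split
#'
#' Splits at the video level (all clips of a video share its split),
#' stratified by attack kind and device profile; deterministic given the
#' seed.
#'
#' @param clips A `pg_clipset`.
#' @param test_fraction Fraction of videos per stratum held out (default
#'   1/6, the 5:1 design).
#' @param seed Integer seed.
#' @return The clipset with a `split` column (`"train"` / `"test"`).
#' @export
split_by_video <- function(clips, test_fraction = 1 / 6, seed = 1L) {
  vids <- distinct(as_tibble(clips)[, c("video_id", "attack_kind", "profile")])
  strata <- split(vids, paste(vids$attack_kind, vids$profile))
  counts <- vapply(strata, nrow, integer(1))
  if (any(counts < 2)) {
    stop_pg("Every attack-kind x profile stratum needs at least 2 videos.",
            "pg_split_error")
  }
  test_ids <- with_local_seed(seed, {
    unlist(lapply(strata, function(s) {
      n_test <- max(1L, round(nrow(s) * test_fraction))
      sample(s$video_id, n_test)
    }), use.names = FALSE)
  })
  out <- mutate(clips, split = ifelse(.data$video_id %in% test_ids,
                                      "test", "train"))
  class(out) <- class(clips)
  attr(out, "channels") <- attr(clips, "channels")
  attr(out, "clip_len") <- attr(clips, "clip_len")
  out
}

#' Serialize a clip set to a directory of CSV matrices with a JSON manifest
#'
#' @param clips A `pg_clipset`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_clipset <- function(clips, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("clip_%06d.csv", seq_len(nrow(clips)))
  for (i in seq_len(nrow(clips))) {
    utils::write.csv(clips$tensor[[i]], file.path(dir, files[i]),
                     row.names = FALSE)
  }
  manifest <- list(
    channels = attr(clips, "channels"),
    clip_len = attr(clips, "clip_len"),
    clips = data.frame(
      file = files, video_id = clips$video_id, label = clips$label,
      attack_kind = clips$attack_kind, profile = clips$profile,
      start = clips$start,
      split = if ("split" %in% names(clips)) clips$split else NA_character_
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a clip set written by [write_clipset()]
#'
#' @param dir Directory containing `manifest.json` and the per-clip CSVs.
#' @return A `pg_clipset`.
#' @export
read_clipset <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) {
    stop_pg("No manifest.json found.", "pg_io_error")
  }
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  info <- man$clips
  tensors <- lapply(info$file, function(f) {
    as.matrix(utils::read.csv(file.path(dir, f), check.names = FALSE))
  })
  out <- tibble(
    video_id = info$video_id, label = info$label,
    attack_kind = info$attack_kind, profile = info$profile,
    start = info$start, tensor = tensors
  )
  if (!all(is.na(info$split))) out$split <- info$split
  class(out) <- c("pg_clipset", class(out))
  attr(out, "channels") <- man$channels
  attr(out, "clip_len") <- man$clip_len
  out
}
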