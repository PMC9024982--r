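# Signal-set assembly: the five channels (rPPG, BPM trace, Y', Cb, Cr) for
# each of the three face regions, aligned frame-by-frame.

#' Extract the five signal channels for each region
#'
#' Runs the full signal chain on one video: per-region skin-mean color traces
#' ([region_mean_signals()]), CHROM pulse extraction, smoothness-priors
#' detrending, band-pass filtering, and a sliding-window BPM trace. The result
#' is the per-frame signal set the clip tensors are built from.
#'
#' @param video A `pg_video`.
#' @param track Optional region track; defaults to the video's own.
#' @param lambda Detrending smoothness parameter.
#' @param cfg Band-pass configuration.
#' @param bpm_window,bpm_stride Sliding-window parameters for the BPM trace.
#' @return A tibble (`frame`, `region`, `rppg`, `bpm`, `y`, `cb`, `cr`) with
#'   metadata attributes `fps`, `video_id`, `label`, `attack_kind`,
#'   `profile`, `truth_bpm`.
#' @export
extract_signals <- function(video, track = NULL, lambda = 300,
                            cfg = bandpass_config(), bpm_window = 90L,
                            bpm_stride = 3L) {
  raw <- region_mean_signals(video, track)
  fps <- attr(raw, "fps")
  out <- lapply(split(raw, raw$region), function(d) {
    pulse <- chrom_pulse(d$mean_r, d$mean_g, d$mean_b, fps, cfg = cfg)
    pulse <- detrend_normalize(pulse, lambda = lambda)
    pulse <- bandpass(pulse, fps, cfg)
    tibble(
      frame = d$frame, region = as.character(d$region[1]),
      rppg = pulse,
      bpm = bpm_trace(pulse, fps, window = bpm_window, stride = bpm_stride),
      y = d$mean_y, cb = d$mean_cb, cr = d$mean_cr
    )
  })
  res <- bind_rows(out)
  res$region <- factor(res$region, levels = c("face", "nose", "eyes"))
  res <- arrange(res, .data$region, .data$frame)
  attr(res, "fps") <- fps
  attr(res, "video_id") <- if (!is.null(video$video_id)) video$video_id else NA_character_
  attr(res, "label") <- video$label
  attr(res, "attack_kind") <- video$attack_kind
  attr(res, "profile") <- video$profile
  attr(res, "truth_bpm") <- video$truth_bpm
  class(res) <- c("pg_signals", class(res))
  res
}

#' Estimate the video-level heart rate from extracted signals
#'
#' @param signals A `pg_signals` tibble from [extract_signals()].
#' @param region Which region's pulse to use (default the whole face).
#' @return A `bpm_estimate`.
#' @export
video_bpm <- function(signals, region = "face") {
  d <- signals[signals$region == region, ]
  estimate_bpm(d$rppg, attr(signals, "fps"))
}

#' Export a signal set as CSV
#'
#' One row per frame, columns per channel per region.
#'
#' @param signals A `pg_signals` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_signals_csv <- function(signals, path) {
  wide <- tidyr::pivot_wider(
    as_tibble(signals),
    names_from = "region",
    values_from = c("rppg", "bpm", "y", "cb", "cr"),
    names_glue = "{region}_{.value}"
  )
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
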