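# Video-integrity screening: reject videos with gross motion or light changes
# before they ever reach the classifier.

#' Motion trace from sparse optical flow
#'
#' Places a 3x3 grid of points at 25/50/75% of the face box on the first
#' frame and tracks them frame-to-frame with pyramidal Lucas-Kanade flow. The
#' per-frame motion value is the mean Euclidean displacement over the tracked
#' points; points that are lost are dropped from the mean (an error is raised
#' only if all are lost).
#'
#' @param video A `pg_video`.
#' @param face_track Optional face track; defaults to the video's own.
#' @param win LK window size in pixels (odd).
#' @param levels Pyramid levels.
#' @return A tibble of class `motion_trace` (`frame` = 0-based transition
#'   index, `displacement` in px/frame) with attribute `video_mean`.
#' @export
motion_trace <- function(video, face_track = NULL, win = 15L, levels = 3L) {
  stopifnot(inherits(video, "pg_video"))
  n <- length(video$frames)
  if (n < 2) stop_pg("Need at least 2 frames.", "pg_length_error")
  if (is.null(face_track)) {
    if (is.null(video$roi_track)) {
      stop_pg("No face track available.", "pg_roi_error")
    }
    face_track <- video$roi_track[video$roi_track$region == "face", ]
  }
  b <- face_track[face_track$frame == min(face_track$frame), ][1, ]
  fr <- c(0.25, 0.50, 0.75)
  pts <- as.matrix(expand.grid(x = b$x + fr * b$w, y = b$y + fr * b$h))

  pyr <- build_pyramid(to_gray(video$frames[[1]]), levels)
  disp <- numeric(n - 1)
  for (t in 2:n) {
    grads <- lapply(pyr, central_gradients)
    pyr_next <- build_pyramid(to_gray(video$frames[[t]]), levels)
    new_pts <- lk_track_points(pyr, grads, pyr_next, pts, win = win)
    active <- !is.na(new_pts[, 1]) & !is.na(pts[, 1])
    if (!any(active)) {
      stop_pg(sprintf("All optical-flow points lost at frame %d.", t - 1L),
              "pg_tracking_error")
    }
    d <- sqrt(rowSums((new_pts[active, , drop = FALSE] -
                         pts[active, , drop = FALSE])^2))
    disp[t - 1] <- mean(d)
    pts <- new_pts
    pyr <- pyr_next
  }
  out <- tibble(frame = seq_len(n - 1) - 1L, displacement = disp)
  class(out) <- c("motion_trace", class(out))
  attr(out, "video_mean") <- mean(disp)
  out
}

#' Light trace from the skin-region luminance
#'
#' The per-frame light value is the absolute change `|Y_t - Y_{t-1}|` of the
#' skin-masked mean luminance.
#'
#' @param y Numeric per-frame mean Y' series (e.g. the face `y` channel of
#'   [extract_signals()] or [region_mean_signals()]).
#' @return A tibble of class `light_trace` (`frame`, `dy`) with attribute
#'   `video_mean`.
#' @export
light_trace <- function(y) {
  if (length(y) < 2) stop_pg("Need at least 2 samples.", "pg_length_error")
  dy <- abs(diff(y))
  out <- tibble(frame = seq_along(dy) - 1L, dy = dy)
  class(out) <- c("light_trace", class(out))
  attr(out, "video_mean") <- mean(dy)
  out
}

#' Video-level mean of a screening trace
#' @param trace A `motion_trace` or `light_trace`.
#' @return The mean per-frame value.
#' @export
video_mean <- function(trace) attr(trace, "video_mean")

#' Calibrate screening thresholds on a genuine population
#'
#' The decision rule is `threshold = mean + k * sd` of the genuine videos'
#' per-video mean motion and light values. Degenerate (zero) thresholds are
#' raised to a configured floor.
#'
#' @param genuine_stats Tibble with one row per genuine video and columns
#'   `motion_mean`, `light_mean`. At least 5 videos are required.
#' @param k Margin in genuine standard deviations (default 6).
#' @param motion_floor,light_floor Lower bounds for the thresholds.
#' @return A list of class `screening_thresholds`.
#' @export
calibrate_thresholds <- function(genuine_stats, k = 6,
                                 motion_floor = 0.1, light_floor = 0.1) {
  req <- c("motion_mean", "light_mean")
  if (!all(req %in% names(genuine_stats))) {
    stop_pg("`genuine_stats` needs columns motion_mean and light_mean.",
            "pg_calibration_error")
  }
  if (nrow(genuine_stats) < 5) {
    stop_pg("Need at least 5 genuine videos to calibrate.",
            "pg_calibration_error")
  }
  thr <- function(v, floor) {
    s <- sd(v)
    if (!is.finite(s)) s <- 0
    max(mean(v) + k * s, floor)
  }
  structure(list(
    motion_threshold = thr(genuine_stats$motion_mean, motion_floor),
    light_threshold = thr(genuine_stats$light_mean, light_floor),
    k = k, n_genuine = nrow(genuine_stats)
  ), class = "screening_thresholds")
}

#' Screen a video's traces against calibrated thresholds
#'
#' A video fails when its mean motion exceeds the motion threshold OR its
#' mean light change exceeds the light threshold; equality passes.
#'
#' @param motion A `motion_trace` (or its video mean).
#' @param light A `light_trace` (or its video mean).
#' @param thresholds A `screening_thresholds`.
#' @return A list of class `screening_decision`: `passed`, `criterion`
#'   (`"none"`, `"motion"`, `"light"` or `"both"`), the two means and the
#'   thresholds.
#' @export
screen_video <- function(motion, light, thresholds) {
  stopifnot(inherits(thresholds, "screening_thresholds"))
  m <- if (is.numeric(motion)) motion else video_mean(motion)
  l <- if (is.numeric(light)) light else video_mean(light)
  fail_m <- m > thresholds$motion_threshold
  fail_l <- l > thresholds$light_threshold
  criterion <- if (fail_m && fail_l) "both" else if (fail_m) "motion" else
    if (fail_l) "light" else "none"
  structure(list(
    passed = criterion == "none", criterion = criterion,
    motion_mean = m, light_mean = l, thresholds = thresholds
  ), class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf(
    "<screening_decision> %s (criterion: %s) motion=%.3f/%.3f light=%.3f/%.3f\n",
    if (x$passed) "PASS" else "FAIL", x$criterion,
    x$motion_mean, x$thresholds$motion_threshold,
    x$light_mean, x$thresholds$light_threshold), ...)
  invisible(x)
}

#' Compute both screening traces for a video
#'
#' Convenience wrapper: optical-flow motion trace plus the light trace of the
#' face region's skin-mean luminance.
#'
#' @param video A `pg_video`.
#' @param track Optional region track; defaults to the video's own.
#' @return A list with `motion` (a `motion_trace`), `light` (a
#'   `light_trace`), `motion_mean`, `light_mean`.
#' @export
screening_traces <- function(video, track = NULL) {
  mt <- motion_trace(video, face_track = if (is.null(track)) NULL else
    track[track$region == "face", ])
  raw <- region_mean_signals(video, track)
  yface <- raw$mean_y[raw$region == "face"]
  lt <- light_trace(yface)
  list(motion = mt, light = lt,
       motion_mean = video_mean(mt), light_mean = video_mean(lt))
}
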