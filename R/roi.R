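# Region-of-interest handling: the whole face plus the nose and eye areas.
# Detection and tracking are injected contracts (the pipeline treats them as
# components, not contributions); defaults use the skin mask itself.

#' Derive nose and eye boxes from face boxes
#'
#' The sub-region convention is geometric and landmark-free: the eye area
#' spans face rows from 20% to 40% of the face height, the nose area rows
#' from 40% to 65%; both are 60% of the face width, horizontally centered.
#'
#' @param face_boxes A tibble of per-frame face boxes (`frame`, `x`, `y`,
#'   `w`, `h`).
#' @return A tibble with the derived `nose` and `eyes` rows.
#' @export
derive_subregions <- function(face_boxes) {
  sub <- function(region, top, bottom) {
    tibble(
      frame = face_boxes$frame, region = region,
      x = as.integer(round(face_boxes$x + 0.2 * face_boxes$w)),
      y = as.integer(round(face_boxes$y + top * face_boxes$h)),
      w = as.integer(round(0.6 * face_boxes$w)),
      h = as.integer(round((bottom - top) * face_boxes$h))
    )
  }
  bind_rows(sub("eyes", 0.20, 0.40), sub("nose", 0.40, 0.65))
}

validate_roi_track <- function(track, width, height, n_frames) {
  req <- c("frame", "region", "x", "y", "w", "h")
  if (!all(req %in% names(track))) {
    stop_pg("Region track must have columns frame, region, x, y, w, h.",
            "pg_roi_error")
  }
  counts <- table(track$region)
  if (!all(c("face", "nose", "eyes") %in% names(counts)) ||
      any(counts[c("face", "nose", "eyes")] != n_frames)) {
    stop_pg("Track must cover face, nose and eyes on every frame.",
            "pg_roi_error")
  }
  if (any(track$w <= 0) || any(track$h <= 0)) {
    stop_pg("Region boxes must have positive size.", "pg_roi_error")
  }
  if (any(track$x < 0) || any(track$y < 0) ||
      any(track$x + track$w > width) || any(track$y + track$h > height)) {
    stop_pg("Region boxes must lie fully inside the frame.", "pg_roi_error")
  }
  # containment of sub-regions in the face box, per frame
  wide <- split(track, track$region)
  for (r in c("nose", "eyes")) {
    s <- wide[[r]][order(wide[[r]]$frame), ]
    f <- wide$face[order(wide$face$frame), ]
    if (any(s$x < f$x | s$y < f$y |
            s$x + s$w > f$x + f$w | s$y + s$h > f$y + f$h)) {
      stop_pg(sprintf("'%s' boxes are not contained in the face box.", r),
              "pg_roi_error")
    }
  }
  invisible(track)
}

# Default detector contract: bounding box of the skin mask on one frame.
skin_box_detector <- function(frame) {
  ycc <- rgb_to_ycbcr(frame / 255)
  msk <- skin_mask(ycc)$mask
  if (!any(msk)) return(NULL)
  rows <- range(which(rowSums(msk) > 0))
  cols <- range(which(colSums(msk) > 0))
  list(x = cols[1] - 1L, y = rows[1] - 1L,
       w = cols[2] - cols[1] + 1L, h = rows[2] - rows[1] + 1L)
}

# Default tracker contract: follow the skin-mask centroid, keeping the box
# size fixed from the initial detection.
skin_centroid_tracker <- function(video, box0) {
  n <- length(video$frames)
  centroid <- function(frame) {
    msk <- skin_mask(rgb_to_ycbcr(frame / 255))$mask
    if (!any(msk)) return(NULL)
    idx <- which(msk, arr.ind = TRUE)
    c(mean(idx[, 2]), mean(idx[, 1]))  # (x, y), 1-based centers
  }
  c0 <- centroid(video$frames[[1]])
  if (is.null(c0)) return(NULL)
  boxes <- vector("list", n)
  for (t in seq_len(n)) {
    ct <- centroid(video$frames[[t]])
    if (is.null(ct)) {
      stop_pg(sprintf("Track lost at frame %d (no skin pixels).", t - 1L),
              "pg_tracking_error")
    }
    dx <- ct[1] - c0[1]
    dy <- ct[2] - c0[2]
    boxes[[t]] <- tibble(
      frame = t - 1L, region = "face",
      x = as.integer(clamp(round(box0$x + dx), 0, video$width - box0$w)),
      y = as.integer(clamp(round(box0$y + dy), 0, video$height - box0$h)),
      w = as.integer(box0$w), h = as.integer(box0$h)
    )
  }
  bind_rows(boxes)
}

#' Track the three regions of interest through a video
#'
#' The face is detected once on the first frame, then followed frame by frame
#' by the tracker; nose and eye boxes are derived geometrically from each face
#' box (see [derive_subregions()]). Both the detector and the tracker are
#' injectable contracts so that established implementations (a DNN face
#' detector, a kernelized correlation filter tracker) can be plugged in; the
#' defaults locate and follow the skin mask, which is adequate for the flat
#' synthetic faces. When `fixture` is supplied (e.g. the generator's
#' ground-truth track), it is validated and passed through unchanged.
#'
#' @param video A `pg_video`.
#' @param detector Function `frame -> list(x, y, w, h)` (0-based box) or
#'   `NULL` on failure.
#' @param tracker Function `(video, box0) -> tibble` of per-frame face boxes.
#' @param fixture Optional precomputed track to validate and return.
#' @return A region track tibble (`frame`, `region`, `x`, `y`, `w`, `h`).
#' @export
track_rois <- function(video, detector = skin_box_detector,
                       tracker = skin_centroid_tracker, fixture = NULL) {
  stopifnot(inherits(video, "pg_video"))
  n <- length(video$frames)
  if (!is.null(fixture)) {
    validate_roi_track(fixture, video$width, video$height, n)
    return(fixture)
  }
  box0 <- detector(video$frames[[1]])
  if (is.null(box0)) {
    stop_pg("No face detected on the first frame.", "pg_detection_error")
  }
  face <- tracker(video, box0)
  if (is.null(face)) {
    stop_pg("Tracker failed to produce a face track.", "pg_tracking_error")
  }
  track <- bind_rows(face, derive_subregions(face))
  validate_roi_track(track, video$width, video$height, n)
  track
}
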