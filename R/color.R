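# RGB -> YCbCr conversion, static skin masking, and per-region mean color
# signals. These are the raw channels everything downstream consumes.

# ITU-R BT.601 full-to-studio-swing transform, R'G'B' in [0, 1].
# Coefficient magnitudes follow the usual printed form; the chroma rows carry
# the standard signs so that each row sums to zero and chroma stays centered
# at 128 (see the methods vignette for the sign-convention note).
.ycbcr_matrix <- matrix(
  c(65.481, 128.553, 24.966,
    -37.797, -74.203, 112.0,
    112.0, -93.786, -18.214),
  nrow = 3, byrow = TRUE,
  dimnames = list(c("y", "cb", "cr"), c("r", "g", "b"))
)
.ycbcr_offset <- c(y = 16, cb = 128, cr = 128)

#' Convert normalized RGB to YCbCr
#'
#' Applies the BT.601 full-to-studio-swing transform: for R', G', B' in
#' \[0, 1\], `Y' = 16 + 65.481 R' + 128.553 G' + 24.966 B'`, with the blue- and
#' red-difference chroma centered at 128. Gray inputs map to `(16 + 219 x,
#' 128, 128)`.
#'
#' @param rgb A numeric object holding normalized RGB values in \[0, 1\]:
#'   either an `h x w x 3` array or an `n x 3` matrix (columns R, G, B).
#' @return An object of the same shape with the three planes/columns replaced
#'   by Y', Cb, Cr on the 8-bit-offset scale (Y' in \[16, 235\], chroma in
#'   \[16, 240\]).
#' @examples
#' rgb_to_ycbcr(matrix(c(0, 0, 0), 1, 3))     # 16, 128, 128
#' rgb_to_ycbcr(matrix(c(1, 1, 1), 1, 3))     # 235, 128, 128
#' @export
rgb_to_ycbcr <- function(rgb) {
  dm <- dim(rgb)
  if (is.null(dm) || !(length(dm) %in% c(2L, 3L)) || dm[length(dm)] != 3L) {
    stop_pg("`rgb` must be an h x w x 3 array or an n x 3 matrix.",
            "pg_domain_error")
  }
  v <- range(rgb, na.rm = TRUE)
  if (v[1] < -1e-9 || v[2] > 1 + 1e-9) {
    stop_pg("RGB values must lie in [0, 1]; divide 8-bit inputs by 255.",
            "pg_domain_error")
  }
  flat <- matrix(as.numeric(rgb), ncol = 3L)
  out <- flat %*% t(.ycbcr_matrix)
  out <- sweep(out, 2L, .ycbcr_offset, "+")
  if (length(dm) == 3L) {
    arr <- array(out, dim = dm)
    dimnames(arr) <- NULL
    arr
  } else {
    colnames(out) <- c("y", "cb", "cr")
    out
  }
}

#' Mask skin pixels with the static YCbCr thresholds
#'
#' A pixel is classified as skin iff `133 <= Cb <= 173` and `77 <= Cr <= 127`,
#' both bounds inclusive. The rule is a fixed heuristic band in the chroma
#' plane; no adaptation to the frame content is performed.
#'
#' @param ycbcr An `h x w x 3` array (planes Y', Cb, Cr) as returned by
#'   [rgb_to_ycbcr()], or an `n x 3` matrix.
#' @param cb_range,cr_range Numeric length-2 inclusive bounds for the chroma
#'   bands.
#' @return A list of class `skin_mask` with elements `mask` (logical matrix or
#'   vector) and `skin_fraction` (mean of the mask).
#' @export
skin_mask <- function(ycbcr, cb_range = c(133, 173), cr_range = c(77, 127)) {
  dm <- dim(ycbcr)
  if (length(dm) == 3L && dm[3] == 3L) {
    cb <- ycbcr[, , 2]
    cr <- ycbcr[, , 3]
  } else if (length(dm) == 2L && dm[2] == 3L) {
    cb <- ycbcr[, 2]
    cr <- ycbcr[, 3]
  } else {
    stop_pg("`ycbcr` must be an h x w x 3 array or an n x 3 matrix.",
            "pg_domain_error")
  }
  mask <- cb >= cb_range[1] & cb <= cb_range[2] &
    cr >= cr_range[1] & cr <= cr_range[2]
  structure(list(mask = mask, skin_fraction = mean(mask)),
            class = "skin_mask")
}

#' Per-region mean color signals over skin pixels
#'
#' For every frame and each region box (face, nose, eyes), computes the mean
#' of R, G, B (0-255 scale) and Y', Cb, Cr over the skin-masked pixels inside
#' the box. The skin mask is computed once per frame on the whole frame.
#' Frames where fewer than `min_skin_fraction` of the box pixels are skin are
#' flagged invalid; gaps of up to `max_gap` consecutive invalid frames are
#' filled by linear interpolation, longer gaps (or an all-invalid region) are
#' an error.
#'
#' @param video A `pg_video` (see [generate_video()] / [read_video()]).
#' @param track A region track tibble (`frame`, `region`, `x`, `y`, `w`, `h`);
#'   defaults to the video's own ground-truth track.
#' @param min_skin_fraction Minimum fraction of box pixels that must be skin
#'   for the frame to count as valid (default 0.05).
#' @param max_gap Longest invalid run that is interpolated over (default 5).
#' @return A tibble with columns `frame` (0-based), `region`, `mean_r`,
#'   `mean_g`, `mean_b`, `mean_y`, `mean_cb`, `mean_cr`, `valid`. The frame
#'   rate is attached as attribute `fps`.
#' @export
region_mean_signals <- function(video, track = NULL,
                                min_skin_fraction = 0.05, max_gap = 5L) {
  stopifnot(inherits(video, "pg_video"))
  if (is.null(track)) track <- video$roi_track
  if (is.null(track)) {
    stop_pg("No region track supplied and the video carries none.",
            "pg_extraction_error")
  }
  n_frames <- length(video$frames)
  validate_roi_track(track, video$width, video$height, n_frames)
  regions <- unique(track$region)
  per_region <- lapply(regions, function(r) {
    matrix(NA_real_, nrow = n_frames, ncol = 7L)
  })
  names(per_region) <- regions
  track_by_region <- split(track, track$region)

  for (t in seq_len(n_frames)) {
    fr <- video$frames[[t]] / 255
    ycc <- rgb_to_ycbcr(fr)
    msk <- skin_mask(ycc)$mask
    for (r in regions) {
      b <- track_by_region[[r]][t, ]
      rows <- (b$y + 1L):(b$y + b$h)
      cols <- (b$x + 1L):(b$x + b$w)
      sub_mask <- msk[rows, cols]
      frac <- mean(sub_mask)
      if (frac >= min_skin_fraction) {
        vals <- vapply(1:3, function(k) {
          c(mean(fr[rows, cols, k][sub_mask]) * 255,
            mean(ycc[rows, cols, k][sub_mask]))
        }, numeric(2))
        # vals: 2 x 3 (rows: rgb-scale mean, ycc mean)
        per_region[[r]][t, ] <- c(vals[1, ], vals[2, ], 1)
      } else {
        per_region[[r]][t, 7] <- 0
      }
    }
  }

  out <- lapply(regions, function(r) {
    m <- per_region[[r]]
    valid <- m[, 7] == 1 & !is.na(m[, 7])
    if (!any(valid)) {
      stop_pg(sprintf("Region '%s' has no frames with enough skin pixels.", r),
              "pg_extraction_error")
    }
    runs <- rle(!valid)
    if (any(runs$values & runs$lengths > max_gap)) {
      stop_pg(sprintf(
        "Region '%s' has an invalid gap longer than %d frames.", r, max_gap),
        "pg_extraction_error")
    }
    for (k in 1:6) {
      m[, k] <- approx(which(valid), m[valid, k], xout = seq_len(nrow(m)),
                       rule = 2)$y
    }
    tibble(
      frame = seq_len(nrow(m)) - 1L, region = r,
      mean_r = m[, 1], mean_g = m[, 2], mean_b = m[, 3],
      mean_y = m[, 4], mean_cb = m[, 5], mean_cr = m[, 6],
      valid = valid
    )
  })
  res <- bind_rows(out)
  res$region <- factor(res$region, levels = c("face", "nose", "eyes"))
  res <- arrange(res, .data$region, .data$frame)
  attr(res, "fps") <- video$fps
  res
}
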