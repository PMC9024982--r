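# Lossless video I/O: image-sequence directories (PNG) with a JSON sidecar
# carrying fps, label, attack kind, ground-truth BPM and the region track.

#' Write a video as a lossless PNG sequence with JSON sidecar
#'
#' @param video A `pg_video`.
#' @param dir Output directory (created if missing). Frames are written as
#'   `frame_000001.png` etc.; metadata goes to `sidecar.json`.
#' @return `dir`, invisibly.
#' @export
write_video <- function(video, dir) {
  stopifnot(inherits(video, "pg_video"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(video$frames)) {
    png::writePNG(video$frames[[i]] / 255,
                  file.path(dir, sprintf("frame_%06d.png", i)))
  }
  sidecar <- list(
    fps = video$fps, width = video$width, height = video$height,
    label = video$label, attack_kind = video$attack_kind,
    truth_bpm = video$truth_bpm, profile = video$profile,
    roi_track = video$roi_track
  )
  jsonlite::write_json(sidecar, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")
  invisible(dir)
}

#' Read a video from a PNG sequence directory
#'
#' Frames are decoded in lexicographic order; fps and labels come from the
#' `sidecar.json` written by [write_video()] (fps falls back to `fps` if no
#' sidecar exists).
#'
#' @param path Directory containing `*.png` frames and optionally
#'   `sidecar.json`.
#' @param fps Frame rate used when no sidecar is present.
#' @return A `pg_video`.
#' @export
read_video <- function(path, fps = 30) {
  if (!dir.exists(path)) {
    stop_pg(sprintf("'%s' is not a readable directory.", path), "pg_io_error")
  }
  files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE))
  if (length(files) == 0) {
    stop_pg(sprintf("No PNG frames found in '%s'.", path), "pg_io_error")
  }
  frames <- lapply(files, function(f) {
    arr <- png::readPNG(f)
    if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
    if (dim(arr)[3] > 3) arr <- arr[, , 1:3, drop = FALSE]
    round(arr * 255)
  })
  dims <- vapply(frames, function(f) dim(f)[1:2], integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop_pg("Frames have inconsistent dimensions.", "pg_format_error")
  }
  meta <- list(fps = fps, label = NA_integer_, attack_kind = NA_character_,
               truth_bpm = NA_real_, profile = NA_character_,
               roi_track = NULL)
  sidecar_path <- file.path(path, "sidecar.json")
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    for (nm in c("fps", "label", "attack_kind", "truth_bpm", "profile")) {
      if (!is.null(sc[[nm]])) meta[[nm]] <- sc[[nm]]
    }
    if (!is.null(sc$roi_track)) {
      meta$roi_track <- as_tibble(sc$roi_track)
    }
  }
  structure(list(
    frames = frames, fps = meta$fps,
    width = dim(frames[[1]])[2], height = dim(frames[[1]])[1],
    label = meta$label, attack_kind = meta$attack_kind,
    truth_bpm = meta$truth_bpm, roi_track = meta$roi_track,
    profile = meta$profile
  ), class = "pg_video")
}
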