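# Synthetic pulsatile face video generator. Faces are flat skin-tone ellipses
# with darker eye/mouth patches and a static surface texture; the pipeline
# consumes color statistics, not appearance, so no photorealism is attempted.

# Base face color: the (unique) color whose YCbCr coordinates sit in the
# middle of the static skin band (Y'=150, Cb=150, Cr=100), obtained by
# inverting the BT.601 transform.
.face_base_rgb <- function() {
  as.numeric(solve(.ycbcr_matrix, c(150, 150, 100) - .ycbcr_offset)) * 255
}

.dark_rgb <- c(40, 30, 30)   # eye/mouth patches; Cb ~126, outside the band
.bg_rgb <- c(180, 180, 180)  # achromatic background, Cb = Cr = 128

# Pulse color direction (G-dominant) and the replay variant with its chroma
# ratio deliberately distorted.
.pulse_weights_live <- c(0.5, 1.0, 0.3)
.pulse_weights_replay <- c(0.25, 1.0, 0.8)
.replay_attenuation <- 0.6
.replay_flicker_hz <- 3.3
.replay_flicker_amp <- 0.004
.replay_noise_factor <- 2
.bend_hz <- 0.8
.sweep_hz <- 0.5
.texture_amp <- 4
.texture_grid <- 12L

# Face geometry in fractions of the frame / face semi-axes.
.face_geometry <- function(width, height) {
  list(cx = width / 2, cy = height / 2,
       a = 0.32 * width, b = 0.42 * height)
}

#' Generate one labeled synthetic video
#'
#' Renders a face video whose skin pixels are modulated by a cardiac pulse at
#' the configured rate (a sinusoid at `heart_rate/60` Hz plus a half-amplitude
#' first harmonic, on a G-dominant color axis), plus respiration drift, head
#' micro-motion, a static skin texture and Gaussian sensor noise. Attack kinds
#' alter the rendering: cut-out photo attacks carry the pulse only in the live
#' (cut-out) sub-regions; replay keeps an attenuated pulse with distorted
#' chroma ratio, display flicker and a raised noise floor; shake/bend/
#' light_sweep are pulseless photo attacks with global jitter or moving
#' shading.
#'
#' @param scene A [scene_config()].
#' @param attack An [attack_spec()] (default genuine).
#' @return A list of class `pg_video`: `frames` (list of `h x w x 3` arrays,
#'   0-255), `fps`, `width`, `height`, `label` (1 = real, 0 = attack),
#'   `attack_kind`, `truth_bpm` (NA when no pulse is rendered), `roi_track`
#'   (ground-truth face/nose/eyes boxes) and `profile`.
#' @examples
#' v <- generate_video(scene_config(duration = 3.2, seed = 42))
#' length(v$frames)
#' @export
generate_video <- function(scene, attack = attack_spec("genuine")) {
  validate_scene_config(scene)
  stopifnot(inherits(attack, "attack_spec"))
  n <- round(scene$duration * scene$fps)
  w <- scene$width
  h <- scene$height
  geo <- .face_geometry(w, h)
  tt <- (seq_len(n) - 1) / scene$fps
  f_pulse <- scene$heart_rate / 60
  f_resp <- scene$respiration_rate / 60
  kind <- attack$kind

  has_pulse <- kind %in% c("genuine", "cutout_eyes_nose_mouth",
                           "cutout_cheek_chin", "replay")
  noise_sigma <- scene$noise_sigma *
    if (kind == "replay") .replay_noise_factor else 1

  with_local_seed(scene$seed, {
    # static surface texture in face-local coordinates (moves with the face)
    gs <- .texture_grid
    tex_grid <- matrix(rnorm(gs * gs), gs, gs)

    # head micro-motion: reflected random walk, +- 3 px
    step_x <- rnorm(n, 0, scene$micro_motion_sigma)
    step_y <- rnorm(n, 0, scene$micro_motion_sigma)
    reflect_walk <- function(steps, lim = 3) {
      pos <- numeric(length(steps))
      cur <- 0
      for (i in seq_along(steps)) {
        cur <- cur + steps[i]
        if (cur > lim) cur <- 2 * lim - cur
        if (cur < -lim) cur <- -2 * lim - cur
        pos[i] <- cur
      }
      pos
    }
    off_x <- reflect_walk(step_x)
    off_y <- reflect_walk(step_y)

    if (kind == "shake") {
      # circular jitter whose chord length per frame equals `magnitude`
      radius <- 4
      dang <- 2 * asin(clamp(attack$magnitude / (2 * radius), 0, 1))
      ang <- cumsum(rep(dang, n))
      off_x <- off_x + radius * cos(ang)
      off_y <- off_y + radius * sin(ang)
    }

    pw <- if (kind == "replay") .pulse_weights_replay else .pulse_weights_live
    pamp <- scene$pulse_amplitude *
      if (kind == "replay") .replay_attenuation else 1
    pulse_t <- sin(2 * pi * f_pulse * tt) + 0.5 * sin(4 * pi * f_pulse * tt)
    resp_t <- sin(2 * pi * f_resp * tt)

    xg <- matrix(rep(seq_len(w) - 0.5, each = h), h, w)
    yg <- matrix(rep(seq_len(h) - 0.5, times = w), h, w)

    frames <- vector("list", n)
    face_centers <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      cx <- geo$cx + off_x[i]
      cy <- geo$cy + off_y[i]
      face_centers[i, ] <- c(cx, cy)
      ex <- (xg - cx) / geo$a
      ey <- (yg - cy) / geo$b
      face <- ex^2 + ey^2 <= 1
      eye_l <- ((ex + 0.38) / 0.16)^2 + ((ey + 0.35) / 0.10)^2 <= 1
      eye_r <- ((ex - 0.38) / 0.16)^2 + ((ey + 0.35) / 0.10)^2 <= 1
      mouth <- (ex / 0.30)^2 + ((ey - 0.55) / 0.09)^2 <= 1
      nose <- (ex / 0.20)^2 + ((ey - 0.05) / 0.20)^2 <= 1
      features <- eye_l | eye_r | mouth

      live <- switch(kind,
        genuine = face,
        replay = face,
        cutout_eyes_nose_mouth = face & (eye_l | eye_r | nose | mouth),
        cutout_cheek_chin = face & ey > 0.25,
        matrix(FALSE, h, w)
      )

      # static texture sampled in face-local coordinates
      tex <- matrix(0, h, w)
      if (any(face)) {
        u <- (ex[face] + 1) / 2 * (gs - 1)
        v <- (ey[face] + 1) / 2 * (gs - 1)
        tex[face] <- .texture_amp *
          bilinear_sample(tex_grid, clamp(u, 0, gs - 1.001),
                          clamp(v, 0, gs - 1.001))
      }

      base <- .face_base_rgb()
      img <- array(0, dim = c(h, w, 3))
      for (k in 1:3) {
        plane <- matrix(.bg_rgb[k], h, w)
        plane[face] <- base[k]
        plane[features] <- .dark_rgb[k]
        plane <- plane + tex
        if (has_pulse && any(live)) {
          # fractional (multiplicative) modulation, as blood absorption
          # scales reflectance; keeps the chrominance projections of the
          # pulse anti-correlated, as the CHROM combination assumes
          plane[live] <- plane[live] * (1 + pamp * pw[k] * pulse_t[i])
          plane[live] <- plane[live] +
            scene$pulse_amplitude * 255 * resp_t[i]
        }
        if (kind == "replay") {
          plane[face] <- plane[face] + .replay_flicker_amp * 255 *
            sin(2 * pi * .replay_flicker_hz * tt[i])
        }
        if (kind == "bend_h") {
          plane <- plane + attack$magnitude * 255 *
            sin(2 * pi * .bend_hz * tt[i]) * (xg / w)
        }
        if (kind == "bend_v") {
          plane <- plane + attack$magnitude * 255 *
            sin(2 * pi * .bend_hz * tt[i]) * (yg / h)
        }
        if (kind == "light_sweep") {
          phase <- (tt[i] * .sweep_hz) %% 1
          x0 <- w * (2 * abs(phase - 0.5))  # triangular sweep across width
          plane <- plane + attack$magnitude * 255 *
            exp(-((xg - x0)^2) / (2 * (w / 6)^2))
        }
        img[, , k] <- plane
      }
      noise <- array(rnorm(h * w * 3, 0, noise_sigma), dim = c(h, w, 3))
      img <- img + noise
      for (k in 1:3) img[, , k] <- img[, , k] * scene$white_balance[k]
      frames[[i]] <- round(clamp(img, 0, 255))
    }

    roi_track <- ground_truth_track(face_centers, geo, w, h)
    structure(list(
      frames = frames, fps = scene$fps, width = w, height = h,
      label = as.integer(kind == "genuine"), attack_kind = kind,
      truth_bpm = if (has_pulse) scene$heart_rate else NA_real_,
      roi_track = roi_track, profile = NA_character_,
      scene = scene, attack = attack
    ), class = "pg_video")
  })
}

# Ground-truth region boxes from the rendered face-ellipse centers.
ground_truth_track <- function(centers, geo, width, height) {
  x <- clamp(round(centers[, 1] - geo$a), 0, width - 1)
  y <- clamp(round(centers[, 2] - geo$b), 0, height - 1)
  bw <- pmin(round(2 * geo$a), width - x)
  bh <- pmin(round(2 * geo$b), height - y)
  n <- nrow(centers)
  face <- tibble(frame = seq_len(n) - 1L, region = "face",
                 x = as.integer(x), y = as.integer(y),
                 w = as.integer(bw), h = as.integer(bh))
  bind_rows(face, derive_subregions(face))
}

#' @export
print.pg_video <- function(x, ...) {
  cat(sprintf(
    "<pg_video> %d frames %dx%d @ %g fps | label=%d kind=%s truth_bpm=%s\n",
    length(x$frames), x$width, x$height, x$fps, x$label, x$attack_kind,
    format(x$truth_bpm)), ...)
  invisible(x)
}

#' Generate a benchmark suite of labeled videos
#'
#' Builds the study-design grid the classifiers are trained and evaluated on:
#' `n_per_class` videos for each of three classes (genuine, cut-out
#' cheek/chin photo, high-quality replay) under two simulated device profiles
#' (`A`: baseline noise, neutral white balance; `B`: higher noise, warm/cool
#' white-balance shift), with heart rates drawn uniformly from \[48, 120\]
#' bpm. The suite is returned lazily as a tibble of per-video configurations
#' (each row carries its own derived seed, so any video can be re-rendered
#' deterministically); use [suite_video()] to realize one row or
#' [suite_clips()] to run extraction over the whole suite one video at a
#' time.
#'
#' @param scene_defaults A [scene_config()] providing everything except
#'   heart rate, noise, white balance and seed.
#' @param n_per_class Number of videos per class and device profile.
#' @param seed Integer seed for heart-rate draws and per-video seeds.
#' @return A tibble with columns `video_id`, `attack_kind`, `profile`,
#'   `label`, `truth_bpm`, `seed`, `scene` (list), `attack` (list).
#' @export
generate_benchmark_suite <- function(scene_defaults = scene_config(),
                                     n_per_class = 10, seed = 1L) {
  stopifnot(n_per_class >= 1)
  validate_scene_config(scene_defaults)
  classes <- c("genuine", "cutout_cheek_chin", "replay")
  profiles <- list(
    A = list(noise_sigma = scene_defaults$noise_sigma,
             white_balance = c(1, 1, 1)),
    B = list(noise_sigma = 1.5 * scene_defaults$noise_sigma,
             white_balance = c(1.03, 1, 0.97))
  )
  grid <- expand.grid(idx = seq_len(n_per_class), profile = names(profiles),
                      attack_kind = classes, stringsAsFactors = FALSE)
  n_videos <- nrow(grid)
  with_local_seed(seed, {
    hrs <- runif(n_videos, 48, 120)
    vseeds <- sample.int(.Machine$integer.max, n_videos)
  })
  rows <- lapply(seq_len(n_videos), function(i) {
    g <- grid[i, ]
    prof <- profiles[[g$profile]]
    sc <- scene_defaults
    sc$heart_rate <- hrs[i]
    sc$noise_sigma <- prof$noise_sigma
    sc$white_balance <- prof$white_balance
    sc$seed <- vseeds[i]
    atk <- attack_spec(g$attack_kind)
    tibble(
      video_id = sprintf("%s_%s_%02d", g$attack_kind, g$profile, g$idx),
      attack_kind = g$attack_kind, profile = g$profile,
      label = as.integer(g$attack_kind == "genuine"),
      truth_bpm = hrs[i], seed = vseeds[i],
      scene = list(sc), attack = list(atk)
    )
  })
  suite <- bind_rows(rows)
  class(suite) <- c("pg_suite", class(suite))
  suite
}

#' Realize one suite row as a rendered video
#'
#' @param suite A suite tibble from [generate_benchmark_suite()] (or one row
#'   of it).
#' @param video_id Which video to render; defaults to the first row.
#' @return A `pg_video`.
#' @export
suite_video <- function(suite, video_id = NULL) {
  row <- if (is.null(video_id)) suite[1, ] else
    suite[suite$video_id == video_id, ]
  if (nrow(row) != 1) stop_pg("video_id not found in suite.", "pg_io_error")
  v <- generate_video(row$scene[[1]], row$attack[[1]])
  v$profile <- row$profile
  v$video_id <- row$video_id
  v
}
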