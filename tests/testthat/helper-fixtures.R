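# Shared fixtures. Videos are generated once per test run and cached here;
# small scenes keep the suite fast while preserving the >= 90-frame minimum.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

tiny_scene <- function(...) {
  scene_config(width = 64, height = 48, duration = 3.2, ...)
}

fixture_genuine <- function() {
  cached("genuine", generate_video(tiny_scene(heart_rate = 72, seed = 42)))
}

fixture_genuine_signals <- function() {
  cached("genuine_signals", extract_signals(fixture_genuine()))
}

fixture_shake <- function() {
  cached("shake",
         generate_video(tiny_scene(seed = 43), attack_spec("shake")))
}

# A uniform-color "video" built by hand (no face), for exact-value checks.
flat_video <- function(rgb, n_frames = 3, w = 20, h = 16) {
  frames <- lapply(seq_len(n_frames), function(i) {
    arr <- array(0, c(h, w, 3))
    for (k in 1:3) arr[, , k] <- rgb[k]
    arr
  })
  track <- dplyr::bind_rows(lapply(c("face", "nose", "eyes"), function(r) {
    tibble::tibble(frame = seq_len(n_frames) - 1L, region = r,
                   x = 2L, y = 2L, w = as.integer(w - 4), h = as.integer(h - 4))
  }))
  structure(list(frames = frames, fps = 30, width = w, height = h,
                 label = 1L, attack_kind = "genuine", truth_bpm = NA_real_,
                 roi_track = track, profile = NA_character_),
            class = "pg_video")
}

# Synthetic clip sets built directly (no videos): class 1 carries a shared
# oscillatory pattern, class 0 is pure noise.
synthetic_clipset <- function(n_per_class = 30, n_channels = 15, seed = 1,
                              signal_amp = 3) {
  withr::with_seed(seed, {
    channels <- pulsegate:::clip_channel_names()[seq_len(n_channels)]
    make_clip <- function(id, label) {
      tt <- seq_len(90)
      base <- if (label == 1) {
        outer(sin(2 * pi * 1.2 * tt / 30), rep(signal_amp, n_channels))
      } else {
        matrix(0, 90, n_channels)
      }
      m <- base + matrix(rnorm(90 * n_channels), 90, n_channels)
      m <- scale(m)
      colnames(m) <- channels
      tibble::tibble(video_id = sprintf("v%03d", id), label = label,
                     attack_kind = ifelse(label == 1, "genuine", "attack"),
                     profile = "A", start = 0L, tensor = list(m))
    }
    out <- dplyr::bind_rows(
      lapply(seq_len(n_per_class), function(i) make_clip(i, 1L)),
      lapply(seq_len(n_per_class), function(i)
        make_clip(n_per_class + i, 0L))
    )
    class(out) <- c("pg_clipset", class(out))
    attr(out, "channels") <- channels
    attr(out, "clip_len") <- 90L
    out
  })
}
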