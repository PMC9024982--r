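# Scene and attack configuration for the synthetic pulsatile video generator.

#' Scene configuration for synthetic face video
#'
#' Describes one recording: geometry, frame rate, the cardiac ground truth and
#' the nuisance processes (respiration drift, head micro-motion, sensor
#' noise). The seed fully determines the rendered pixels.
#'
#' @param width,height Frame size in pixels.
#' @param fps Frame rate in frames/s. Must exceed twice the pulse frequency
#'   (`2 * heart_rate / 60`) so the pulse stays below Nyquist.
#' @param duration Length in seconds; must yield at least 90 frames.
#' @param heart_rate Ground-truth pulse rate in bpm, within \[42, 240\].
#' @param pulse_amplitude Fractional color modulation of skin pixels caused by
#'   the pulse (default 0.01, i.e. ~2.6 intensity units on G).
#' @param respiration_rate Respiration drift rate in breaths/min (adds a slow
#'   luminance oscillation the detrending stage must remove).
#' @param micro_motion_sigma Per-frame standard deviation (pixels) of the
#'   head's random-walk micro-motion.
#' @param noise_sigma Per-pixel, per-channel Gaussian sensor noise (0-255
#'   intensity units).
#' @param white_balance Length-3 channel gains emulating a device's white
#'   balance.
#' @param seed Integer seed; identical configs with identical seeds render
#'   identical videos.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(width = 96, height = 72, fps = 30, duration = 10,
                         heart_rate = 72, pulse_amplitude = 0.01,
                         respiration_rate = 15, micro_motion_sigma = 0.1,
                         noise_sigma = 2, white_balance = c(1, 1, 1),
                         seed = 1L) {
  cfg <- list(
    width = as.integer(width), height = as.integer(height), fps = fps,
    duration = duration, heart_rate = heart_rate,
    pulse_amplitude = pulse_amplitude, respiration_rate = respiration_rate,
    micro_motion_sigma = micro_motion_sigma, noise_sigma = noise_sigma,
    white_balance = white_balance, seed = as.integer(seed)
  )
  class(cfg) <- "scene_config"
  validate_scene_config(cfg)
  cfg
}

validate_scene_config <- function(cfg) {
  stopifnot(inherits(cfg, "scene_config"))
  if (cfg$heart_rate < 42 || cfg$heart_rate > 240) {
    stop_pg("`heart_rate` must lie in [42, 240] bpm.", "pg_config_error")
  }
  if (cfg$fps <= 2 * cfg$heart_rate / 60) {
    stop_pg("`fps` must exceed twice the pulse frequency (Nyquist).",
            "pg_config_error")
  }
  if (round(cfg$duration * cfg$fps) < 90) {
    stop_pg("`duration` must yield at least 90 frames.", "pg_config_error")
  }
  if (cfg$width < 32 || cfg$height < 32) {
    stop_pg("Frames must be at least 32 x 32 pixels.", "pg_config_error")
  }
  if (length(cfg$white_balance) != 3 || any(cfg$white_balance <= 0)) {
    stop_pg("`white_balance` must be three positive gains.", "pg_config_error")
  }
  invisible(cfg)
}

.attack_kinds <- c("genuine", "cutout_eyes_nose_mouth", "cutout_cheek_chin",
                   "replay", "shake", "bend_h", "bend_v", "light_sweep")

.default_magnitudes <- c(
  genuine = 0, cutout_eyes_nose_mouth = 1, cutout_cheek_chin = 1,
  replay = 1, shake = 5, bend_h = 0.2, bend_v = 0.2, light_sweep = 0.2
)

#' Attack specification
#'
#' Selects the presentation-attack type rendered by [generate_video()].
#' `cutout_*` kinds emulate a printed photo with regions cut out so the
#' attacker's live skin (and its pulse) shows through; `replay` emulates a
#' high-quality screen replay of a live face; `shake`, `bend_h`/`bend_v` and
#' `light_sweep` are the gross-motion/lighting attacks the screening stage
#' must catch.
#'
#' @param kind One of `r paste0('"', .attack_kinds, '"', collapse = ", ")`.
#' @param magnitude Kind-specific amplitude: pixels/frame for `shake`,
#'   fractional shading amplitude for `bend_*` and `light_sweep`. Ignored for
#'   `genuine`; defaults are per-kind.
#' @return A list of class `attack_spec`.
#' @export
attack_spec <- function(kind = "genuine", magnitude = NULL) {
  kind <- match.arg(kind, .attack_kinds)
  if (is.null(magnitude)) magnitude <- unname(.default_magnitudes[kind])
  structure(list(kind = kind, magnitude = magnitude), class = "attack_spec")
}
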