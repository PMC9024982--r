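# High-level experiment runners: the canonical ways this package is exercised
# end to end. The CLI and the acceptance script are thin wrappers over these.

#' Heart-rate recovery experiment
#'
#' Generates `n` genuine videos with heart rates drawn uniformly from
#' \[48, 120\] bpm, runs the full extraction chain on each face region and
#' compares the estimated BPM with the ground truth.
#'
#' @param n Number of videos.
#' @param seed Integer seed.
#' @param scene_defaults Scene configuration template.
#' @return A tibble (`video`, `truth_bpm`, `estimated_bpm`, `abs_error`).
#' @export
run_bpm_experiment <- function(n = 50, seed = 1L,
                               scene_defaults = scene_config()) {
  draws <- with_local_seed(seed, {
    list(hr = runif(n, 48, 120),
         seeds = sample.int(.Machine$integer.max, n))
  })
  rows <- lapply(seq_len(n), function(i) {
    sc <- scene_defaults
    sc$heart_rate <- draws$hr[i]
    sc$seed <- draws$seeds[i]
    v <- generate_video(sc)
    est <- video_bpm(extract_signals(v))
    tibble(video = i, truth_bpm = draws$hr[i], estimated_bpm = est$bpm,
           abs_error = abs(est$bpm - draws$hr[i]))
  })
  bind_rows(rows)
}

#' Screening experiment
#'
#' Calibrates motion/light thresholds on a genuine population, then screens
#' fresh genuine videos and shake/bend/light-sweep attacks.
#'
#' @param n_calibrate Genuine videos used for threshold calibration.
#' @param n_fresh Fresh genuine videos screened after calibration.
#' @param n_attack Videos per attack kind.
#' @param attack_kinds Attack kinds to screen.
#' @param seed Integer seed.
#' @param scene_defaults Scene configuration template.
#' @param k Threshold margin (see [calibrate_thresholds()]).
#' @return A list: `thresholds`, `results` (per-video tibble with
#'   `kind`, `motion_mean`, `light_mean`, `passed`, `criterion`),
#'   `genuine_pass_rate`, `attack_rejection_rate` (both in percent).
#' @export
run_screening_experiment <- function(n_calibrate = 20, n_fresh = 20,
                                     n_attack = 20,
                                     attack_kinds = c("shake", "bend_h",
                                                      "light_sweep"),
                                     seed = 1L,
                                     scene_defaults = scene_config(),
                                     k = 6) {
  n_total <- n_calibrate + n_fresh + n_attack * length(attack_kinds)
  draws <- with_local_seed(seed, {
    list(hr = runif(n_total, 48, 120),
         seeds = sample.int(.Machine$integer.max, n_total))
  })
  idx <- 0L
  next_video <- function(kind) {
    idx <<- idx + 1L
    sc <- scene_defaults
    sc$heart_rate <- draws$hr[idx]
    sc$seed <- draws$seeds[idx]
    generate_video(sc, attack_spec(kind))
  }
  stats_for <- function(kind) {
    v <- next_video(kind)
    tr <- screening_traces(v)
    tibble(kind = kind, motion_mean = tr$motion_mean,
           light_mean = tr$light_mean)
  }
  cal <- bind_rows(lapply(seq_len(n_calibrate), function(i)
    stats_for("genuine")))
  thresholds <- calibrate_thresholds(cal, k = k)
  screened <- bind_rows(
    lapply(seq_len(n_fresh), function(i) stats_for("genuine")),
    bind_rows(lapply(attack_kinds, function(kind)
      bind_rows(lapply(seq_len(n_attack), function(i) stats_for(kind)))))
  )
  if (nrow(screened) == 0) {
    return(list(thresholds = thresholds, calibration = cal,
                results = screened, genuine_pass_rate = NA_real_,
                attack_rejection_rate = NA_real_))
  }
  screened <- screened |>
    mutate(decision = purrr::map2(.data$motion_mean, .data$light_mean,
                                  ~screen_video(.x, .y, thresholds)),
           passed = purrr::map_lgl(.data$decision, "passed"),
           criterion = purrr::map_chr(.data$decision, "criterion")) |>
    select(-"decision")
  genuine <- screened$kind == "genuine"
  list(
    thresholds = thresholds,
    calibration = cal,
    results = screened,
    genuine_pass_rate = 100 * mean(screened$passed[genuine]),
    attack_rejection_rate = 100 * mean(!screened$passed[!genuine])
  )
}

#' End-to-end classification benchmark
#'
#' Generates a benchmark suite, extracts clip tensors, splits 5:1 at the
#' video level, trains a classifier and evaluates it on the held-out clips.
#'
#' @param n_per_class Videos per class and device profile.
#' @param seed Seed driving suite generation, the split and training.
#' @param spec A [model_spec()].
#' @param regions Regions used for the clip tensors (`"face"` alone gives
#'   the face-only configuration).
#' @param scene_defaults Scene configuration template.
#' @param config A [train_config()]; its seed defaults to `seed`.
#' @param clips Optional precomputed `pg_clipset` (skips generation).
#' @return A list: `report` (an `eval_report`), `classifier`, `predictions`,
#'   `clips`.
#' @export
run_benchmark <- function(n_per_class = 10, seed = 1L,
                          spec = model_spec("cnn", "per_signal_branches"),
                          regions = c("face", "nose", "eyes"),
                          scene_defaults = scene_config(),
                          config = NULL, clips = NULL) {
  if (is.null(config)) config <- train_config(seed = seed)
  if (is.null(clips)) {
    suite <- generate_benchmark_suite(scene_defaults, n_per_class,
                                      seed = seed)
    clips <- suite_clips(suite, regions = regions)
  }
  clips <- split_by_video(clips, test_fraction = 1 / 6, seed = seed)
  train_set <- filter(clips, .data$split == "train")
  test_set <- filter(clips, .data$split == "test")
  clf <- train_classifier(spec, train_set, test_set, config)
  pred <- predict(clf, test_set)
  list(report = evaluate_predictions(pred), classifier = clf,
       predictions = pred, clips = clips)
}

#' Restrict a clip set to a subset of regions
#'
#' Slices the stored tensors down to the named regions' channels (e.g. for
#' the face-only model) without re-extracting signals.
#'
#' @param clips A `pg_clipset` built with all three regions.
#' @param regions Regions to keep, in clip-tensor order.
#' @return A `pg_clipset` with narrower tensors.
#' @export
subset_regions <- function(clips, regions = "face") {
  keep <- clip_channel_names(regions)
  have <- attr(clips, "channels")
  if (!all(keep %in% have)) {
    stop_pg("Requested regions not present in the clip set.",
            "pg_input_error")
  }
  out <- mutate(clips, tensor = purrr::map(.data$tensor,
                                           ~.x[, keep, drop = FALSE]))
  class(out) <- class(clips)
  attr(out, "channels") <- keep
  attr(out, "clip_len") <- attr(clips, "clip_len")
  out
}
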