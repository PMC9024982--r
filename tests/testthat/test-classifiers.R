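# Classifier construction, training sanity, determinism and prediction.

test_that("all default architectures build, score in [0,1], stay desk-scale", {
  clips <- synthetic_clipset(n_per_class = 3)
  for (kind in c("cnn", "lstm", "crnn")) {
    for (fusion in c("joint", "per_signal_branches")) {
      spec <- model_spec(kind, fusion)
      m <- build_model(spec, attr(clips, "channels"))
      expect_lt(parameter_count(m), 5e6)
      z <- pulsegate:::model_forward(m, pulsegate:::clips_to_array(clips))
      expect_equal(dim(z), c(6, 1))
      sc <- 1 / (1 + exp(-z))
      expect_true(all(sc >= 0 & sc <= 1))
    }
  }
})

test_that("per-signal branches each consume one signal's region channels", {
  channels <- pulsegate:::clip_channel_names()
  m <- build_model(model_spec("cnn", "per_signal_branches"), channels)
  expect_length(m$slices, 5)
  for (s in 1:5) {
    expect_length(m$slices[[s]], 3)  # 90 x 3 slice per branch
    sig <- sub("^(face|nose|eyes)_", "", channels[m$slices[[s]]])
    expect_length(unique(sig), 1)    # same signal type across regions
  }
  expect_error(build_model(model_spec("cnn", "per_signal_branches"),
                           channels[1:7]), class = "pg_config_error")
})

test_that("a linearly separable clip set is learned to accuracy 1 quickly", {
  clips <- synthetic_clipset(n_per_class = 25, seed = 2)
  for (kind in c("cnn", "lstm", "crnn")) {
    clf <- train_classifier(model_spec(kind), clips, NULL,
                            train_config(epochs = 20, batch_size = 25,
                                         seed = 1))
    expect_equal(max(clf$history$train_acc), 1,
                 info = paste("kind =", kind))
  }
})

test_that("without class signal the validation AUC stays at chance", {
  # both classes are pure noise: the labels carry no learnable structure
  tr <- synthetic_clipset(n_per_class = 30, seed = 3, signal_amp = 0)
  te <- synthetic_clipset(n_per_class = 30, seed = 4, signal_amp = 0)
  te$video_id <- paste0("t_", te$video_id)
  clf <- train_classifier(model_spec("cnn"), tr, te,
                          train_config(epochs = 5, seed = 1))
  pred <- predict(clf, te)
  auc <- pulsegate:::auc_pairwise(pred$score, pred$label)
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("training is deterministic given the seed", {
  clips <- synthetic_clipset(n_per_class = 10, seed = 5)
  cfg <- train_config(epochs = 3, seed = 7)
  c1 <- train_classifier(model_spec("cnn"), clips, NULL, cfg)
  c2 <- train_classifier(model_spec("cnn"), clips, NULL, cfg)
  expect_identical(pulsegate:::nn_snapshot(c1$model),
                   pulsegate:::nn_snapshot(c2$model))
  expect_identical(c1$history, c2$history)
})

test_that("prediction is deterministic and invariant to clip order", {
  clips <- synthetic_clipset(n_per_class = 8, seed = 6)
  clf <- train_classifier(model_spec("cnn"), clips, NULL,
                          train_config(epochs = 2, seed = 1))
  p1 <- predict(clf, clips)
  p2 <- predict(clf, clips)
  expect_identical(p1$score, p2$score)

  perm <- withr::with_seed(3, sample(nrow(clips)))
  shuffled <- clips[perm, ]
  class(shuffled) <- class(clips)
  p3 <- predict(clf, shuffled)
  expect_equal(p3$score, p1$score[perm], tolerance = 1e-12)
  expect_true(all(p1$decision == (p1$score >= 0.5)))

  # shape contract
  face_only <- subset_regions(clips, "face")
  expect_error(predict(clf, face_only), class = "pg_input_error")
})

test_that("disjoint-video contract and empty splits are enforced", {
  clips <- synthetic_clipset(n_per_class = 6, seed = 8)
  expect_error(
    train_classifier(model_spec("cnn"), clips, clips,
                     train_config(epochs = 1)),
    class = "pg_data_error")
  empty <- clips[0, ]
  class(empty) <- class(clips)
  expect_error(train_classifier(model_spec("cnn"), empty, NULL,
                                train_config(epochs = 1)),
               class = "pg_data_error")
})

test_that("model history is exposed through tidy/glance", {
  clips <- synthetic_clipset(n_per_class = 6, seed = 9)
  clf <- train_classifier(model_spec("cnn"), clips, NULL,
                          train_config(epochs = 2, seed = 1))
  h <- tidy(clf)
  expect_true(all(c("epoch", "train_loss", "val_loss") %in% names(h)))
  g <- glance(clf)
  expect_equal(g$kind, "cnn")
  expect_equal(nrow(g), 1)
})
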