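# Clip classifiers: LSTM, CNN and CRNN over (90, channels) clip tensors,
# jointly or as five per-signal branches fused before the output layer.

#' Classifier architecture specification
#'
#' Three compact architectures over the 90-step clip tensors:
#' * `lstm` - three stacked LSTM layers, a fully connected layer, dropout
#'   0.5, sigmoid output;
#' * `cnn` - five temporal-convolution stages (kernels 7,5,3,3,3; channels
#'   32,64,128,128,64) with batch normalization and two time-halving poolings,
#'   global average pooling, dropout, sigmoid output;
#' * `crnn` - a convolutional front end whose temporal feature map feeds a
#'   two-layer LSTM stack.
#'
#' With `fusion = "per_signal_branches"` five parallel (narrower) branches are
#' built, one per signal type, each seeing that signal's three region
#' channels; their penultimate features are concatenated before the final
#' layer.
#'
#' @param kind `"lstm"`, `"cnn"` or `"crnn"`.
#' @param fusion `"joint"` or `"per_signal_branches"`.
#' @param dropout Dropout rate before the output layer (default 0.5).
#' @param lstm_hidden,lstm_layers LSTM width and depth (joint LSTM model).
#' @param cnn_channels,cnn_kernels Convolution stage widths and kernel sizes
#'   (joint CNN model).
#' @return A list of class `model_spec`.
#' @export
model_spec <- function(kind = c("cnn", "lstm", "crnn"),
                       fusion = c("joint", "per_signal_branches"),
                       dropout = 0.5, lstm_hidden = 32, lstm_layers = 3,
                       cnn_channels = c(32, 64, 128, 128, 64),
                       cnn_kernels = c(7, 5, 3, 3, 3)) {
  kind <- match.arg(kind)
  fusion <- match.arg(fusion)
  if (kind == "lstm" && !(lstm_layers %in% 1:3)) {
    stop_pg("LSTM depth must be 1-3 recurrent layers.", "pg_config_error")
  }
  if (kind == "cnn" && length(cnn_channels) != length(cnn_kernels)) {
    stop_pg("cnn_channels and cnn_kernels must have equal length.",
            "pg_config_error")
  }
  structure(list(kind = kind, fusion = fusion, dropout = dropout,
                 lstm_hidden = lstm_hidden, lstm_layers = lstm_layers,
                 cnn_channels = cnn_channels, cnn_kernels = cnn_kernels),
            class = "model_spec")
}

# Trunk builders return list(layers, feat_dim).
.cnn_trunk <- function(c_in, widths, kernels, pool_after = c(1, 2)) {
  layers <- list()
  prev <- c_in
  for (s in seq_along(widths)) {
    layers <- c(layers, list(nn_conv1d(prev, widths[s], kernels[s]),
                             nn_batchnorm(widths[s]), nn_relu()))
    if (s %in% pool_after) layers <- c(layers, list(nn_maxpool2()))
    prev <- widths[s]
  }
  list(layers = c(layers, list(nn_gap())), feat_dim = prev)
}

.lstm_trunk <- function(c_in, hidden, n_layers) {
  layers <- list()
  prev <- c_in
  for (l in seq_len(n_layers)) {
    layers <- c(layers, list(nn_lstm(prev, hidden,
                                     return_seq = l < n_layers)))
    prev <- hidden
  }
  list(layers = layers, feat_dim = hidden)
}

.crnn_trunk <- function(c_in, conv_widths, conv_kernels, hidden) {
  layers <- list()
  prev <- c_in
  for (s in seq_along(conv_widths)) {
    layers <- c(layers, list(nn_conv1d(prev, conv_widths[s], conv_kernels[s]),
                             nn_batchnorm(conv_widths[s]), nn_relu(),
                             nn_maxpool2()))
    prev <- conv_widths[s]
  }
  layers <- c(layers, list(nn_lstm(prev, hidden, return_seq = TRUE),
                           nn_lstm(hidden, hidden, return_seq = FALSE)))
  list(layers = layers, feat_dim = hidden)
}

#' Build an untrained classifier
#'
#' Constructs the network for a given channel layout. For
#' `per_signal_branches` the input channels must follow the clip-tensor
#' convention (region-major: face, nose, eyes x rPPG, BPM, Y', Cb, Cr), so
#' that branch `s` receives channels `s, s+5, s+10`.
#'
#' @param spec A [model_spec()].
#' @param channels Character vector of input channel names (in clip-tensor
#'   order), e.g. `attr(clips, "channels")`.
#' @param init_seed Seed for the initial weights (retrained models re-seed
#'   from their [train_config()]).
#' @return A list of class `pg_model`.
#' @export
build_model <- function(spec, channels, init_seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  n_ch <- length(channels)
  if (spec$fusion == "per_signal_branches") {
    n_regions <- n_ch / 5L
    if (n_regions != floor(n_regions) || n_regions < 1) {
      stop_pg("Per-signal branches need a multiple of 5 channels.",
              "pg_config_error")
    }
    slices <- lapply(seq_len(5L), function(s) s + 5L * (seq_len(n_regions) - 1L))
    trunk_for <- function(c_in) {
      switch(spec$kind,
        cnn = .cnn_trunk(c_in, c(16, 32, 48), c(7, 5, 3)),
        lstm = .lstm_trunk(c_in, 16, 2),
        crnn = .crnn_trunk(c_in, 16, 5, 24)
      )
    }
    trunks <- lapply(slices, function(sl) trunk_for(length(sl)))
  } else {
    slices <- list(seq_len(n_ch))
    trunks <- list(switch(spec$kind,
      cnn = .cnn_trunk(n_ch, spec$cnn_channels, spec$cnn_kernels),
      lstm = .lstm_trunk(n_ch, spec$lstm_hidden, spec$lstm_layers),
      crnn = .crnn_trunk(n_ch, c(32, 64), c(7, 5), 48)
    ))
  }
  feat_dim <- sum(vapply(trunks, function(t) t$feat_dim, numeric(1)))
  head <- if (spec$kind == "lstm") {
    list(nn_dense(feat_dim, 16), nn_relu(), nn_dropout(spec$dropout),
         nn_dense(16, 1))
  } else {
    list(nn_dropout(spec$dropout), nn_dense(feat_dim, 1))
  }
  model <- structure(list(
    spec = spec, channels = channels, slices = slices,
    branches = lapply(trunks, function(t) t$layers), head = head,
    feat_dims = vapply(trunks, function(t) t$feat_dim, numeric(1))
  ), class = "pg_model")
  with_local_seed(init_seed, nn_init_layers(nn_all_layers(model)))
  model
}

model_forward <- function(model, x, training = FALSE) {
  feats <- lapply(seq_along(model$branches), function(b) {
    xb <- x[, , model$slices[[b]], drop = FALSE]
    seq_forward(model$branches[[b]], xb, training)
  })
  h <- do.call(cbind, feats)
  seq_forward(model$head, h, training)
}

model_backward <- function(model, dlogit) {
  dfeat <- seq_backward(model$head, dlogit)
  ends <- cumsum(model$feat_dims)
  starts <- c(1, head(ends, -1) + 1)
  for (b in seq_along(model$branches)) {
    seq_backward(model$branches[[b]],
                 dfeat[, starts[b]:ends[b], drop = FALSE])
  }
  invisible(NULL)
}

#' Number of trainable parameters of a model
#' @param model A `pg_model` or trained `pg_classifier`.
#' @return Integer parameter count.
#' @export
parameter_count <- function(model) {
  if (inherits(model, "pg_classifier")) model <- model$model
  nn_param_count(model)
}

#' Training configuration
#'
#' @param epochs Maximum epochs (default 40).
#' @param batch_size Minibatch size (default 64).
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param seed Seed fixing initialization, shuffling and dropout.
#' @param patience Early-stopping patience on validation loss (default 10).
#' @param verbose Print one line per epoch.
#' @return A list of class `train_config`.
#' @export
train_config <- function(epochs = 40, batch_size = 64, learning_rate = 1e-3,
                         seed = 1L, patience = 10, verbose = FALSE) {
  structure(list(epochs = epochs, batch_size = batch_size,
                 learning_rate = learning_rate, seed = as.integer(seed),
                 patience = patience, verbose = verbose),
            class = "train_config")
}

# Stack the clip tensors of a clipset into an (n, T, C) array.
clips_to_array <- function(clips) {
  n <- nrow(clips)
  if (n == 0) stop_pg("Empty clip set.", "pg_data_error")
  d <- dim(clips$tensor[[1]])
  x <- array(0, c(n, d[1], d[2]))
  for (i in seq_len(n)) x[i, , ] <- clips$tensor[[i]]
  x
}

.bce_logits <- function(z, y) {
  # numerically stable binary cross-entropy with logits
  mean(pmax(z, 0) - z * y + log1p(exp(-abs(z))))
}

model_scores <- function(model, x, chunk = 512L) {
  n <- dim(x)[1]
  out <- numeric(n)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    z <- model_forward(model, x[idx, , , drop = FALSE], training = FALSE)
    out[idx] <- 1 / (1 + exp(-as.numeric(z)))
  }
  out
}

#' Train a clip classifier
#'
#' Minimizes binary cross-entropy with Adam; keeps the checkpoint with the
#' best validation loss (training loss when no validation set is given) and
#' stops early after `patience` epochs without improvement. Deterministic
#' given the config seed.
#'
#' @param model A `pg_model` from [build_model()], or a [model_spec()] (the
#'   model is then built for the training clips' channels).
#' @param train_clips A `pg_clipset` with `label` in \{0, 1\} (1 = real).
#' @param val_clips Optional validation `pg_clipset`, disjoint by video.
#' @param config A [train_config()].
#' @return A list of class `pg_classifier`: the trained `model`, `history`
#'   tibble (per-epoch losses/accuracies), `best_epoch`, `config`.
#' @export
train_classifier <- function(model, train_clips, val_clips = NULL,
                             config = train_config()) {
  if (inherits(model, "model_spec")) {
    model <- build_model(model, attr(train_clips, "channels") %||%
                           colnames(train_clips$tensor[[1]]))
  }
  if (nrow(train_clips) == 0 ||
      (!is.null(val_clips) && nrow(val_clips) == 0)) {
    stop_pg("Empty train or validation split.", "pg_data_error")
  }
  if (!is.null(val_clips)) {
    overlap <- intersect(unique(train_clips$video_id),
                         unique(val_clips$video_id))
    overlap <- overlap[!is.na(overlap)]
    if (length(overlap) > 0) {
      stop_pg("Train and validation splits share videos.", "pg_data_error")
    }
  }
  x <- clips_to_array(train_clips)
  y <- as.numeric(train_clips$label)
  xv <- if (!is.null(val_clips)) clips_to_array(val_clips)
  yv <- if (!is.null(val_clips)) as.numeric(val_clips$label)
  n <- dim(x)[1]

  history <- list()
  best <- list(loss = Inf, epoch = 0L, params = NULL)
  stale <- 0L
  step <- 0L
  with_local_seed(config$seed, {
    nn_init_layers(nn_all_layers(model))
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- x[idx, , , drop = FALSE]
        yb <- y[idx]
        z <- model_forward(model, xb, training = TRUE)
        loss <- .bce_logits(as.numeric(z), yb)
        dz <- matrix((1 / (1 + exp(-as.numeric(z))) - yb) / length(yb),
                     ncol = 1)
        model_backward(model, dz)
        step <- step + 1L
        nn_adam_step(model, config$learning_rate, step)
        ep_loss <- ep_loss + loss * length(idx)
      }
      ep_loss <- ep_loss / n
      tr_scores <- model_scores(model, x)
      tr_acc <- mean((tr_scores >= 0.5) == (y == 1))
      if (!is.null(val_clips)) {
        vz <- model_scores(model, xv)
        val_loss <- .bce_logits(stats::qlogis(clamp(vz, 1e-12, 1 - 1e-12)), yv)
        val_acc <- mean((vz >= 0.5) == (yv == 1))
      } else {
        val_loss <- ep_loss
        val_acc <- tr_acc
      }
      history[[epoch]] <- tibble(epoch = epoch, train_loss = ep_loss,
                                 train_acc = tr_acc, val_loss = val_loss,
                                 val_acc = val_acc)
      if (config$verbose) {
        message(sprintf(
          "epoch %3d  loss %.4f  acc %.3f  val_loss %.4f  val_acc %.3f",
          epoch, ep_loss, tr_acc, val_loss, val_acc))
      }
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, epoch = epoch,
                     params = nn_snapshot(model))
        stale <- 0L
      } else {
        stale <- stale + 1L
        if (stale >= config$patience) break
      }
      if (tr_acc == 1 && ep_loss < 1e-3) break
    }
  })
  if (!is.null(best$params)) nn_set_params(model, best$params)
  structure(list(model = model, spec = model$spec,
                 channels = model$channels, config = config,
                 history = bind_rows(history), best_epoch = best$epoch),
            class = "pg_classifier")
}

#' Predict clip scores with a trained classifier
#'
#' @param object A `pg_classifier`.
#' @param clips A `pg_clipset` whose tensors match the model's channels.
#' @param tau Decision threshold (default 0.5; `score >= tau` is "real").
#' @param ... Unused.
#' @return The clip tibble (without tensors) plus `score` in \[0, 1\] and
#'   logical `decision`.
#' @export
predict.pg_classifier <- function(object, clips, tau = 0.5, ...) {
  d <- dim(clips$tensor[[1]])
  if (d[2] != length(object$channels)) {
    stop_pg(sprintf("Clip has %d channels; model expects %d.", d[2],
                    length(object$channels)), "pg_input_error")
  }
  x <- clips_to_array(clips)
  scores <- model_scores(object$model, x)
  out <- as_tibble(clips)[, setdiff(names(clips), "tensor")]
  out$score <- scores
  out$decision <- scores >= tau
  out
}

#' @export
print.pg_classifier <- function(x, ...) {
  cat(sprintf(
    "<pg_classifier> %s/%s, %d params, best epoch %d (val loss %.4f)\n",
    x$spec$kind, x$spec$fusion, parameter_count(x), x$best_epoch,
    min(x$history$val_loss)), ...)
  invisible(x)
}

#' @rdname train_classifier
#' @param x A `pg_classifier`.
#' @param ... Unused.
#' @export
tidy.pg_classifier <- function(x, ...) x$history

#' @rdname train_classifier
#' @export
glance.pg_classifier <- function(x, ...) {
  tibble(
    kind = x$spec$kind, fusion = x$spec$fusion,
    parameters = parameter_count(x), epochs = nrow(x$history),
    best_epoch = x$best_epoch,
    val_loss = min(x$history$val_loss),
    val_acc = x$history$val_acc[which.min(x$history$val_loss)]
  )
}
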