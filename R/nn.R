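# Minimal neural-network core for the clip classifiers. Sequence inputs are
# arrays (batch, time, channels); dense features are matrices (batch, feat).
# Each layer is an environment exposing init()/forward()/backward() plus the
# named parameter/gradient lists the Adam step consumes. Everything is double
# precision and deterministic given the R RNG state.

nn_layer <- function(type) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  e$param_names <- character(0)
  e$init <- function() invisible(NULL)
  e
}

nn_dense <- function(n_in, n_out) {
  force(n_in); force(n_out)
  e <- nn_layer("dense")
  e$param_names <- c("W", "b")
  e$init <- function() {
    e$W <- matrix(rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
    e$b <- numeric(n_out)
  }
  e$forward <- function(x, training = FALSE) {
    e$x <- x
    sweep(x %*% e$W, 2, e$b, "+")
  }
  e$backward <- function(dy) {
    e$gW <- crossprod(e$x, dy)
    e$gb <- colSums(dy)
    dy %*% t(e$W)
  }
  e
}

nn_relu <- function() {
  e <- nn_layer("relu")
  e$forward <- function(x, training = FALSE) {
    e$mask <- x > 0
    x * e$mask
  }
  e$backward <- function(dy) dy * e$mask
  e
}

nn_dropout <- function(p = 0.5) {
  force(p)
  e <- nn_layer("dropout")
  e$p <- p
  e$forward <- function(x, training = FALSE) {
    if (!training || p <= 0) {
      e$mask <- NULL
      return(x)
    }
    e$mask <- (runif(length(x)) >= p) / (1 - p)
    x * e$mask
  }
  e$backward <- function(dy) if (is.null(e$mask)) dy else dy * e$mask
  e
}

# 1-D temporal convolution (stride 1, same padding, odd kernel) via im2col.
nn_conv1d <- function(c_in, c_out, kernel) {
  force(c_in); force(c_out)
  stopifnot(kernel %% 2 == 1)
  e <- nn_layer("conv1d")
  e$param_names <- c("W", "b")
  e$init <- function() {
    fan_in <- kernel * c_in
    e$W <- matrix(rnorm(fan_in * c_out, 0, sqrt(2 / fan_in)), fan_in, c_out)
    e$b <- numeric(c_out)
  }
  pad <- (kernel - 1L) %/% 2L
  e$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    n <- dm[1]; Tt <- dm[2]
    xsh <- array(0, c(n, Tt, kernel * c_in))
    for (j in seq_len(kernel)) {
      off <- j - 1L - pad
      tdst <- seq_len(Tt)[seq_len(Tt) + off >= 1 & seq_len(Tt) + off <= Tt]
      xsh[, tdst, (j - 1L) * c_in + seq_len(c_in)] <- x[, tdst + off, ]
    }
    dim(xsh) <- c(n * Tt, kernel * c_in)
    e$xcol <- xsh
    e$in_dim <- dm
    y <- sweep(xsh %*% e$W, 2, e$b, "+")
    dim(y) <- c(n, Tt, c_out)
    y
  }
  e$backward <- function(dy) {
    dm <- e$in_dim
    n <- dm[1]; Tt <- dm[2]
    dym <- dy
    dim(dym) <- c(n * Tt, c_out)
    e$gW <- crossprod(e$xcol, dym)
    e$gb <- colSums(dym)
    dxcol <- dym %*% t(e$W)
    dim(dxcol) <- c(n, Tt, kernel * c_in)
    dx <- array(0, dm)
    for (j in seq_len(kernel)) {
      off <- j - 1L - pad
      tdst <- seq_len(Tt)[seq_len(Tt) + off >= 1 & seq_len(Tt) + off <= Tt]
      dx[, tdst + off, ] <- dx[, tdst + off, ] +
        dxcol[, tdst, (j - 1L) * c_in + seq_len(c_in)]
    }
    dx
  }
  e
}

# Batch normalization over (batch, time) per channel; also accepts matrices.
nn_batchnorm <- function(ch, momentum = 0.9, eps = 1e-5) {
  force(ch); force(momentum); force(eps)
  e <- nn_layer("batchnorm")
  e$param_names <- c("gamma", "beta")
  e$init <- function() {
    e$gamma <- rep(1, ch)
    e$beta <- numeric(ch)
    e$run_mean <- numeric(ch)
    e$run_var <- rep(1, ch)
  }
  flatten <- function(x) {
    dm <- dim(x)
    if (length(dm) == 3L) dim(x) <- c(dm[1] * dm[2], dm[3])
    x
  }
  e$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    xm <- flatten(x)
    if (training) {
      mu <- colMeans(xm)
      xc <- sweep(xm, 2, mu)
      v <- colMeans(xc^2)
      e$run_mean <- momentum * e$run_mean + (1 - momentum) * mu
      e$run_var <- momentum * e$run_var + (1 - momentum) * v
    } else {
      mu <- e$run_mean
      v <- e$run_var
      xc <- sweep(xm, 2, mu)
    }
    istd <- 1 / sqrt(v + eps)
    xhat <- sweep(xc, 2, istd, "*")
    y <- sweep(sweep(xhat, 2, e$gamma, "*"), 2, e$beta, "+")
    e$cache <- list(xhat = xhat, istd = istd, dm = dm,
                    training = training)
    dim(y) <- dm
    y
  }
  e$backward <- function(dy) {
    cc <- e$cache
    dym <- flatten(dy)
    e$ggamma <- colSums(dym * cc$xhat)
    e$gbeta <- colSums(dym)
    m <- nrow(dym)
    dxhat <- sweep(dym, 2, e$gamma, "*")
    if (cc$training) {
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cc$xhat, 2, colMeans(dxhat * cc$xhat), "*")
      dx <- sweep(t1 - t2, 2, cc$istd, "*")
    } else {
      dx <- sweep(dxhat, 2, cc$istd, "*")
    }
    dim(dx) <- cc$dm
    dx
  }
  e
}

# Max pooling over time, factor 2 (odd tail dropped).
nn_maxpool2 <- function() {
  e <- nn_layer("maxpool2")
  e$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    T2 <- dm[2] %/% 2L
    a <- x[, seq(1L, 2L * T2, 2L), , drop = FALSE]
    b <- x[, seq(2L, 2L * T2, 2L), , drop = FALSE]
    e$first <- a >= b
    e$in_dim <- dm
    pmax(a, b)
  }
  e$backward <- function(dy) {
    dm <- e$in_dim
    T2 <- dm[2] %/% 2L
    dx <- array(0, dm)
    dx[, seq(1L, 2L * T2, 2L), ] <- dy * e$first
    dx[, seq(2L, 2L * T2, 2L), ] <- dy * !e$first
    dx
  }
  e
}

# Global average pooling over time: (n, T, C) -> (n, C).
nn_gap <- function() {
  e <- nn_layer("gap")
  e$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    e$in_dim <- dm
    colMeans(aperm(x, c(2, 1, 3)))
  }
  e$backward <- function(dy) {
    dm <- e$in_dim
    aperm(array(dy / dm[2], c(dm[1], dm[3], dm[2])), c(1, 3, 2))
  }
  e
}

# LSTM layer; returns the full sequence or only the last hidden state.
nn_lstm <- function(c_in, hidden, return_seq = FALSE) {
  force(c_in); force(hidden); force(return_seq)
  e <- nn_layer("lstm")
  e$param_names <- c("W", "U", "b")
  H <- hidden
  e$init <- function() {
    s <- 1 / sqrt(H)
    e$W <- matrix(runif(c_in * 4 * H, -s, s), c_in, 4 * H)
    e$U <- matrix(runif(H * 4 * H, -s, s), H, 4 * H)
    b <- numeric(4 * H)
    b[(H + 1):(2 * H)] <- 1  # forget-gate bias
    e$b <- b
  }
  ii <- function(k) ((k - 1) * H + 1):(k * H)
  e$forward <- function(x, training = FALSE) {
    dm <- dim(x)
    n <- dm[1]; Tt <- dm[2]
    h <- matrix(0, n, H)
    cc <- matrix(0, n, H)
    cache <- vector("list", Tt)
    hs <- array(0, c(n, Tt, H))
    for (t in seq_len(Tt)) {
      xt <- matrix(x[, t, ], n, c_in)
      a <- sweep(xt %*% e$W + h %*% e$U, 2, e$b, "+")
      ig <- 1 / (1 + exp(-a[, ii(1), drop = FALSE]))
      fg <- 1 / (1 + exp(-a[, ii(2), drop = FALSE]))
      gg <- tanh(a[, ii(3), drop = FALSE])
      og <- 1 / (1 + exp(-a[, ii(4), drop = FALSE]))
      c_prev <- cc
      cc <- fg * c_prev + ig * gg
      tc <- tanh(cc)
      h_prev <- h
      h <- og * tc
      hs[, t, ] <- h
      cache[[t]] <- list(xt = xt, ig = ig, fg = fg, gg = gg, og = og,
                         c_prev = c_prev, tc = tc, h_prev = h_prev)
    }
    e$cache <- cache
    e$in_dim <- dm
    if (return_seq) hs else h
  }
  e$backward <- function(dy) {
    dm <- e$in_dim
    n <- dm[1]; Tt <- dm[2]
    gW <- matrix(0, c_in, 4 * H)
    gU <- matrix(0, H, 4 * H)
    gb <- numeric(4 * H)
    dh_next <- matrix(0, n, H)
    dc_next <- matrix(0, n, H)
    dx <- array(0, dm)
    for (t in Tt:1) {
      cc <- e$cache[[t]]
      dh <- dh_next
      if (return_seq) dh <- dh + matrix(dy[, t, ], n, H)
      else if (t == Tt) dh <- dh + dy
      do_ <- dh * cc$tc
      dc <- dc_next + dh * cc$og * (1 - cc$tc^2)
      di <- dc * cc$gg
      dg <- dc * cc$ig
      df <- dc * cc$c_prev
      dc_next <- dc * cc$fg
      da <- cbind(di * cc$ig * (1 - cc$ig),
                  df * cc$fg * (1 - cc$fg),
                  dg * (1 - cc$gg^2),
                  do_ * cc$og * (1 - cc$og))
      gW <- gW + crossprod(cc$xt, da)
      gU <- gU + crossprod(cc$h_prev, da)
      gb <- gb + colSums(da)
      dx[, t, ] <- da %*% t(e$W)
      dh_next <- da %*% t(e$U)
    }
    e$gW <- gW
    e$gU <- gU
    e$gb <- gb
    dx
  }
  e
}

seq_forward <- function(layers, x, training = FALSE) {
  for (ly in layers) x <- ly$forward(x, training)
  x
}

seq_backward <- function(layers, dy) {
  for (ly in rev(layers)) dy <- ly$backward(dy)
  dy
}

nn_init_layers <- function(layers) {
  for (ly in layers) ly$init()
  invisible(NULL)
}

nn_all_layers <- function(model) {
  c(unlist(model$branches, recursive = FALSE), model$head)
}

nn_get_params <- function(model) {
  lapply(nn_all_layers(model), function(ly) {
    stats::setNames(lapply(ly$param_names, function(p) get(p, envir = ly)),
                    ly$param_names)
  })
}

nn_set_params <- function(model, params) {
  layers <- nn_all_layers(model)
  for (i in seq_along(layers)) {
    for (p in layers[[i]]$param_names) {
      assign(p, params[[i]][[p]], envir = layers[[i]])
    }
    # batch-norm running stats travel with the snapshot
    if (!is.null(params[[i]][[".run_mean"]])) {
      layers[[i]]$run_mean <- params[[i]][[".run_mean"]]
      layers[[i]]$run_var <- params[[i]][[".run_var"]]
    }
  }
  invisible(model)
}

nn_snapshot <- function(model) {
  lapply(nn_all_layers(model), function(ly) {
    out <- stats::setNames(lapply(ly$param_names, function(p)
      get(p, envir = ly)), ly$param_names)
    if (ly$type == "batchnorm") {
      out$.run_mean <- ly$run_mean
      out$.run_var <- ly$run_var
    }
    out
  })
}

# One Adam update over every parameter of the model.
nn_adam_step <- function(model, lr, t, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8) {
  for (ly in nn_all_layers(model)) {
    for (p in ly$param_names) {
      g <- get(paste0("g", p), envir = ly)
      st <- ly$adam[[p]]
      if (is.null(st)) st <- list(m = g * 0, v = g * 0)
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      if (is.null(ly$adam)) ly$adam <- list()
      ly$adam[[p]] <- st
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      assign(p, get(p, envir = ly) - lr * mhat / (sqrt(vhat) + eps),
             envir = ly)
    }
  }
  invisible(model)
}

nn_param_count <- function(model) {
  sum(vapply(nn_all_layers(model), function(ly) {
    sum(vapply(ly$param_names, function(p) length(get(p, envir = ly)),
               numeric(1)))
  }, numeric(1)))
}
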