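# Sparse pyramidal Lucas-Kanade optical flow. Only what the screening stage
# needs: track a handful of points frame-to-frame with subpixel accuracy.
# Vectorized over points and window pixels.

to_gray <- function(frame) {
  0.299 * frame[, , 1] + 0.587 * frame[, , 2] + 0.114 * frame[, , 3]
}

# 2x2 block-average downsampling (crops a trailing odd row/column).
downsample2 <- function(img) {
  h <- 2L * (nrow(img) %/% 2L)
  w <- 2L * (ncol(img) %/% 2L)
  img <- img[seq_len(h), seq_len(w)]
  (img[seq(1, h, 2), seq(1, w, 2)] + img[seq(2, h, 2), seq(1, w, 2)] +
     img[seq(1, h, 2), seq(2, w, 2)] + img[seq(2, h, 2), seq(2, w, 2)]) / 4
}

build_pyramid <- function(gray, levels) {
  pyr <- vector("list", levels)
  pyr[[1]] <- gray
  for (l in seq_len(levels - 1L)) {
    if (min(dim(pyr[[l]])) < 16) {
      pyr <- pyr[seq_len(l)]
      break
    }
    pyr[[l + 1L]] <- downsample2(pyr[[l]])
  }
  pyr
}

central_gradients <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  gx <- matrix(0, h, w)
  gy <- matrix(0, h, w)
  gx[, 2:(w - 1)] <- (img[, 3:w] - img[, 1:(w - 2)]) / 2
  gy[2:(h - 1), ] <- (img[3:h, ] - img[1:(h - 2), ]) / 2
  list(gx = gx, gy = gy)
}

# Refine displacements `d` (n x 2) for all points at one pyramid level.
# Returns list(d, ok): `ok[p]` FALSE when the point left the image or sits on
# a textureless (aperture-degenerate) patch.
.lk_level <- function(I, grad, J, x, y, d, win, max_iter = 6L, eps = 0.03) {
  r <- win %/% 2L
  offs <- expand.grid(ox = -r:r, oy = -r:r)
  n <- length(x)
  K <- nrow(offs)
  Px <- outer(x, rep(1, K)) + matrix(offs$ox, n, K, byrow = TRUE)
  Py <- outer(y, rep(1, K)) + matrix(offs$oy, n, K, byrow = TRUE)
  ip <- matrix(bilinear_sample(I, as.vector(Px), as.vector(Py)), n, K)
  ix <- matrix(bilinear_sample(grad$gx, as.vector(Px), as.vector(Py)), n, K)
  iy <- matrix(bilinear_sample(grad$gy, as.vector(Px), as.vector(Py)), n, K)
  valid <- !is.na(ip)
  ip[!valid] <- 0
  ix[is.na(ix)] <- 0
  iy[is.na(iy)] <- 0
  ok <- rowMeans(valid) >= 0.5
  gxx <- rowSums(ix * ix)
  gxy <- rowSums(ix * iy)
  gyy <- rowSums(iy * iy)
  det <- gxx * gyy - gxy^2
  ok <- ok & det > 1e-6 * K
  det[!ok] <- 1
  for (it in seq_len(max_iter)) {
    jp <- matrix(bilinear_sample(J, as.vector(Px + d[, 1]),
                                 as.vector(Py + d[, 2])), n, K)
    jvalid <- valid & !is.na(jp)
    jp[is.na(jp)] <- 0
    ok <- ok & rowMeans(jvalid) >= 0.5
    e <- (ip - jp) * jvalid
    bx <- rowSums(e * ix)
    by <- rowSums(e * iy)
    ddx <- (gyy * bx - gxy * by) / det
    ddy <- (gxx * by - gxy * bx) / det
    ddx[!ok] <- 0
    ddy[!ok] <- 0
    d <- d + cbind(ddx, ddy)
    if (all(abs(ddx) < eps & abs(ddy) < eps)) break
  }
  list(d = d, ok = ok)
}

# Track points (0-based n x 2 matrix) from frame I to frame J through a
# pyramid. Returns an n x 2 matrix of new positions; NA rows = lost points.
# Small displacements (the common, genuine case) are resolved on the finest
# level only; the full coarse-to-fine pass runs when any point moves far.
lk_track_points <- function(pyr_i, grads_i, pyr_j, pts, win = 15L) {
  levels <- min(length(pyr_i), length(pyr_j))
  active <- !is.na(pts[, 1])
  out <- matrix(NA_real_, nrow(pts), 2)
  if (!any(active)) return(out)
  x <- pts[active, 1]
  y <- pts[active, 2]

  fine <- .lk_level(pyr_i[[1]], grads_i[[1]], pyr_j[[1]], x, y,
                    matrix(0, length(x), 2), win = win)
  small <- all(fine$ok) && all(abs(fine$d) <= 2)
  if (small || levels == 1L) {
    d <- fine$d
    ok_fine <- fine$ok
  } else {
    d <- matrix(0, length(x), 2)
    ok_fine <- rep(TRUE, length(x))
    for (l in levels:1) {
      s <- 2^(l - 1)
      res <- .lk_level(pyr_i[[l]], grads_i[[l]], pyr_j[[l]],
                       x / s, y / s, d / s, win = win)
      # keep the coarser estimate for points failing at this level; failure
      # at the finest level means the point is lost
      d[res$ok, ] <- res$d[res$ok, , drop = FALSE] * s
      if (l == 1) ok_fine <- res$ok
    }
  }
  new_pts <- cbind(x, y) + d
  new_pts[!ok_fine, ] <- NA_real_
  out[active, ] <- new_pts
  out
}
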