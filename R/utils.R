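# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All stochastic package code funnels through this so
# that a scene/config seed fully determines the output.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= 0
}

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_pg <- function(msg, class) {
  abort(msg, class = c(class, "pulsegate_error"))
}

# Bilinear interpolation of a matrix `img` (rows = y, cols = x) at fractional
# 0-based coordinates. Out-of-range queries return NA.
bilinear_sample <- function(img, x, y) {
  h <- nrow(img)
  w <- ncol(img)
  x0 <- floor(x)
  y0 <- floor(y)
  fx <- x - x0
  fy <- y - y0
  ok <- x0 >= 0 & y0 >= 0 & x0 <= w - 2 & y0 <= h - 2
  out <- rep(NA_real_, length(x))
  if (any(ok)) {
    base <- x0[ok] * h + y0[ok] + 1  # linear index of (y0+1, x0+1)
    v00 <- img[base]
    v10 <- img[base + 1]
    v01 <- img[base + h]
    v11 <- img[base + h + 1]
    fxo <- fx[ok]
    fyo <- fy[ok]
    out[ok] <- (1 - fyo) * ((1 - fxo) * v00 + fxo * v01) +
      fyo * ((1 - fxo) * v10 + fxo * v11)
  }
  out
}
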