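# Color conversion, skin masking and per-region mean signals.

test_that("rgb_to_ycbcr matches an independent matrix oracle", {
  # Oracle: coefficients written out independently of the implementation.
  oracle <- function(rgb) {
    y <- 16 + 65.481 * rgb[, 1] + 128.553 * rgb[, 2] + 24.966 * rgb[, 3]
    cb <- 128 - 37.797 * rgb[, 1] - 74.203 * rgb[, 2] + 112.0 * rgb[, 3]
    cr <- 128 + 112.0 * rgb[, 1] - 93.786 * rgb[, 2] - 18.214 * rgb[, 3]
    cbind(y, cb, cr)
  }
  set.seed(7)
  px <- matrix(runif(3000), ncol = 3)
  got <- rgb_to_ycbcr(px)
  expect_lt(max(abs(got - oracle(px))), 1e-9)

  # gray axis: zero input leaves the offsets, white hits the 219 swing
  expect_equal(as.numeric(rgb_to_ycbcr(matrix(0, 1, 3))), c(16, 128, 128))
  expect_equal(as.numeric(rgb_to_ycbcr(matrix(1, 1, 3))), c(235, 128, 128))
  expect_equal(as.numeric(rgb_to_ycbcr(matrix(0.5, 1, 3))),
               c(125.5, 128, 128))
})

test_that("rgb_to_ycbcr preserves array shape and rejects bad domains", {
  arr <- array(runif(4 * 5 * 3), c(4, 5, 3))
  out <- rgb_to_ycbcr(arr)
  expect_equal(dim(out), dim(arr))
  expect_error(rgb_to_ycbcr(arr * 300), class = "pg_domain_error")
  expect_error(rgb_to_ycbcr(matrix(1, 2, 2)), class = "pg_domain_error")
})

test_that("skin mask applies the static chroma bands with inclusive bounds", {
  px <- function(cb, cr) matrix(c(150, cb, cr), 1, 3)
  expect_true(skin_mask(px(150, 100))$mask)   # mid-band
  expect_false(skin_mask(px(132, 100))$mask)  # just below Cb lower bound
  expect_true(skin_mask(px(133, 100))$mask)   # inclusive lower Cb
  expect_true(skin_mask(px(173, 127))$mask)   # inclusive upper corners
  expect_true(skin_mask(px(150, 77))$mask)    # inclusive lower Cr
  expect_false(skin_mask(px(174, 100))$mask)
  expect_false(skin_mask(px(150, 128))$mask)

  # frame entirely inside the thresholds has skin_fraction 1
  arr <- array(0, c(6, 8, 3))
  arr[, , 1] <- 170
  arr[, , 2] <- 150
  arr[, , 3] <- 100
  expect_equal(skin_mask(arr)$skin_fraction, 1)
})

test_that("region means of a uniform skin-colored video equal the pixel value", {
  skin_rgb <- round(pulsegate:::.face_base_rgb())
  v <- flat_video(skin_rgb)
  sig <- region_mean_signals(v)
  expect_true(all(sig$valid))
  for (r in c("face", "nose", "eyes")) {
    d <- sig[sig$region == r, ]
    expect_equal(d$mean_r, rep(skin_rgb[1], 3))
    expect_equal(d$mean_g, rep(skin_rgb[2], 3))
    expect_equal(d$mean_b, rep(skin_rgb[3], 3))
  }
  # and the YCbCr means are the converted pixel
  ycc <- rgb_to_ycbcr(matrix(skin_rgb / 255, 1, 3))
  expect_equal(sig$mean_y[1], unname(ycc[1, 1]))
  expect_equal(sig$mean_cb[1], unname(ycc[1, 2]))
})

test_that("regions with no skin pixels are an extraction error", {
  v <- flat_video(c(128, 128, 128))  # achromatic: Cb = Cr = 128, not skin
  expect_error(region_mean_signals(v), class = "pg_extraction_error")
})

test_that("short invalid gaps are interpolated, long ones are an error", {
  skin_rgb <- round(pulsegate:::.face_base_rgb())
  v <- flat_video(skin_rgb, n_frames = 12)
  # frames 5-6 lose all skin (achromatic)
  for (t in 5:6) v$frames[[t]][] <- 128
  sig <- region_mean_signals(v)
  face <- sig[sig$region == "face", ]
  expect_false(any(face$valid[5:6]))
  expect_equal(face$mean_g[5], skin_rgb[2])  # interpolated across the gap
  # a gap longer than max_gap aborts
  for (t in 3:9) v$frames[[t]][] <- 128
  expect_error(region_mean_signals(v), class = "pg_extraction_error")
})
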