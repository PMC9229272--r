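test_that("log luminance map fixes the endpoints and the analytic midpoint", {
  m <- matrix(c(0, 15, 255), 1)
  out <- log_luminance_map(m, N = 256)
  expect_equal(out[1], 0)                         # log(1) = 0
  expect_equal(out[3], 255)                       # 255*log(256)/log(256)
  expect_equal(out[2], 255 * log(16) / log(256))  # = 127.5
  expect_equal(out[2], 127.5)
})

test_that("gamma correction matches its closed form and is monotone", {
  img <- matrix(runif(256, 0, 255), 16)
  expect_equal(gamma_correct(img, 1), img)
  expect_equal(gamma_correct(matrix(63.75), 0.5), matrix(127.5))
  g <- gamma_correct(img, 0.4)
  expect_identical(order(img), order(g))  # no ordering inversion
  expect_error(gamma_correct(img, 0), "positive")
})

test_that("gamma < 1 pulls the corner/centre brightness ratio toward 1", {
  img <- frame_cellfree(strength = 0.3, noise_sigma = 0)
  ratio <- function(m) m[1, 1] / m[48, 48]
  expect_gt(ratio(gamma_correct(img, 0.5)), ratio(img))
  expect_lt(ratio(gamma_correct(img, 0.5)), 1)
})

test_that("piecewise stretch interpolates linearly and stays monotone", {
  levels <- matrix(0:255, 16)
  expect_equal(piecewise_linear_stretch(levels, a = 50, b = 150, y_a = 50, y_b = 150),
               levels)  # breakpoints on the diagonal: identity
  expect_equal(piecewise_linear_stretch(matrix(100), 50, 150, 20, 235)[1], 127.5)
  set.seed(42)
  for (i in 1:20) {
    ab <- sort(sample(1:254, 2))
    yy <- sort(stats::runif(2, 0, 255))
    out <- piecewise_linear_stretch(levels, ab[1], ab[2], yy[1], yy[2])
    expect_true(all(diff(as.vector(out)) >= -1e-9))
    expect_true(all(out >= 0 & out <= 255))
  }
  expect_error(piecewise_linear_stretch(levels, 100, 100, 0, 255), "a < b")
})

test_that("min-max stretch hits the target endpoints and is idempotent", {
  img <- matrix(seq(10, 90, by = 10), 3, 3)
  out <- minmax_stretch(img, 0, 255)
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  expect_equal(out[img == 50][1], (50 - 10) / 80 * 255)  # 127.5
  expect_equal(minmax_stretch(out, 0, 255), out)          # idempotence
  full <- matrix(c(0, 100, 255), 1)
  expect_equal(minmax_stretch(full, 0, 255), full)        # already spanning
  expect_error(minmax_stretch(matrix(5, 2, 2), 0, 255), "constant")
})

test_that("gain application is a clipped pixelwise product", {
  img <- matrix(c(100, 200), 1)
  expect_equal(correct_vignette(img, matrix(1, 1, 2)), img)
  out <- correct_vignette(img, matrix(1.5, 1, 2))
  expect_equal(out[1], 150)
  expect_equal(out[2], 255)  # 300 clipped
  expect_error(correct_vignette(img, matrix(1, 2, 2)), "shape")
  expect_error(correct_vignette(img, matrix(c(1, -1), 1)), "positive")
})

test_that("entropy-minimisation gain is ~1 on a flat image", {
  set.seed(7)
  img <- matrix(140 + rnorm(96 * 96, 0, 2), 96)
  g <- estimate_vignette_gain(img)
  expect_lt(max(abs(g - 1)), 0.05)
})

test_that("entropy-minimisation recovers a known radial gain within 5% at the corner", {
  set.seed(8)
  flat <- matrix(150 + rnorm(96 * 96, 0, 2), 96)
  g_true <- 1 / vignette_field(96, 96, 0.3)  # true corrective gain, corner 1/0.7
  observed <- flat / g_true
  g_hat <- estimate_vignette_gain(observed)
  expect_lt(abs(g_hat[1, 1] - g_true[1, 1]) / g_true[1, 1], 0.05)
  expect_lt(abs(g_hat[96, 96] - g_true[96, 96]) / g_true[96, 96], 0.05)
  # the objective actually decreased
  expect_lt(attr(g_hat, "entropy"), rotospin:::log_hist_entropy(observed))
})

test_that("preprocessing preserves shape and the [0,255] range", {
  img <- frame_cellfree(strength = 0.3, noise_sigma = 3)
  for (out in list(log_luminance_map(img), gamma_correct(img, 0.4),
                   piecewise_linear_stretch(img, 60, 180, 20, 235),
                   minmax_stretch(img), preprocess_frame(img))) {
    expect_identical(dim(out), dim(img))
    expect_gte(min(out), 0)
    expect_lte(max(out), 255)
  }
})
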