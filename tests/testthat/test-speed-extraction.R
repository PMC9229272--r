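as_series <- function(x, fps = 15) {
  s <- tibble::tibble(frame = seq_along(x), area = x)
  attr(s, "fps") <- fps
  s
}

test_that("uniform-kernel smoothing preserves length and mean exactly", {
  set.seed(21)
  x <- 100 + rnorm(60, 0, 5)
  for (w in c(1, 3, 5, 9)) {
    sm <- smooth_series(as_series(x), w)
    expect_equal(nrow(sm), 60)
    expect_equal(mean(sm$area), mean(x))  # mirror padding conserves the sum
  }
  expect_equal(smooth_series(as_series(x), 1)$area, x)          # identity
  const <- smooth_series(as_series(rep(7, 20)), 5)
  expect_equal(const$area, rep(7, 20))                          # constant fixed
  expect_error(smooth_series(as_series(x), 4), "odd")
})

test_that("smoothing suppresses an impulse without displacing sinusoid troughs", {
  t <- 1:50
  clean <- 100 + 20 * sin(2 * pi * t / 10)
  noisy <- clean
  noisy[23] <- noisy[23] + 30  # impulse
  sm <- smooth_series(as_series(noisy), 3)$area
  expect_lt(max(abs(sm - smooth_series(as_series(clean), 3)$area)), 30 / 3 + 1e-9)
  tr_clean <- find_troughs(as_series(clean), min_separation = 5)
  tr_sm <- find_troughs(as_series(sm), min_separation = 5)
  expect_equal(length(tr_clean), length(tr_sm))
  expect_true(all(abs(tr_clean - tr_sm) <= 1))
})

test_that("troughs of a pure sinusoid are spaced exactly one period apart", {
  t <- 1:50
  y <- 100 + 20 * sin(2 * pi * t / 10)
  troughs <- find_troughs(as_series(y), min_separation = 5)
  expect_true(all(diff(troughs) == 10))
  # closed-form minima of sin at t = 7.5 + 10k: nearest samples are 7/8 ties,
  # 17/18 ties, ... the plateau rule takes the centre (the earlier sample)
  expect_equal(troughs[1], 7)
})

test_that("monotone series and constant series yield no measurable troughs", {
  expect_error(find_troughs(as_series(1:30)), class = "rotospin_no_troughs")
  expect_error(find_troughs(as_series(rep(5, 30))), class = "rotospin_no_troughs")
})

test_that("a flat-bottomed (plateau) trough is counted once, at its centre", {
  y <- c(10, 8, 5, 5, 5, 8, 10, 9, 4, 9, 10)
  troughs <- find_troughs(as_series(y), min_separation = 2, min_prominence = 1)
  expect_equal(troughs, c(4L, 9L))
})

test_that("trough spacing converts to rpm by 60*fps/spacing", {
  res <- rotation_speed(c(10, 19), fps = 15)
  expect_equal(res$mean_rpm, 100)           # 60*15/9
  expect_equal(res$n_cycles, 1)
  res2 <- rotation_speed(c(5, 10, 15, 20), fps = 15)
  expect_equal(res2$per_cycle_rpm, rep(180, 3))
  expect_equal(res2$max_deviation_rpm, 0)   # equal spacings
  expect_equal(res2$mean_rpm_pooled, 180)
  # symmetry factor 2 halves every speed
  res3 <- rotation_speed(c(10, 19), fps = 15, symmetry_factor = 2)
  expect_equal(res3$mean_rpm, 50)
  expect_error(rotation_speed(c(19, 10), fps = 15), "increasing")
  expect_error(rotation_speed(7, fps = 15), "increasing|>= 2")
})

test_that("mixed spacings reproduce hand-computed per-cycle speeds", {
  res <- rotation_speed(c(3, 8, 14, 19, 24), fps = 15)
  expect_equal(res$per_cycle_rpm, c(180, 150, 180, 180))
  expect_equal(res$mean_rpm, mean(c(180, 150, 180, 180)))
  expect_equal(res$max_deviation_rpm, max(abs(c(180, 150, 180, 180) - 172.5)))
  expect_equal(res$mean_rpm_pooled, 60 * 15 * 4 / 21)
})

test_that("tidy and glance expose the per-cycle table and the summary row", {
  res <- rotation_speed(c(3, 8, 14, 19, 24), fps = 15)
  td <- tidy(res)
  expect_equal(nrow(td), 4)
  expect_equal(td$spacing_frames, c(5, 6, 5, 5))
  expect_equal(td$rpm, res$per_cycle_rpm)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$mean_rpm, res$mean_rpm)
  expect_equal(gl$n_cycles, 4)
})

test_that("end-to-end estimates stay within the trough-quantization bound", {
  for (case in list(list(rpm = 60, seed = 1), list(rpm = 120, seed = 2))) {
    sc <- scene_reference(rpm = case$rpm, seed = case$seed)
    res <- measure_rotation(sc$frames, seed_point = c(48, 48), symmetry_factor = 2)
    expect_lt(abs(res$mean_rpm - case$rpm) / case$rpm, 0.07)
  }
})

test_that("doubling the frame rate leaves the estimated rpm unchanged", {
  est <- function(fps) {
    sc <- render_video(scene_config(
      n_frames = 10 * fps, fps = fps,
      cells = list(cell_spec(semi_axes = c(12, 12, 8), rotation_rpm = 86)),
      rng_seed = 3))
    measure_rotation(sc$frames, seed_point = c(48, 48), symmetry_factor = 2)$mean_rpm
  }
  expect_lt(abs(est(15) - est(30)) / 86, 0.05)
})
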