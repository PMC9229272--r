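test_that("a sphere's projected outline area is constant and close to pi*a^2", {
  sc <- scene_clean(list(cell_spec(semi_axes = c(10, 10, 10), rotation_rpm = 120)),
                    n_frames = 15)
  expect_length(unique(sc$truth$area_px), 1)
  expect_lt(abs(sc$truth$area_px[1] - pi * 10^2), 6)  # rasterization band
})

test_that("ellipsoid projection follows sqrt(a^2 cos^2 + c^2 sin^2) at the poles", {
  # theta = 0: semi-axes (10, 10); theta = pi/2: (10, 6)
  at_phase <- function(phase) {
    sc <- scene_clean(list(cell_spec(semi_axes = c(10, 10, 6), rotation_rpm = 0,
                                     phase0 = phase)), n_frames = 2)
    sc$truth$area_px[1]
  }
  expect_lt(abs(at_phase(0) - pi * 10 * 10), 6)
  expect_lt(abs(at_phase(pi / 2) - pi * 10 * 6), 6)
  # intermediate angle matches the closed form too
  th <- pi / 5
  expect_lt(abs(at_phase(th) - pi * 10 * sqrt(100 * cos(th)^2 + 36 * sin(th)^2)), 6)
})

test_that("zero vignette strength leaves corners as bright as the centre", {
  cfg <- scene_config(cells = list(), vignette_strength = 0, noise_sigma = 0,
                      n_debris = 0, rng_seed = 1)
  img <- render_frame(cfg, 1)
  expect_equal(img[1, 1], img[48, 48])
  expect_equal(length(unique(as.vector(img))), 1L)
})

test_that("the vignette field is quadratic with the stated corner falloff", {
  g <- vignette_field(96, 96, 0.3)
  expect_equal(g[1, 1], 0.7)
  expect_equal(g[96, 96], 0.7)
  ctr <- (1 + 96) / 2
  expect_equal(max(g), 1 - 0.3 * (2 * (48 - ctr)^2) / (2 * (1 - ctr)^2))
})

test_that("rotation phase advances 2*pi*rpm/(60*fps) per frame", {
  sc <- scene_reference(rpm = 86, seed = 2, n_frames = 12)
  expect_equal(unique(round(diff(sc$truth$angle_rad), 12)),
               round(2 * pi * 86 / 900, 12))
  # 86 rpm at 15 fps: one revolution every ~10.465 frames
  expect_equal(2 * pi / (2 * pi * 86 / 900), 900 / 86)
})

test_that("area repeat period is half a revolution for a bare ellipsoid, full with a spot", {
  expect_equal(scene_reference(rpm = 86, seed = 1, n_frames = 2)$area_period_frames,
               900 / 86 / 2)
  expect_equal(scene_spot_sphere(rpm = 90, seed = 1, n_frames = 2)$area_period_frames,
               900 / 90)
})

test_that("rpm = 0 gives identical frames up to noise and constant truth area", {
  sc <- scene_clean(list(cell_spec(rotation_rpm = 0)), n_frames = 5)
  expect_length(unique(sc$truth$area_px), 1)
  expect_identical(sc$frames$frames[[1]], sc$frames$frames[[5]])
})

test_that("rendering is bit-identical for identical configs and seeds", {
  cfg <- scene_config(n_frames = 6, rng_seed = 11)
  a <- render_video(cfg)
  b <- render_video(cfg)
  expect_identical(a$frames$frames, b$frames$frames)
  expect_identical(a$truth, b$truth)
  # a different seed changes the pixels
  c <- render_video(scene_config(n_frames = 6, rng_seed = 12))
  expect_false(identical(a$frames$frames[[1]], c$frames$frames[[1]]))
  # render_frame reproduces render_video's frames one by one
  expect_identical(render_frame(cfg, 3), a$frames$frames[[3]])
})

test_that("midpoint thresholding of a clean render recovers the true area exactly", {
  sc <- scene_clean(list(cell_spec(semi_axes = c(11, 11, 7), rotation_rpm = 86)),
                    n_frames = 8)
  cfg_mid <- (140 + 185) / 2
  for (t in c(1, 4, 8)) {
    mask <- binarize(sc$frames$frames[[t]], cfg_mid)
    expect_equal(sum(mask), sc$truth$area_px[t])
  }
})

test_that("cells translate at the configured velocity and orbit", {
  sc <- scene_clean(list(cell_spec(rotation_rpm = 0, centroid = c(20, 20),
                                   velocity = c(0.5, 1))), n_frames = 10)
  expect_equal(sc$truth$row, 20 + 0.5 * (0:9))
  expect_equal(sc$truth$col, 20 + 1 * (0:9))
  orb <- scene_clean(list(cell_spec(rotation_rpm = 0, centroid = c(32, 32),
                                    orbit_radius = 8, orbit_period = 12)),
                     n_frames = 13)
  expect_equal(orb$truth$row[1], 32)  # path starts at the stated centroid
  expect_equal(orb$truth$col[1], 32)
  expect_equal(orb$truth$row[13], 32, tolerance = 1e-10)  # closes after a period
  steps <- sqrt(diff(orb$truth$row)^2 + diff(orb$truth$col)^2)
  expect_true(all(abs(steps - 2 * 8 * sin(pi / 12)) < 1e-9))
})
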