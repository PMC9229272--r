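# exhaustive-search oracle: between-class variance computed directly for
# every candidate threshold, independent of the cumulative-sum implementation
otsu_brute_force <- function(image) {
  v <- pmin(pmax(round(as.vector(image)), 0), 255)
  best_t <- NA_integer_
  best_s <- -Inf
  for (t in 0:254) {
    bg <- v[v <= t]; fg <- v[v > t]
    if (length(bg) == 0 || length(fg) == 0) next
    w0 <- length(bg) / length(v)
    s <- w0 * (1 - w0) * (mean(bg) - mean(fg))^2
    if (s > best_s + 1e-12) {  # strict improvement => smallest-t tie-break
      best_s <- s
      best_t <- t
    }
  }
  best_t
}

test_that("otsu threshold equals the exhaustive oracle on random and structured images", {
  set.seed(101)
  for (i in 1:20) {
    img <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64)
    expect_identical(as.integer(otsu_threshold(img)), otsu_brute_force(img))
  }
  # bimodal: 100 px at 50, 100 px at 200 -> any split works, smallest wins
  bim <- matrix(c(rep(50, 100), rep(200, 100)), 20)
  expect_identical(as.integer(otsu_threshold(bim)), 50L)
  expect_identical(otsu_brute_force(bim), 50L)
  # structured: gradient plus bright blob
  grad <- matrix(rep(seq(20, 120, length.out = 64), 64), 64, byrow = TRUE)
  grad[20:30, 20:30] <- 230
  expect_identical(as.integer(otsu_threshold(grad)), otsu_brute_force(grad))
  expect_error(otsu_threshold(matrix(7, 4, 4)), "distinct")
})

test_that("binarize partitions the image at the threshold", {
  img <- matrix(c(0, 10, 128, 255), 2)
  expect_equal(sum(binarize(img, 255)), 0)
  expect_equal(sum(binarize(img, 0) == 0) + sum(binarize(img, 0) == 1), 4)
  m <- binarize(img, 100)
  expect_equal(sum(m) + sum(m == 0), length(img))
  expect_equal(sum(m), 2)
})

test_that("small-object removal deletes only sub-threshold components", {
  mask <- matrix(0L, 20, 20)
  mask[2:4, 2] <- 1L                 # area 3
  mask[8:17, 6:17] <- 1L             # area 120
  out <- remove_small_objects(mask, 10)
  expect_equal(sum(out), 120)
  expect_true(all(out[8:17, 6:17] == 1L))
  expect_identical(remove_small_objects(mask, 0), mask)
  expect_true(all(out <= mask))      # monotone removal
})

test_that("disk dilation of a point gives the plus-shaped element and is extensive", {
  mask <- matrix(0L, 5, 5); mask[3, 3] <- 1L
  out <- dilate_mask(mask, 1)
  expect_equal(sum(out), 5)
  expect_equal(out[2:4, 3], rep(1L, 3))
  expect_equal(out[3, 2:4], rep(1L, 3))
  expect_identical(dilate_mask(mask, 0), mask)
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(rbinom(100, 1, 0.2), 10)
    d <- dilate_mask(m, sample(1:2, 1))
    expect_true(all(d >= m))  # foreground only grows
  }
})

test_that("connected-domain labelling is 8-connected with exact measurements", {
  expect_equal(nrow(label_components(matrix(0L, 5, 5))), 0)
  mask <- matrix(0L, 10, 12)
  mask[2:4, 2:4] <- 1L
  mask[6:8, 8:10] <- 1L
  det <- label_components(mask)
  expect_equal(nrow(det), 2)
  expect_equal(det$area, c(9L, 9L))
  expect_equal(det$centroid_row, c(3, 7))
  expect_equal(det$centroid_col, c(3, 9))
  expect_equal(det$row0, c(2L, 6L))
  expect_equal(det$height, c(3L, 3L))
  # diagonal touch = one component (8-connectivity)
  diagm <- matrix(0L, 4, 4); diagm[1, 1] <- 1L; diagm[2, 2] <- 1L
  expect_equal(nrow(label_components(diagm)), 1)
  expect_equal(label_components(diagm)$area, 2L)
})

test_that("detection areas sum to the mask's foreground pixel count", {
  set.seed(12)
  for (i in 1:5) {
    m <- matrix(rbinom(400, 1, 0.3), 20)
    det <- label_components(m)
    expect_equal(sum(det$area), sum(m))
    lab <- attr(det, "label_matrix")
    expect_equal(sum(lab > 0), sum(m))
  }
})

test_that("the full segmentation stage finds exactly the rendered cells", {
  sc <- render_video(scene_config(
    width = 120, height = 96, n_frames = 2,
    cells = list(cell_spec(centroid = c(30, 30)),
                 cell_spec(centroid = c(60, 85), semi_axes = c(10, 10, 10))),
    vignette_strength = 0.2, noise_sigma = 2, n_debris = 4, rng_seed = 9))
  det <- segment_frame(preprocess_frame(sc$frames$frames[[1]]))
  expect_equal(nrow(det), 2)  # debris blobs removed by the area cutoff
  # detected area close to truth: dilation adds at most a one-pixel band
  d1 <- select_cell(det, seed_point = c(30, 30))
  perim <- 2 * pi * 12
  expect_lt(abs(d1$area - sc$truth$area_px[1]), perim * 1 + 10)
})
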