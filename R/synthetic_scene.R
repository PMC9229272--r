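#' Specify one synthetic cell
#'
#' Describes a triaxial ellipsoid cell (semi-axes `a`, `b`, `c` in pixels;
#' `a = b = c` gives a sphere) rotating at a fixed speed, optionally
#' translating. Two rotation geometries are rendered:
#'
#' * `out_of_plane`: the rotation axis lies in the image plane (along image
#'   rows). The projected outline is an ellipse whose semi-axis along the
#'   rotation-varying direction is `sqrt(a^2 cos^2(theta) + c^2 sin^2(theta))`,
#'   so the projected area oscillates with the rotation -- the signal the
#'   area-change method measures. For a texture-free ellipsoid the projection
#'   is pi-symmetric: the area repeats twice per revolution.
#' * `in_plane`: the rotation axis is the optical axis. The outline is
#'   constant; only internal texture (dark/bright spots) rotates, which is
#'   what the quarter-bounding-box measurement picks up.
#'
#' Internal spots are placed deterministically on a ring of radius `0.5 * a`
#' at evenly spaced body angles. A dark spot (`spot_contrast < 0`) that drops
#' below the segmentation threshold bites a hole into the binarized cell once
#' per revolution (out-of-plane: only while on the camera-facing hemisphere),
#' breaking the pi-symmetry so that the area period equals the full rotation
#' period.
#'
#' @param semi_axes Numeric length-3, ellipsoid semi-axes (a, b, c) in pixels.
#' @param rotation_rpm Rotation speed, revolutions per minute (>= 0).
#' @param rotation_mode `"out_of_plane"` or `"in_plane"`.
#' @param centroid Initial centroid `(row, col)` in pixels.
#' @param velocity Constant drift `(d_row, d_col)` in pixels/frame.
#' @param orbit_radius,orbit_period Optional circular drift: the centroid
#'   additionally moves on a circle of this radius (px), completing one orbit
#'   every `orbit_period` frames.
#' @param n_spots Number of internal texture spots (0 = texture-free).
#' @param spot_contrast Additive intensity of spots relative to the cell body
#'   (negative = dark spots).
#' @param spot_radius Spot radius in pixels.
#' @param phase0 Initial rotation phase, radians.
#' @return A `cell_spec` list.
#' @export
cell_spec <- function(semi_axes = c(12, 12, 8), rotation_rpm = 86,
                      rotation_mode = c("out_of_plane", "in_plane"),
                      centroid = NULL, velocity = c(0, 0),
                      orbit_radius = 0, orbit_period = 60,
                      n_spots = 0, spot_contrast = -60, spot_radius = 3,
                      phase0 = 0) {
  rotation_mode <- match.arg(rotation_mode)
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), rotation_rpm >= 0,
            length(velocity) == 2, orbit_radius >= 0, orbit_period > 0,
            n_spots >= 0, spot_radius > 0)
  structure(list(
    semi_axes = as.numeric(semi_axes), rotation_rpm = rotation_rpm,
    rotation_mode = rotation_mode, centroid = centroid,
    velocity = as.numeric(velocity),
    orbit_radius = orbit_radius, orbit_period = orbit_period,
    n_spots = as.integer(n_spots), spot_contrast = spot_contrast,
    spot_radius = spot_radius, phase0 = phase0
  ), class = "cell_spec")
}

#' Configure a synthetic rotating-cell scene
#'
#' The renderer emulates the imaging conditions of low-magnification
#' fluorescence video of cells in an ODEP chip: a brighter image centre with
#' dark vignetted corners (multiplicative radial gain
#' `g(r) = 1 - vignette_strength * (r/r_corner)^2`), low cell/background
#' contrast, small bright impurity blobs ("debris"), and Gaussian sensor
#' noise. Everything is deterministic given `rng_seed`.
#'
#' @param width,height Image size in pixels.
#' @param n_frames Number of frames (>= 2).
#' @param fps Frame rate, frames/second.
#' @param cells List of [cell_spec()] objects (default: one cell at centre).
#' @param vignette_strength Gain falloff at the corners, in `[0, 1)`.
#' @param background_level,cell_level Background and cell body intensities on
#'   the 8-bit scale.
#' @param noise_sigma Gaussian noise standard deviation (intensity units).
#' @param n_debris Number of small bright impurity blobs.
#' @param rng_seed Integer seed controlling noise and debris placement.
#' @return A `scene_config` list.
#' @export
scene_config <- function(width = 96, height = 96, n_frames = 159, fps = 15,
                         cells = list(cell_spec()), vignette_strength = 0.3,
                         background_level = 140, cell_level = 185,
                         noise_sigma = 2, n_debris = 3, rng_seed = 1L) {
  stopifnot(width >= 8, height >= 8, n_frames >= 2, fps > 0,
            vignette_strength >= 0, vignette_strength < 1,
            background_level >= 0, background_level <= 255,
            cell_level >= 0, cell_level <= 255,
            noise_sigma >= 0, n_debris >= 0)
  cells <- lapply(cells, function(cl) {
    if (!inherits(cl, "cell_spec")) rlang::abort("`cells` must be cell_spec objects.")
    if (is.null(cl$centroid)) cl$centroid <- c(height / 2, width / 2)
    cl
  })
  structure(list(
    width = as.integer(width), height = as.integer(height),
    n_frames = as.integer(n_frames), fps = fps, cells = cells,
    vignette_strength = vignette_strength,
    background_level = background_level, cell_level = cell_level,
    noise_sigma = noise_sigma, n_debris = as.integer(n_debris),
    rng_seed = as.integer(rng_seed)
  ), class = "scene_config")
}

# evaluate expr under a temporary RNG seed, restoring global RNG state
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

frame_noise_seed <- function(config, t) {
  as.integer((as.numeric(config$rng_seed) * 7919 + t * 104729) %% 2147483629)
}

# rotation phase of a cell at 1-based frame t
cell_angle <- function(cell, fps, t) {
  cell$phase0 + 2 * pi * cell$rotation_rpm * (t - 1) / (60 * fps)
}

# centroid of a cell at 1-based frame t (drift + optional circular orbit)
cell_centroid_at <- function(cell, t) {
  pos <- cell$centroid + cell$velocity * (t - 1)
  if (cell$orbit_radius > 0) {
    ang <- 2 * pi * (t - 1) / cell$orbit_period
    # subtract the t=1 orbit offset so the path starts at `centroid`
    pos <- pos + cell$orbit_radius * (c(sin(ang), cos(ang)) - c(0, 1))
  }
  pos
}

# semi-axes (row, col) of the projected outline at phase theta
projected_semi_axes <- function(cell, theta) {
  ax <- cell$semi_axes
  if (cell$rotation_mode == "out_of_plane") {
    c(ax[2], sqrt(ax[1]^2 * cos(theta)^2 + ax[3]^2 * sin(theta)^2))
  } else {
    c(ax[2], ax[1])
  }
}

# logical mask of pixels whose centres fall inside an axis-aligned ellipse
ellipse_mask <- function(height, width, centre, semi) {
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  ((rr - centre[1]) / semi[1])^2 + ((cc - centre[2]) / semi[2])^2 <= 1
}

# deterministic body-frame spot layout: ring of radius a/2, evenly spaced
spot_layout <- function(cell) {
  if (cell$n_spots == 0L) return(NULL)
  j <- seq_len(cell$n_spots)
  list(
    phi = 2 * pi * (j - 1) / cell$n_spots + pi / 5,
    rho = rep(0.5 * cell$semi_axes[1], cell$n_spots)
  )
}

draw_disk <- function(img, centre, radius, value, within = NULL) {
  h <- nrow(img); w <- ncol(img)
  r0 <- max(1L, floor(centre[1] - radius)); r1 <- min(h, ceiling(centre[1] + radius))
  c0 <- max(1L, floor(centre[2] - radius)); c1 <- min(w, ceiling(centre[2] + radius))
  if (r0 > r1 || c0 > c1) return(img)
  rr <- matrix(r0:r1, r1 - r0 + 1L, c1 - c0 + 1L)
  cc <- matrix(c0:c1, r1 - r0 + 1L, c1 - c0 + 1L, byrow = TRUE)
  inside <- (rr - centre[1])^2 + (cc - centre[2])^2 <= radius^2
  if (!is.null(within)) inside <- inside & within[r0:r1, c0:c1]
  sub <- img[r0:r1, c0:c1]
  sub[inside] <- value
  img[r0:r1, c0:c1] <- sub
  img
}

# static bright impurity blobs, deterministic from the scene seed
debris_table <- function(config) {
  if (config$n_debris == 0L) {
    return(data.frame(row = numeric(0), col = numeric(0),
                      radius = numeric(0), level = numeric(0)))
  }
  with_local_seed(config$rng_seed, {
    data.frame(
      row = stats::runif(config$n_debris, 2, config$height - 1),
      col = stats::runif(config$n_debris, 2, config$width - 1),
      radius = stats::runif(config$n_debris, 1, 2.5),
      level = stats::runif(config$n_debris, min(config$cell_level + 20, 250), 255)
    )
  })
}

#' Render one frame of a synthetic scene
#'
#' Draws background, debris, each cell's projected outline and rotated
#' internal spots at frame `t`, then applies the multiplicative vignette and
#' adds Gaussian noise (clipped to \[0, 255\]). Deterministic given the scene
#' seed: the same `(config, t)` always yields the same pixels, and the frame
#' is identical to frame `t` of [render_video()].
#'
#' @param config A [scene_config()].
#' @param t 1-based frame index.
#' @return Numeric matrix `height x width` with values in \[0, 255\].
#' @export
render_frame <- function(config, t) {
  stopifnot(inherits(config, "scene_config"), t >= 1, t <= config$n_frames)
  h <- config$height; w <- config$width
  img <- matrix(config$background_level, h, w)

  deb <- debris_table(config)
  for (k in seq_len(nrow(deb))) {
    img <- draw_disk(img, c(deb$row[k], deb$col[k]), deb$radius[k], deb$level[k])
  }

  for (cell in config$cells) {
    theta <- cell_angle(cell, config$fps, t)
    ctr <- cell_centroid_at(cell, t)
    body <- ellipse_mask(h, w, ctr, projected_semi_axes(cell, theta))
    img[body] <- config$cell_level
    spots <- spot_layout(cell)
    if (!is.null(spots)) {
      for (j in seq_along(spots$phi)) {
        alpha <- theta + spots$phi[j]
        if (cell$rotation_mode == "in_plane") {
          off <- spots$rho[j] * c(sin(alpha), cos(alpha))
          vis <- TRUE
        } else {
          # spot on the rotating equator; visible on the camera-facing side
          off <- c(0, spots$rho[j] * cos(alpha))
          vis <- sin(alpha) > 0
        }
        if (vis) {
          img <- draw_disk(img, ctr + off, cell$spot_radius,
                           clip255(config$cell_level + cell$spot_contrast),
                           within = body)
        }
      }
    }
  }

  img <- img * vignette_field(h, w, config$vignette_strength)
  if (config$noise_sigma > 0) {
    noise <- with_local_seed(frame_noise_seed(config, t),
                             stats::rnorm(h * w, 0, config$noise_sigma))
    img <- img + matrix(noise, h, w)
  }
  clip255(img)
}

#' Quadratic vignette gain field
#'
#' `g(r) = 1 - strength * (r / r_corner)^2` about the image centre, the
#' multiplicative falloff the renderer applies and the correction stage
#' removes.
#'
#' @param height,width Image size.
#' @param strength Falloff at the corner, in `[0, 1)`.
#' @return Numeric matrix of gains in `(0, 1]`.
#' @export
vignette_field <- function(height, width, strength) {
  if (strength == 0) return(matrix(1, height, width))
  ctr <- c((1 + height) / 2, (1 + width) / 2)
  rr <- matrix(seq_len(height), height, width)
  cc <- matrix(seq_len(width), height, width, byrow = TRUE)
  r2 <- (rr - ctr[1])^2 + (cc - ctr[2])^2
  r2corner <- (1 - ctr[1])^2 + (1 - ctr[2])^2
  1 - strength * r2 / r2corner
}

#' Render a full synthetic video with ground truth
#'
#' Rotation follows `theta_t = phase0 + 2*pi*rpm*(t-1)/(60*fps)`. The truth
#' table records, for the first cell, the exact phase, centroid and the
#' rasterized projected outline area of every frame, plus the true rpm and
#' the area repeat period in frames (`60*fps/rpm / 2` for a texture-free
#' out-of-plane ellipsoid, whose projection is pi-symmetric; the full period
#' `60*fps/rpm` when internal spots break that symmetry).
#'
#' @param config A [scene_config()].
#' @return A list of class `scene` with elements `frames` (a [frame_stack()])
#'   and `truth` (a tibble: `frame`, `angle_rad`, `row`, `col`, `area_px`),
#'   plus `true_rpm` and `area_period_frames`.
#' @export
render_video <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  frames <- lapply(seq_len(config$n_frames), function(t) render_frame(config, t))
  cell <- config$cells[[1]]
  truth <- purrr::map_dfr(seq_len(config$n_frames), function(t) {
    theta <- cell_angle(cell, config$fps, t)
    ctr <- cell_centroid_at(cell, t)
    body <- ellipse_mask(config$height, config$width, ctr,
                         projected_semi_axes(cell, theta))
    tibble::tibble(frame = t, angle_rad = theta,
                   row = ctr[1], col = ctr[2], area_px = sum(body))
  })
  period <- if (cell$rotation_rpm > 0) {
    full <- 60 * config$fps / cell$rotation_rpm
    if (cell$rotation_mode == "out_of_plane" && cell$n_spots == 0L) full / 2 else full
  } else {
    NA_real_
  }
  structure(list(
    frames = frame_stack(frames, config$fps),
    truth = truth,
    true_rpm = cell$rotation_rpm,
    area_period_frames = period
  ), class = "scene")
}

#' @export
print.scene <- function(x, ...) {
  cat(sprintf("<scene> %d frames, true rpm %g, area period %.2f frames\n",
              length(x$frames), x$true_rpm, x$area_period_frames))
  invisible(x)
}
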