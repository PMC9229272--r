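#' Otsu threshold selection
#'
#' Selects the grey level `t*` in `0..255` that maximizes the between-class
#' (interclass) variance of the background (`<= t`) / foreground (`> t`)
#' split of the 256-bin histogram -- the split with the lowest probability of
#' misclassification for a bimodal histogram. Ties are broken by the smallest
#' threshold, so the result is deterministic.
#'
#' Pixels are binned by rounding to the nearest integer level; intermediate
#' floating-point images from the stretch stage are therefore handled
#' directly.
#'
#' @param image Numeric matrix in \[0, 255\] with at least two distinct
#'   levels after rounding.
#' @return Integer threshold in `0..254`, with attribute
#'   `between_class_variance`.
#' @export
otsu_threshold <- function(image) {
  lev <- pmin(pmax(round(image), 0), 255)
  counts <- tabulate(as.vector(lev) + 1L, 256L)
  if (sum(counts > 0) < 2) rlang::abort("Otsu needs >= 2 distinct grey levels.")
  n <- sum(counts)
  p <- counts / n
  vals <- 0:255
  omega <- cumsum(p)                 # P(class0) for t = 0..255
  mu <- cumsum(p * vals)             # partial mean numerator
  mu_total <- mu[256]
  # between-class variance for thresholds t = 0..254 (both classes non-empty)
  w0 <- omega[1:255]
  sigma_b <- (mu_total * w0 - mu[1:255])^2 / (w0 * (1 - w0))
  sigma_b[w0 == 0 | w0 == 1] <- -Inf
  t_star <- which.max(sigma_b) - 1L  # which.max takes the first (smallest) max
  structure(t_star, between_class_variance = sigma_b[t_star + 1L])
}

#' Binarize an image at a threshold
#'
#' Pixels strictly above `t` become foreground (cells are brighter than
#' background after contrast stretching; invert the image upstream for
#' dark-cell imagery).
#'
#' @param image Numeric matrix.
#' @param t Threshold in \[0, 255\].
#' @return Integer 0/1 matrix of the same shape.
#' @export
binarize <- function(image, t) {
  stopifnot(t >= 0, t <= 255)
  mask <- matrix(0L, nrow(image), ncol(image))
  mask[image > t] <- 1L
  mask
}

# 8-connected component labels of a binary mask, as an integer matrix.
# Foreground pixels form graph vertices; edges join E / S / SE / SW
# neighbours; components are read off the adjacency graph. Labels are
# renumbered 1..k in order of component bounding-box (row0, col0).
label_matrix <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  fg <- which(mask != 0)
  lab <- matrix(0L, h, w)
  if (length(fg) == 0L) return(lab)
  vid <- integer(h * w)
  vid[fg] <- seq_along(fg)
  rows <- ((fg - 1L) %% h) + 1L
  cols <- ((fg - 1L) %/% h) + 1L
  edge_to <- function(dr, dc) {
    ok <- rows + dr >= 1L & rows + dr <= h & cols + dc >= 1L & cols + dc <= w
    nb <- fg[ok] + dr + dc * h
    ok2 <- vid[nb] > 0L
    cbind(vid[fg[ok][ok2]], vid[nb[ok2]])
  }
  edges <- rbind(edge_to(0L, 1L), edge_to(1L, 0L), edge_to(1L, 1L), edge_to(-1L, 1L))
  g <- igraph::graph_from_edgelist(
    rbind(edges, cbind(seq_along(fg), seq_along(fg))), directed = FALSE)
  comp <- igraph::components(g)$membership[seq_along(fg)]
  # renumber components by bounding-box top-left corner
  row0 <- tapply(rows, comp, min)
  col0 <- tapply(cols, comp, min)
  ord <- order(row0, col0)
  renum <- integer(length(ord))
  renum[ord] <- seq_along(ord)
  lab[fg] <- renum[comp]
  lab
}

#' Remove small connected components from a binary mask
#'
#' Deletes every 8-connected foreground component whose pixel area is below
#' `min_area` -- the noise blobs, impurities and broken-cell fragments that
#' survive thresholding. Components at or above the cutoff are untouched.
#'
#' @param mask Integer 0/1 matrix.
#' @param min_area Minimum component area, pixels (default 30, roughly a
#'   quarter of a 12 micron cell at the emulated magnification).
#' @return Cleaned 0/1 mask; output foreground is a subset of the input's.
#' @export
remove_small_objects <- function(mask, min_area = 30) {
  stopifnot(min_area >= 0)
  if (min_area == 0) return(mask)
  lab <- label_matrix(mask)
  if (max(lab) == 0L) return(mask)
  areas <- tabulate(lab[lab > 0L], max(lab))
  drop <- which(areas < min_area)
  out <- mask
  out[lab %in% drop] <- 0L
  out
}

# offsets of a disk structuring element of the given radius
disk_offsets <- function(radius) {
  r <- floor(radius)
  d <- expand.grid(dr = -r:r, dc = -r:r)
  d[d$dr^2 + d$dc^2 <= radius^2, , drop = FALSE]
}

#' Morphological dilation by a disk
#'
#' Expands the foreground by a disk of the given radius (radius 1 = the
#' 5-pixel plus-shaped element), smoothing ragged cell outlines and closing
#' small gaps left by thresholding. Extensive: input foreground is always a
#' subset of the output.
#'
#' @param mask Integer 0/1 matrix.
#' @param radius Disk radius in pixels (0 = identity).
#' @return Dilated 0/1 mask.
#' @export
dilate_mask <- function(mask, radius = 1) {
  stopifnot(radius >= 0)
  if (radius == 0) return(mask)
  h <- nrow(mask); w <- ncol(mask)
  out <- matrix(0L, h, w)
  offs <- disk_offsets(radius)
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    sr <- max(1, 1 + dr):min(h, h + dr)
    sc <- max(1, 1 + dc):min(w, w + dc)
    out[sr, sc] <- out[sr, sc] | mask[sr - dr, sc - dc]
  }
  mode(out) <- "integer"
  out
}

#' Label connected domains and measure them
#'
#' Labels every 8-connected foreground component and returns one row per
#' detection: pixel area, the tightest axis-aligned bounding box (the
#' "external rectangle"), and the centroid (mean of member pixel
#' coordinates, the "shape centre"). Rows are ordered by bounding-box
#' top-left corner `(row0, col0)` and labelled `1..k` in that order.
#'
#' @param mask Integer 0/1 matrix.
#' @return A tibble with columns `label`, `row0`, `col0`, `height`, `width`,
#'   `area`, `centroid_row`, `centroid_col` (all 1-based, boxes inclusive),
#'   carrying the integer label image in attribute `label_matrix`.
#' @export
label_components <- function(mask) {
  lab <- label_matrix(mask)
  k <- max(lab)
  if (k == 0L) {
    out <- tibble::tibble(label = integer(), row0 = integer(), col0 = integer(),
                          height = integer(), width = integer(), area = integer(),
                          centroid_row = numeric(), centroid_col = numeric())
    attr(out, "label_matrix") <- lab
    return(out)
  }
  fg <- which(lab > 0L)
  rows <- ((fg - 1L) %% nrow(lab)) + 1L
  cols <- ((fg - 1L) %/% nrow(lab)) + 1L
  lb <- lab[fg]
  out <- tibble::tibble(
    label = 1:k,
    row0 = as.integer(tapply(rows, lb, min)),
    col0 = as.integer(tapply(cols, lb, min)),
    height = as.integer(tapply(rows, lb, max)) - as.integer(tapply(rows, lb, min)) + 1L,
    width = as.integer(tapply(cols, lb, max)) - as.integer(tapply(cols, lb, min)) + 1L,
    area = as.integer(tabulate(lb, k)),
    centroid_row = as.numeric(tapply(rows, lb, mean)),
    centroid_col = as.numeric(tapply(cols, lb, mean))
  )
  attr(out, "label_matrix") <- lab
  out
}

#' Segment one preprocessed frame into detections
#'
#' Otsu threshold, binarize, small-object removal, disk dilation, and
#' connected-domain labelling in one call -- the per-frame segmentation stage
#' of the pipeline.
#'
#' @param image Preprocessed numeric matrix in \[0, 255\].
#' @param min_area Minimum component area kept, pixels.
#' @param dilate_radius Disk radius for the smoothing dilation.
#' @param invert Set `TRUE` for imagery in which cells are darker than the
#'   background.
#' @return The [label_components()] tibble, with the final 0/1 mask in
#'   attribute `mask` and the chosen threshold in attribute `threshold`.
#' @export
segment_frame <- function(image, min_area = 30, dilate_radius = 1,
                          invert = FALSE) {
  if (invert) image <- 255 - image
  t_star <- otsu_threshold(image)
  mask <- binarize(image, t_star)
  mask <- remove_small_objects(mask, min_area)
  mask <- dilate_mask(mask, dilate_radius)
  det <- label_components(mask)
  attr(det, "mask") <- mask
  attr(det, "threshold") <- as.integer(t_star)
  det
}
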