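#' Frame-difference motion mask
#'
#' Marks pixels whose absolute intensity change between two frames exceeds a
#' threshold -- the classic frame-difference detector for moving targets.
#' With `diff_threshold = NULL` the threshold is chosen by Otsu's method on
#' the absolute-difference image (parameter-free); if the difference image is
#' essentially constant (nothing moved), an empty mask is returned.
#'
#' @param prev,curr Numeric matrices of identical shape, \[0, 255\].
#' @param diff_threshold Intensity threshold, or `NULL` for Otsu.
#' @return Integer 0/1 motion mask.
#' @export
frame_difference <- function(prev, curr, diff_threshold = NULL) {
  if (!all(dim(prev) == dim(curr))) rlang::abort("frame shape mismatch.")
  d <- abs(curr - prev)
  if (is.null(diff_threshold)) {
    if (max(round(d)) == min(round(d))) {
      return(matrix(0L, nrow(d), ncol(d)))
    }
    diff_threshold <- as.numeric(otsu_threshold(d))
  }
  binarize(d, diff_threshold)
}

#' Predict the next position of a track
#'
#' Constant-velocity extrapolation from the last two trajectory points; with
#' a single point the prediction is the point itself. Used to gate the next
#' frame's association so a nearby second cell cannot capture the track.
#'
#' @param traj A trajectory tibble with `row` and `col` columns (>= 1 row).
#' @return Numeric `(row, col)` prediction.
#' @examples
#' predict_position(tibble::tibble(row = c(10, 12), col = c(10, 14)))  # 14, 18
#' @export
predict_position <- function(traj) {
  n <- nrow(traj)
  if (n < 1) rlang::abort("need at least one trajectory point.")
  if (n == 1) return(c(traj$row[1], traj$col[1]))
  c(2 * traj$row[n] - traj$row[n - 1], 2 * traj$col[n] - traj$col[n - 1])
}

#' Track the motion trajectory of the cell of interest
#'
#' Per frame, moving-target candidates come from the frame-difference mask
#' (cleaned of sub-`min_area/4` specks and labelled); the candidate nearest
#' the constant-velocity prediction, within the gate, localises the cell.
#' The reported position is then refined to the centroid of the nearest
#' detection in the current frame's segmentation: a raw difference blob
#' straddles the cell's previous and current footprints, so its centroid
#' lags a moving cell by about half the displacement, while the segmentation
#' centroid does not. When nothing moves (a stationary rotator) the
#' segmentation centroid nearest the prediction is used directly. If neither
#' source yields a candidate within the gate for more than `coastdown`
#' consecutive frames, the track is declared lost and truncated.
#'
#' @param stack A [frame_stack()] (>= 2 frames).
#' @param seed_point,label Cell-of-interest selection in frame 1.
#' @param gate Association gate radius, pixels.
#' @param coastdown Consecutive frames the track may coast on prediction
#'   alone before being declared lost.
#' @param diff_threshold Passed to [frame_difference()].
#' @param min_area,dilate_radius,invert Segmentation parameters.
#' @param ... Preprocessing parameters ([preprocess_frame()]).
#' @return A `trajectory` tibble: `frame`, `row`, `col`, `step_px`
#'   (Euclidean displacement from the previous point; 0 for the first).
#' @export
track_trajectory <- function(stack, seed_point = NULL, label = NULL,
                             gate = NULL, coastdown = 3,
                             diff_threshold = NULL, min_area = 30,
                             dilate_radius = 1, invert = FALSE, ...) {
  stopifnot(inherits(stack, "frame_stack"), length(stack) >= 2)
  fnums <- frame_numbers(stack)
  pre_args <- list(...)
  # the entropy gain field, when requested, is fitted once on frame 1
  if (identical(pre_args$vignette, "entropy") && is.null(pre_args$gain)) {
    pre_args$gain <- estimate_vignette_gain(stack$frames[[1]])
  }
  pre <- function(img) do.call(preprocess_frame, c(list(img), pre_args))
  seg <- function(img) segment_frame(pre(img), min_area = min_area,
                                     dilate_radius = dilate_radius,
                                     invert = invert)
  det0_all <- seg(stack$frames[[1]])
  det0 <- select_cell(det0_all, seed_point = seed_point, label = label)
  if (is.null(gate)) gate <- 2 * sqrt(det0$height^2 + det0$width^2)

  traj <- tibble::tibble(frame = fnums[1], row = det0$centroid_row,
                         col = det0$centroid_col, step_px = 0)
  missed <- 0L
  for (i in 2:length(stack$frames)) {
    pred <- predict_position(traj)
    # moving-target candidates from the frame difference
    dmask <- frame_difference(stack$frames[[i - 1]], stack$frames[[i]],
                              diff_threshold)
    dmask <- remove_small_objects(dmask, max(1, floor(min_area / 4)))
    cand <- label_components(dmask)
    anchor <- NULL
    if (nrow(cand) > 0) {
      dd <- sqrt((cand$centroid_row - pred[1])^2 + (cand$centroid_col - pred[2])^2)
      if (min(dd) <= gate) anchor <- c(cand$centroid_row[which.min(dd)],
                                       cand$centroid_col[which.min(dd)])
    }
    if (is.null(anchor)) anchor <- pred  # stationary cell: no motion evidence
    # refine to the current frame's segmentation centroid
    dets <- seg(stack$frames[[i]])
    pos <- NULL
    if (nrow(dets) > 0) {
      dd <- sqrt((dets$centroid_row - anchor[1])^2 + (dets$centroid_col - anchor[2])^2)
      if (min(dd) <= gate) pos <- c(dets$centroid_row[which.min(dd)],
                                    dets$centroid_col[which.min(dd)])
    }
    if (is.null(pos)) {
      missed <- missed + 1L
      if (missed > coastdown) {
        rlang::warn(sprintf("track lost at frame %d; trajectory truncated.", fnums[i]))
        break
      }
      pos <- pred
    } else {
      missed <- 0L
    }
    step <- sqrt((pos[1] - traj$row[nrow(traj)])^2 + (pos[2] - traj$col[nrow(traj)])^2)
    traj <- dplyr::bind_rows(traj, tibble::tibble(
      frame = fnums[i], row = pos[1], col = pos[2], step_px = step))
  }
  class(traj) <- c("trajectory", class(traj))
  traj
}
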