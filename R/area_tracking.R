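#' Select the cell of interest among detections
#'
#' The one manual step the method retains: the user points at (or names) the
#' cell whose rotation is to be measured. A seed point falling inside a
#' labelled component selects that component; otherwise the detection with
#' the nearest centroid is taken (ties broken by the lower label).
#'
#' @param detections A [label_components()] tibble (its `label_matrix`
#'   attribute, when present, is used for exact point-in-component lookup).
#' @param seed_point Numeric `(row, col)`; ignored when `label` is given.
#' @param label Component label to select directly.
#' @param gate Maximum acceptable centroid distance in pixels when the point
#'   is outside every component (`Inf` = always take the nearest).
#' @return The selected one-row detection tibble.
#' @export
select_cell <- function(detections, seed_point = NULL, label = NULL,
                        gate = Inf) {
  if (nrow(detections) == 0L) rlang::abort("no detections to select from.")
  if (!is.null(label)) {
    hit <- detections[detections$label == label, ]
    if (nrow(hit) == 0L) rlang::abort(sprintf("no detection with label %s.", label))
    return(hit)
  }
  if (is.null(seed_point)) rlang::abort("give either `seed_point` or `label`.")
  lab <- attr(detections, "label_matrix")
  if (!is.null(lab)) {
    r <- round(seed_point[1]); c <- round(seed_point[2])
    if (r >= 1 && r <= nrow(lab) && c >= 1 && c <= ncol(lab) && lab[r, c] > 0L) {
      return(detections[detections$label == lab[r, c], ])
    }
  }
  d <- sqrt((detections$centroid_row - seed_point[1])^2 +
              (detections$centroid_col - seed_point[2])^2)
  if (min(d) > gate) rlang::abort("no detection within the selection gate.")
  detections[which.min(d), ]  # which.min: first (lowest-label) on ties
}

#' Start a track from a selected detection
#'
#' @param detection One-row detection tibble.
#' @param gate Search gate radius in pixels for frame-to-frame association;
#'   default twice the detection's bounding-box diagonal, large enough for
#'   any plausible inter-frame motion yet small enough that a well-separated
#'   neighbouring cell cannot capture the track.
#' @return A `track_state` list.
#' @export
track_state <- function(detection, gate = NULL) {
  if (is.null(gate)) {
    gate <- 2 * sqrt(detection$height^2 + detection$width^2)
  }
  stopifnot(gate > 0)
  structure(list(detection = detection,
                 centroid = c(detection$centroid_row, detection$centroid_col),
                 gate = gate),
            class = "track_state")
}

#' Associate the tracked cell with a detection in the next frame
#'
#' Nearest-centroid association within the gate. Returns the matched
#' detection and the updated state; signals a `rotospin_track_lost` error
#' when no candidate lies within the gate.
#'
#' @param state A [track_state()].
#' @param detections_next Detections of the next frame.
#' @return List with elements `detection` and `state`.
#' @export
associate <- function(state, detections_next) {
  if (nrow(detections_next) == 0L) {
    rlang::abort("track lost: no detections in frame.", class = "rotospin_track_lost")
  }
  d <- sqrt((detections_next$centroid_row - state$centroid[1])^2 +
              (detections_next$centroid_col - state$centroid[2])^2)
  if (min(d) > state$gate) {
    rlang::abort("track lost: no detection within gate.", class = "rotospin_track_lost")
  }
  det <- detections_next[which.min(d), ]
  state$detection <- det
  state$centroid <- c(det$centroid_row, det$centroid_col)
  list(detection = det, state = state)
}

#' Cell area within one quarter of its bounding box
#'
#' Counts the selected cell's foreground pixels inside the top-left quadrant
#' of its minimal bounding box. For in-plane rotation the outline area is
#' constant, but internal or asymmetric structure sweeps through the fixed
#' quadrant as the cell turns, so this count oscillates with the rotation --
#' the in-plane analogue of the projected-area signal. (For a perfectly
#' rotationally symmetric cell the count is constant at about a quarter of
#' the area: some internal texture or asymmetry is required.) Any fixed
#' quadrant yields the same period; top-left is the package's deterministic
#' choice.
#'
#' @param mask 0/1 mask or integer label matrix the detection came from.
#' @param det One-row detection tibble.
#' @return Foreground pixel count in the quadrant.
#' @export
quarter_box_area <- function(mask, det) {
  if (det$height < 2 || det$width < 2) {
    rlang::abort("bounding box too small for a quarter-box measurement.")
  }
  rows <- det$row0:(det$row0 + floor(det$height / 2) - 1L)
  cols <- det$col0:(det$col0 + floor(det$width / 2) - 1L)
  sub <- mask[rows, cols, drop = FALSE]
  if (max(mask) > 1L) sum(sub == det$label) else sum(sub != 0L)
}

#' Build the projected-area time series of one tracked cell
#'
#' Runs preprocessing and segmentation on every frame, selects the cell of
#' interest in the first frame, follows it by nearest-centroid association,
#' and records its area per frame: the whole-outline pixel area
#' (`mode = "outline"`, for out-of-plane rotation) or the quarter-bounding-box
#' count (`mode = "quarter_box"`, for in-plane rotation). This curve's
#' periodicity carries the rotation speed.
#'
#' If the track is lost (no detection within the gate) the series is
#' truncated at the last associated frame with a warning; the loss frame is
#' recorded in attribute `lost_at`.
#'
#' @param stack A [frame_stack()] (possibly a window of one).
#' @param seed_point,label Cell-of-interest selection in the first frame, as
#'   in [select_cell()].
#' @param mode `"outline"` or `"quarter_box"`.
#' @param gate Association gate radius, pixels (default from [track_state()]).
#' @param min_area,dilate_radius,invert Segmentation parameters
#'   ([segment_frame()]).
#' @param ... Preprocessing parameters passed to [preprocess_frame()].
#' @return An `area_series` tibble with columns `frame` (1-based absolute
#'   frame number), `area` (px), `row`, `col` (tracked centroid); attributes
#'   `fps` and `mode`.
#' @export
build_area_series <- function(stack, seed_point = NULL, label = NULL,
                              mode = c("outline", "quarter_box"),
                              gate = NULL, min_area = 30, dilate_radius = 1,
                              invert = FALSE, ...) {
  stopifnot(inherits(stack, "frame_stack"), length(stack) >= 2)
  mode <- match.arg(mode)
  fnums <- frame_numbers(stack)
  rows <- vector("list", length(stack))
  state <- NULL
  lost_at <- NA_integer_
  # the entropy gain field, when requested, is fitted once on frame 1
  pre_args <- list(...)
  if (identical(pre_args$vignette, "entropy") && is.null(pre_args$gain)) {
    pre_args$gain <- estimate_vignette_gain(stack$frames[[1]])
  }
  for (i in seq_along(stack$frames)) {
    img <- do.call(preprocess_frame, c(list(stack$frames[[i]]), pre_args))
    det_all <- segment_frame(img, min_area = min_area,
                             dilate_radius = dilate_radius, invert = invert)
    if (i == 1L) {
      det <- select_cell(det_all, seed_point = seed_point, label = label)
      state <- track_state(det, gate = gate)
    } else {
      res <- tryCatch(associate(state, det_all), rotospin_track_lost = function(e) NULL)
      if (is.null(res)) {
        lost_at <- fnums[i]
        rlang::warn(sprintf("track lost at frame %d; series truncated.", fnums[i]))
        break
      }
      det <- res$detection
      state <- res$state
    }
    area <- if (mode == "outline") {
      det$area
    } else {
      quarter_box_area(attr(det_all, "label_matrix"), det)
    }
    rows[[i]] <- tibble::tibble(frame = fnums[i], area = as.numeric(area),
                                row = det$centroid_row, col = det$centroid_col)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "fps") <- stack$fps
  attr(out, "mode") <- mode
  attr(out, "lost_at") <- lost_at
  class(out) <- c("area_series", class(out))
  out
}
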