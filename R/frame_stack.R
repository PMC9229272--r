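#' Frame stack: an ordered grayscale video plus its acquisition frame rate
#'
#' A `frame_stack` is the package's video container: a list of numeric
#' matrices (intensities on the 8-bit scale, 0--255; stored as doubles so
#' intermediate arithmetic never double-rounds) together with the frame rate
#' in frames per second. All frames must share one shape. Frame numbers are
#' 1-based throughout.
#'
#' @param frames List of numeric matrices, all of identical dimension, with
#'   values in \[0, 255\].
#' @param fps Acquisition frame rate in frames/second (> 0).
#' @return An object of class `frame_stack`.
#' @examples
#' fs <- frame_stack(list(matrix(0, 4, 4), matrix(255, 4, 4)), fps = 15)
#' length(fs)
#' @export
frame_stack <- function(frames, fps) {
  if (!is.list(frames) || length(frames) < 1L) {
    rlang::abort("`frames` must be a non-empty list of matrices.")
  }
  if (!all(vapply(frames, is.matrix, logical(1)))) {
    rlang::abort("every frame must be a numeric matrix.")
  }
  dims <- vapply(frames, dim, integer(2))
  if (length(frames) > 1L && any(dims[1, ] != dims[1, 1] | dims[2, ] != dims[2, 1])) {
    rlang::abort("all frames must have the same dimensions.")
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    rlang::abort("`fps` must be a single positive number.")
  }
  structure(list(frames = frames, fps = as.numeric(fps)), class = "frame_stack")
}

#' @export
length.frame_stack <- function(x) length(x$frames)

#' Extract a frame window from a stack
#'
#' @param x A `frame_stack`.
#' @param i Integer frame indices (1-based).
#' @param ... Ignored.
#' @return A `frame_stack` over the selected frames; the original frame
#'   numbers are kept in the `frame_offset` attribute so downstream results
#'   can still report absolute frame numbers.
#' @export
`[.frame_stack` <- function(x, i, ...) {
  i <- as.integer(i)
  if (any(i < 1L | i > length(x$frames))) {
    rlang::abort("frame index out of range.")
  }
  out <- frame_stack(x$frames[i], x$fps)
  attr(out, "frame_numbers") <- frame_numbers(x)[i]
  out
}

#' Absolute frame numbers of a stack
#'
#' @param x A `frame_stack`.
#' @return Integer vector of 1-based frame numbers, honouring any window
#'   taken with `[`.
#' @export
frame_numbers <- function(x) {
  fn <- attr(x, "frame_numbers")
  if (is.null(fn)) seq_along(x$frames) else fn
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf(
    "<frame_stack> %d frames of %d x %d px @ %g fps\n",
    length(x$frames), d[1], d[2], x$fps
  ))
  invisible(x)
}

#' @export
dim.frame_stack <- function(x) dim(x$frames[[1]])

clip255 <- function(x) pmin(pmax(x, 0), 255)
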