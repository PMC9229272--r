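# moving average with symmetric (mirror) edge padding; with a uniform kernel
# this padding reflects every boundary weight back inside, so the series sum
# -- hence the mean -- is conserved exactly
smooth_ma <- function(x, width) {
  n <- length(x)
  if (width == 1L) return(x)
  half <- (width - 1L) %/% 2L
  pad <- c(x[half:1], x, x[n:(n - half + 1L)])
  y <- stats::filter(pad, rep(1 / width, width), sides = 2)
  as.numeric(y[(half + 1L):(half + n)])
}

#' Smooth an area series by uniform convolution
#'
#' Moving-average convolution with a uniform kernel of odd width; edges are
#' handled by mirror reflection, which preserves both the series length and
#' its mean exactly. This is the denoising step that removes the excess
#' peaks from the raw area-change curve so that one trough per area cycle
#' survives.
#'
#' @param series An `area_series` tibble (from [build_area_series()]) or any
#'   data frame with `frame` and `area` columns.
#' @param width Odd kernel width in frames, `1 <= width < nrow(series)`
#'   (1 = identity). Widths approaching the area period annihilate the
#'   signal; [measure_rotation()] picks the width from the estimated period
#'   when asked to.
#' @return The series with `area` replaced by its smoothed values; the width
#'   is recorded in attribute `smoothing_width`.
#' @export
smooth_series <- function(series, width = 5) {
  stopifnot(is.data.frame(series), all(c("frame", "area") %in% names(series)))
  if (width %% 2 != 1 || width < 1 || width >= nrow(series)) {
    rlang::abort("`width` must be odd and in [1, length(series)).")
  }
  series$area <- smooth_ma(series$area, as.integer(width))
  attr(series, "smoothing_width") <- as.integer(width)
  series
}

# dominant period (frames) of a series from its sample autocorrelation:
# the first local maximum of the acf at lag >= 2, refined by parabolic
# interpolation. NA when no convincing peak exists.
estimate_period <- function(x, min_corr = 0.1) {
  n <- length(x)
  if (n < 6 || stats::sd(x) == 0) return(NA_real_)
  lag_max <- min(n - 2L, max(10L, floor(n / 2)))
  r <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE)$acf)[-1]
  for (l in 2:(length(r) - 1)) {
    if (r[l] > r[l - 1] && r[l] >= r[l + 1] && r[l] > min_corr) {
      denom <- r[l - 1] - 2 * r[l] + r[l + 1]
      frac <- if (denom < 0) 0.5 * (r[l - 1] - r[l + 1]) / denom else 0
      return(l + max(-0.5, min(0.5, frac)))
    }
  }
  NA_real_
}

# prominence of a local minimum: depth below the lower of the highest bars
# reachable left and right before meeting a deeper sample
trough_prominence <- function(y, i) {
  left <- if (i == 1) numeric(0) else y[(i - 1):1]
  right <- if (i == length(y)) numeric(0) else y[(i + 1):length(y)]
  wall <- function(side) {
    if (length(side) == 0) return(Inf)
    deeper <- which(side < y[i])
    top <- if (length(deeper)) side[seq_len(deeper[1] - 1)] else side
    if (length(top)) max(top) else -Inf
  }
  min(wall(left), wall(right)) - y[i]
}

#' Locate the troughs of an area-change curve
#'
#' Finds the local minima of the (smoothed) area series -- the frames where
#' the projected area reaches the bottom of each cycle. A sample qualifies
#' when it is strictly deeper than both neighbours (a flat run of equal
#' values deeper than both adjacent runs counts once, at its centre), its
#' prominence reaches `min_prominence`, and it lies at least `min_separation`
#' frames from every deeper accepted trough (deeper troughs win conflicts).
#'
#' @param series Data frame with `frame` and `area` columns.
#' @param min_separation Minimum spacing between accepted troughs, frames.
#' @param min_prominence Minimum prominence in area units; default 2% of the
#'   series mean.
#' @return Increasing vector of trough frame numbers (1-based). Signals a
#'   `rotospin_no_troughs` error when fewer than two are found, since no
#'   speed can then be measured.
#' @export
find_troughs <- function(series, min_separation = 3, min_prominence = NULL) {
  stopifnot(is.data.frame(series), nrow(series) >= 3)
  y <- series$area
  if (is.null(min_prominence)) min_prominence <- 0.02 * mean(y)
  runs <- rle(y)
  k <- length(runs$values)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- integer(0)
  if (k >= 3) {
    for (j in 2:(k - 1)) {
      if (runs$values[j] < runs$values[j - 1] && runs$values[j] < runs$values[j + 1]) {
        cand <- c(cand, (starts[j] + ends[j]) %/% 2L)
      }
    }
  }
  cand <- cand[vapply(cand, function(i) trough_prominence(y, i), numeric(1)) >=
                 min_prominence]
  # deepest-first greedy enforcement of the separation constraint
  keep <- integer(0)
  for (i in cand[order(y[cand])]) {
    if (all(abs(i - keep) >= min_separation)) keep <- c(keep, i)
  }
  keep <- sort(keep)
  if (length(keep) < 2) {
    rlang::abort("fewer than two troughs found: cannot measure a rotation speed.",
                 class = "rotospin_no_troughs")
  }
  series$frame[keep]
}

#' Rotation speed from trough frame numbers
#'
#' Converts the spacing of adjacent area-cycle troughs into revolutions per
#' minute: each adjacent pair `(X_{i-1}, X_i)` gives a per-cycle speed
#' `n = 60 * fps / (X_i - X_{i-1}) / symmetry_factor`. With
#' `symmetry_factor = 1` one area cycle is one full revolution; use
#' `symmetry_factor = 2` for shapes whose projection repeats twice per turn
#' (a texture-free symmetric ellipsoid rotating out of plane). The summary
#' follows the mean +/- maximum-deviation convention over the observed
#' cycles; a pooled estimate `60 * fps * K / (X_last - X_first) /
#' symmetry_factor` over all `K` cycles is reported alongside.
#'
#' @param troughs Strictly increasing trough frame numbers (>= 2).
#' @param fps Frame rate, frames/second.
#' @param symmetry_factor 1 or 2 (area repeats per revolution).
#' @param smoothing_width Bookkeeping: the kernel width used upstream.
#' @return A `rotation_result` object: `trough_frames`, `per_cycle_rpm`,
#'   `mean_rpm`, `mean_rpm_pooled`, `max_deviation_rpm`, `n_cycles`,
#'   `symmetry_factor`, `fps`, `smoothing_width`.
#' @examples
#' rotation_speed(c(10, 19), fps = 15)  # 60*15/9 = 100 rpm
#' @export
rotation_speed <- function(troughs, fps, symmetry_factor = 1,
                           smoothing_width = NA_integer_) {
  if (length(troughs) < 2 || any(diff(troughs) <= 0)) {
    rlang::abort("`troughs` must be >= 2 strictly increasing frame numbers.")
  }
  stopifnot(fps > 0, symmetry_factor %in% c(1, 2))
  per_cycle <- 60 * fps / diff(troughs) / symmetry_factor
  k <- length(per_cycle)
  mean_rpm <- mean(per_cycle)
  pooled <- 60 * fps * k / (troughs[k + 1] - troughs[1]) / symmetry_factor
  structure(list(
    trough_frames = troughs,
    per_cycle_rpm = per_cycle,
    mean_rpm = mean_rpm,
    mean_rpm_pooled = pooled,
    max_deviation_rpm = max(abs(per_cycle - mean_rpm)),
    n_cycles = k,
    symmetry_factor = symmetry_factor,
    fps = fps,
    smoothing_width = smoothing_width
  ), class = "rotation_result")
}

#' Analyse an existing area series into a rotation speed
#'
#' The denoise-and-read-off stage on its own: smooth, find troughs, apply
#' the trough-spacing formula. With `smooth = "auto"` (default) the kernel
#' width and trough separation are derived from an autocorrelation estimate
#' of the area period: width = largest odd number at most `ceiling(P/2)`
#' (keeping the kernel well below the period so the oscillation survives),
#' separation = `max(1, floor(0.6 * P))`. If no period can be estimated the
#' fixed defaults (width 5, separation 3) are used.
#'
#' @param series Data frame with `frame` and `area` columns.
#' @param smooth `"auto"`, or an odd integer kernel width (1 = none).
#' @param min_separation `"auto"` or an integer spacing in frames.
#' @param min_prominence Passed to [find_troughs()].
#' @param symmetry_factor 1 or 2, see [rotation_speed()].
#' @return A `rotation_result`; the (smoothed) series is attached as
#'   attribute `series`.
#' @export
analyze_area_series <- function(series, smooth = "auto",
                                min_separation = "auto",
                                min_prominence = NULL, symmetry_factor = 1) {
  fps <- attr(series, "fps")
  if (is.null(fps)) rlang::abort("`series` must carry an `fps` attribute.")
  auto_w <- identical(smooth, "auto")
  auto_s <- identical(min_separation, "auto")
  if (auto_w || auto_s) {
    p <- estimate_period(series$area)
    if (auto_w) {
      smooth <- if (is.na(p)) 5L else {
        w <- ceiling(p / 2)
        w <- as.integer(if (w %% 2 == 0) w - 1 else w)
        max(1L, min(w, as.integer(nrow(series)) - 2L))
      }
      if (smooth %% 2 == 0L) smooth <- smooth - 1L
    }
    if (auto_s) min_separation <- if (is.na(p)) 3L else max(1L, floor(0.6 * p))
  }
  smoothed <- smooth_series(series, width = smooth)
  troughs <- find_troughs(smoothed, min_separation = min_separation,
                          min_prominence = min_prominence)
  out <- rotation_speed(troughs, fps = fps, symmetry_factor = symmetry_factor,
                        smoothing_width = as.integer(smooth))
  attr(out, "series") <- smoothed
  out
}

#' Measure a cell's self-rotation speed from a video
#'
#' The end-to-end pipeline: per-frame preprocessing and segmentation, cell
#' selection and tracking into an area series, optional restriction to a
#' frame window (e.g. the stabilised tail of a recording), convolution
#' smoothing, trough detection, and the trough-spacing speed formula.
#'
#' @param stack A [frame_stack()].
#' @param seed_point,label Cell-of-interest selection ([select_cell()]).
#' @param mode `"outline"` (out-of-plane rotation) or `"quarter_box"`
#'   (in-plane rotation).
#' @param frames Optional integer window of frame numbers to analyse, e.g.
#'   `101:159`.
#' @param smooth,min_separation,min_prominence,symmetry_factor See
#'   [analyze_area_series()].
#' @param ... Further arguments to [build_area_series()] (segmentation and
#'   preprocessing parameters).
#' @return A `rotation_result` with the area series attached.
#' @export
measure_rotation <- function(stack, seed_point = NULL, label = NULL,
                             mode = c("outline", "quarter_box"),
                             frames = NULL, smooth = "auto",
                             min_separation = "auto", min_prominence = NULL,
                             symmetry_factor = 1, ...) {
  mode <- match.arg(mode)
  if (!is.null(frames)) stack <- stack[frames]
  series <- build_area_series(stack, seed_point = seed_point, label = label,
                              mode = mode, ...)
  analyze_area_series(series, smooth = smooth,
                      min_separation = min_separation,
                      min_prominence = min_prominence,
                      symmetry_factor = symmetry_factor)
}

#' @export
print.rotation_result <- function(x, ...) {
  cat(sprintf(
    paste0("<rotation_result> %.1f rpm (max dev %.1f) over %d cycles\n",
           "  troughs: %s\n  pooled: %.1f rpm | symmetry factor %d | fps %g\n"),
    x$mean_rpm, x$max_deviation_rpm, x$n_cycles,
    paste(x$trough_frames, collapse = ", "),
    x$mean_rpm_pooled, x$symmetry_factor, x$fps))
  invisible(x)
}
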