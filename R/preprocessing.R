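#' Logarithmic luminance mapping
#'
#' Maps grey level `L` to `i(L) = (N-1) * log(1 + L) / log(256)`, the
#' compressive mapping used before histogram-entropy calculations: it spreads
#' the dark end of the histogram so that the dark-corner population and the
#' normal-luminosity population stay distinguishable during shadow
#' correction. The log base cancels in the ratio.
#'
#' @param image Numeric matrix, intensities in \[0, 255\].
#' @param N Number of representable grey values (256 for 8-bit).
#' @return Numeric matrix, clipped to \[0, N-1\].
#' @examples
#' log_luminance_map(matrix(c(0, 15, 255), 1))  # 0, 127.5, 255
#' @export
log_luminance_map <- function(image, N = 256) {
  stopifnot(is.matrix(image), N >= 2)
  pmin(pmax((N - 1) * log1p(image) / log(256), 0), N - 1)
}

# shannon entropy (nats) of a soft histogram of the log-mapped image, bin
# width 1 on the 8-bit log-luminance scale; linear interpolation between
# adjacent bins keeps the objective continuous in the pixel values. The
# upper end is NOT clipped: clipping would let an arbitrarily large gain
# saturate the image into a zero-entropy constant, a degenerate optimum.
log_hist_entropy <- function(image) {
  v <- pmax(255 * log1p(as.vector(image)) / log(256), 0)
  lo <- floor(v)
  frac <- v - lo
  counts <- numeric(max(lo) + 2L)
  agg_lo <- rowsum(1 - frac, lo)
  counts[as.integer(rownames(agg_lo)) + 1L] <- agg_lo[, 1]
  up <- frac > 0
  if (any(up)) {
    agg_hi <- rowsum(frac[up], lo[up] + 1L)
    idx <- as.integer(rownames(agg_hi)) + 1L
    counts[idx] <- counts[idx] + agg_hi[, 1]
  }
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

# radial basis (rho^2, rho^4, ...) evaluated on a (possibly strided) grid
radial_basis <- function(height, width, n_terms, rows = seq_len(height),
                         cols = seq_len(width)) {
  ctr <- c((1 + height) / 2, (1 + width) / 2)
  rr <- matrix(rows, length(rows), length(cols))
  cc <- matrix(cols, length(rows), length(cols), byrow = TRUE)
  r2corner <- (1 - ctr[1])^2 + (1 - ctr[2])^2
  rho2 <- ((rr - ctr[1])^2 + (cc - ctr[2])^2) / r2corner
  lapply(seq_len(n_terms), function(k) rho2^k)
}

gain_from_coefs <- function(basis, beta) {
  g <- 1
  for (k in seq_along(beta)) g <- g + beta[k] * basis[[k]]
  g
}

#' Estimate a vignetting gain field by histogram-entropy minimization
#'
#' Fits a smooth multiplicative gain `g(r) = 1 + sum_k beta_k * rho^(2k)`
#' (`rho` = radius normalised to the corner, even powers up to
#' `model_order`) such that applying the gain minimises the Shannon entropy
#' of the unit-width-bin histogram of the log-mapped corrected image. The log
#' mapping (see [log_luminance_map()]) keeps the dark-corner population
#' separated in the histogram until the correction actually merges it with
#' the main population, which makes the entropy landscape far less prone to
#' spurious local optima than entropy on raw luminance. A vignetted frame has
#' a broad/bimodal histogram; a flat one is narrow, so minimum entropy means
#' maximal flatness.
#'
#' Optimisation is derivative-free: golden-section over the quadratic
#' coefficient, then Nelder-Mead over all coefficients (started from the 1-D
#' solution) when `model_order > 2`. Coefficients are constrained
#' non-negative so `g >= 1` everywhere (the gain only brightens, matching a
#' falloff-type artefact).
#'
#' @param image Numeric matrix in \[0, 255\], not constant.
#' @param model_order Highest radial power (even; 2, 4 or 6). Order 6 is the
#'   default: the exact inverse of a quadratic falloff `1 - s*rho^2` is the
#'   geometric series `1 + s*rho^2 + s^2*rho^4 + ...`, and three terms bring
#'   the corner approximation error under 1% for falloffs up to ~35%.
#' @param stride Pixel subsampling stride used during optimisation (the
#'   returned field is always full resolution).
#' @return Gain matrix (same shape as `image`, values >= 1) with attributes
#'   `coefficients` (the fitted betas) and `entropy` (achieved objective).
#' @export
estimate_vignette_gain <- function(image, model_order = 6, stride = 2) {
  stopifnot(is.matrix(image), model_order %in% c(2, 4, 6), stride >= 1)
  if (max(image) == min(image)) {
    rlang::abort("cannot estimate a gain field from a constant image.")
  }
  n_terms <- model_order / 2
  rows <- seq(1, nrow(image), by = stride)
  cols <- seq(1, ncol(image), by = stride)
  sub <- image[rows, cols, drop = FALSE]
  basis <- radial_basis(nrow(image), ncol(image), n_terms, rows, cols)

  obj1 <- function(b1) log_hist_entropy(sub * (1 + b1 * basis[[1]]))
  b1 <- stats::optimize(obj1, interval = c(0, 4))$minimum
  beta <- c(b1, rep(0, n_terms - 1))
  if (n_terms > 1) {
    objk <- function(b) {
      if (any(b < 0)) return(1e6 + sum(pmax(-b, 0)) * 1e3)
      log_hist_entropy(sub * gain_from_coefs(basis, b))
    }
    fit <- stats::optim(beta, objk, method = "Nelder-Mead",
                        control = list(maxit = 400, reltol = 1e-6))
    if (objk(fit$par) <= objk(beta)) beta <- pmax(fit$par, 0)
  }
  full_basis <- radial_basis(nrow(image), ncol(image), n_terms)
  gain <- gain_from_coefs(full_basis, beta)
  attr(gain, "coefficients") <- beta
  attr(gain, "entropy") <- log_hist_entropy(sub * gain_from_coefs(basis, beta))
  gain
}

#' Apply a multiplicative gain field
#'
#' Pixelwise product of image and gain, clipped to \[0, 255\].
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param gain Strictly positive gain matrix of the same shape.
#' @return Corrected image.
#' @export
correct_vignette <- function(image, gain) {
  if (!all(dim(image) == dim(gain))) rlang::abort("gain/image shape mismatch.")
  if (any(gain <= 0)) rlang::abort("gain must be strictly positive.")
  clip255(image * gain)
}

#' Gamma correction
#'
#' `f(I) = I^gamma` on intensities normalised to \[0, 1\], rescaled to
#' \[0, 255\]. `gamma < 1` brightens dark regions (lifting vignetted
#' corners); `gamma > 1` the converse. Strictly monotone, so pixel ordering
#' is preserved.
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param gamma Positive exponent. Default 0.4: small enough to flatten a
#'   typical ~30% corner falloff by well over half (in relative terms a
#'   multiplicative falloff is compressed roughly by the factor gamma), while
#'   keeping cells separable from background (contrast is restored by the
#'   stretch stage anyway).
#' @return Corrected image.
#' @export
gamma_correct <- function(image, gamma = 0.4) {
  if (!is.numeric(gamma) || length(gamma) != 1 || gamma <= 0) {
    rlang::abort("`gamma` must be a single positive number.")
  }
  255 * (clip255(image) / 255)^gamma
}

#' Piecewise-linear (segmented) contrast stretch
#'
#' Three linear segments map `[0, a] -> [0, y_a]`, `[a, b] -> [y_a, y_b]`,
#' `[b, M_f] -> [y_b, M_f]`, continuous at the breakpoints. Configured with a
#' middle slope above 1 this expands the grey interval occupied by the cells
#' while compressing the uninteresting dark and bright tails (stray light,
#' saturated impurities).
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param a,b Input breakpoints, `0 <= a < b <= M_f`.
#' @param y_a,y_b Output levels at the breakpoints, `0 <= y_a <= y_b <= M_f`.
#' @param M_f Maximum representable grey level.
#' @return Stretched image; the mapping is monotone non-decreasing.
#' @export
piecewise_linear_stretch <- function(image, a, b, y_a, y_b, M_f = 255) {
  if (!(a >= 0 && a < b && b <= M_f)) rlang::abort("need 0 <= a < b <= M_f.")
  if (!(y_a >= 0 && y_a <= y_b && y_b <= M_f)) {
    rlang::abort("need 0 <= y_a <= y_b <= M_f.")
  }
  x <- clip255(image)
  out <- x
  lo <- x <= a
  mid <- x > a & x <= b
  hi <- x > b
  out[lo] <- if (a > 0) x[lo] * y_a / a else y_a
  out[mid] <- y_a + (x[mid] - a) * (y_b - y_a) / (b - a)
  out[hi] <- if (b < M_f) y_b + (x[hi] - b) * (M_f - y_b) / (M_f - b) else y_b
  out
}

#' Min-max contrast stretch to a target interval
#'
#' `I' = (I - I_min) / (I_max - I_min) * (MAX - MIN) + MIN`, where
#' `I_min`/`I_max` are the image's own extremes, so the output exactly spans
#' `[MIN, MAX]`.
#'
#' @param image Numeric matrix, not constant.
#' @param MIN,MAX Target interval bounds, `MIN < MAX`.
#' @return Stretched image.
#' @export
minmax_stretch <- function(image, MIN = 0, MAX = 255) {
  stopifnot(MIN < MAX)
  lo <- min(image); hi <- max(image)
  if (hi == lo) rlang::abort("cannot stretch a constant image.")
  (image - lo) / (hi - lo) * (MAX - MIN) + MIN
}

#' Full preprocessing of one frame
#'
#' Vignette removal (gamma correction by default; the entropy-minimisation
#' gain fit behind `vignette = "entropy"`, which is markedly slower) followed
#' by contrast stretching (min-max by default, or the segmented linear
#' stretch). All arithmetic stays in floating point; the result is still on
#' the \[0, 255\] scale.
#'
#' @param image Numeric matrix in \[0, 255\].
#' @param vignette `"gamma"`, `"entropy"` or `"none"`.
#' @param gamma Exponent for the gamma route.
#' @param gain Optional precomputed gain field for the entropy route (fit
#'   once per video, applied per frame).
#' @param stretch `"minmax"`, `"piecewise"` or `"none"`.
#' @param stretch_params List of parameters for the chosen stretch
#'   (`MIN`/`MAX`, or `a`/`b`/`y_a`/`y_b`).
#' @return Preprocessed image.
#' @export
preprocess_frame <- function(image,
                             vignette = c("gamma", "entropy", "none"),
                             gamma = 0.4, gain = NULL,
                             stretch = c("minmax", "piecewise", "none"),
                             stretch_params = list()) {
  vignette <- match.arg(vignette)
  stretch <- match.arg(stretch)
  img <- switch(vignette,
    gamma = gamma_correct(image, gamma),
    entropy = {
      if (is.null(gain)) gain <- estimate_vignette_gain(image)
      correct_vignette(image, gain)
    },
    none = image
  )
  switch(stretch,
    minmax = do.call(minmax_stretch, c(list(img), stretch_params)),
    piecewise = do.call(piecewise_linear_stretch, c(list(img), stretch_params)),
    none = img
  )
}
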