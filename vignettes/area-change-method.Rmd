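---
title: "Measuring cell self-rotation with the area-change method"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring cell self-rotation with the area-change method}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the methods implemented in **rotospin**: the
image-formation model behind the synthetic scene generator, the
processing pipeline, and the reasoning behind every default that is not
self-evident.

## 1. Problem setting

A cell suspended in a microfluidic chamber spins in place under an
optically induced dielectrophoretic torque. Recordings are short
(order 10 s at 15 fps), low-magnification (a cell spans ~25 px),
low-contrast, vignetted toward the frame corners, and contaminated by
debris and sensor noise. The quantity of interest is the rotation rate
in rpm, typically between 30 and 160 rpm.

At this scale no internal landmark can be followed. Instead we exploit
that a non-spherical cell's *projected area* oscillates as it rotates
about an in-plane axis: the estimator is the spacing between successive
troughs of the area-versus-frame series,

$$ n = \frac{60 f}{X_i - X_{i-1}} \ \mathrm{rpm}, $$

with $f$ the frame rate and $X_i$ the trough frame indices.

## 2. Image-formation model (the scene generator)

`render_video()` produces frames from a fully specified model so that
every downstream algorithm can be tested against exact ground truth.

* **Cell geometry.** A cell is a shaded ellipsoid with semi-axes
  $(a, b, c)$ in pixels (default $12, 12, 8$, matching a ~12 µm
  lymphocyte at the reference magnification where 1 px ≈ 1 µm). For
  out-of-plane rotation at angle $\theta$, the projection is an ellipse
  with semi-axes $b$ and $\sqrt{a^2\cos^2\theta + c^2\sin^2\theta}$ —
  the exact signal the area method relies on. In-plane rotation keeps
  the outline fixed and rotates the texture.
* **Texture.** Optional dark membrane spots on a ring at radius $a/2$,
  rendered only on the camera-facing hemisphere. A spot breaks the
  half-turn symmetry of a bare ellipsoid and drives the
  quarter-bounding-box signal for in-plane rotation.
* **Motion.** Constant-velocity drift and/or a circular orbit,
  parameterised so the path starts exactly at the configured centroid.
* **Optics and sensor.** Quadratic radial vignette
  $g(r) = 1 - s\,(r/r_\mathrm{corner})^2$ multiplying the frame
  (default strength $s = 0.3$, i.e. 30 % darker corners); background
  level 140, cell level 185 on a 0–255 scale (deliberately low
  contrast); i.i.d. Gaussian sensor noise ($\sigma = 2$); a few static
  debris blobs.
* **Determinism.** All stochastic elements derive from `rng_seed`; each
  frame's noise uses a seed computed from `(rng_seed, t)`, so rendering
  frame 50 alone equals frame 50 of the full render, and the global RNG
  state is saved and restored.

**Realism and limits.** The generator reproduces the features that
actually stress the pipeline — small scale, low contrast, vignetting,
debris, noise, the half-turn symmetry ambiguity — but it idealises
others: perfect focus, rigid cells, no motion blur, no Brownian jitter,
no illumination flicker, and noise that is Gaussian rather than
Poisson-dominated. Accuracy numbers obtained on it should be read as
validating the *algorithms*, not as predictions of error on any given
microscope.

## 3. Preprocessing

1. **Vignette correction**, two routes:
   * `vignette = "gamma"` (default): power-law remap
     $I' = 255\,(I/255)^\gamma$. With $\gamma < 1$ dark corners are
     lifted more than the bright centre, flattening the field without
     estimating it.
   * `vignette = "entropy"`: fit a radial gain field
     $1 + \sum_k \beta_k \rho^{2k}$ (order 6) by minimising the entropy
     of the log-luminance histogram of the corrected image — a flat
     field concentrates the histogram. The search is a golden-section
     scan on the leading coefficient followed by Nelder–Mead on all
     coefficients. Two numerical details matter: the objective uses a
     *soft* histogram (each value spread linearly over its two
     neighbouring unit bins) so it is continuous in the coefficients,
     and the image is **not clipped to 255 inside the objective** —
     clipping lets absurdly large gains saturate the image to a
     constant, which has zero entropy and is a degenerate optimum.
2. **Log luminance map** $i(L) = (N-1)\log(1+L)/\log 256$, used inside
   the entropy objective.
3. **Contrast stretch**: min–max stretch to $[0, 255]$ by default, or a
   two-breakpoint piecewise-linear stretch.

### Why $\gamma = 0.4$

Flatness is measured as the coefficient of variation (CV = sd/mean) of
a cell-free frame: unlike the raw standard deviation, CV is invariant
to the overall brightness change that a gamma remap causes. For the
quadratic vignette model, a first-order expansion gives
$\mathrm{CV}(I^\gamma) \approx \gamma\,\mathrm{CV}(I)$, so halving the
CV requires $\gamma \le 0.5$ *with nothing to spare*: $\gamma = 0.5$
sits exactly on the margin and sampling noise can push it over. The
default $\gamma = 0.4$ buys headroom (expected CV ratio 0.4) while
staying mild enough not to crush cell/background contrast. This was
fixed from the closed-form analysis before any end-to-end runs.

## 4. Segmentation

* **Otsu threshold** computed exactly over the 256 grey levels by
  maximising between-class variance with cumulative sums; ties resolve
  to the smallest threshold. The test suite checks it against a brute
  force $O(256\,n)$ search.
* **Connected components**: 8-connected labelling (built on an
  adjacency graph; labels are renumbered by bounding-box position so
  they are deterministic), small-object removal (`min_area = 30` px —
  about a quarter of the smallest expected cell cross-section, safely
  above debris size), and a radius-1 disk dilation to heal single-pixel
  gaps in the low-contrast outline.

## 5. Area series and speed extraction

`build_area_series()` segments each frame, associates the tracked cell
by nearest centroid with constant-velocity prediction, and records
either the outline area or the quarter-bounding-box area (the pixel
count in the top-left quadrant of the bounding box, which oscillates
under in-plane rotation of a textured cell).

`analyze_area_series()` then:

1. **Smooths** with a centred moving average using *mirror padding*,
   which conserves the series mean exactly and avoids endpoint bias.
2. **Detects troughs** as local minima with a minimum separation and a
   minimum prominence (default 2 % of the mean area). Integer-valued
   series produce flat runs; a plateau lower than both neighbouring
   runs counts as one trough at its centre, otherwise ties at adjacent
   frames would silently split or drop cycles.
3. **Converts spacings to rpm** and divides by the `symmetry_factor`
   (2 for a bare out-of-plane ellipsoid, whose projection repeats every
   half turn; 1 when a visible feature breaks that symmetry). Both the
   mean of per-cycle rates and the pooled rate (first-to-last trough)
   are reported.

### Why smoothing width and separation are `"auto"`

Fixed defaults cannot serve the whole 30–160 rpm range: at 155 rpm with
symmetry factor 2 a cycle lasts only $60 \cdot 15 / 155 / 2 \approx
2.9$ frames, so a width-5 moving average would annihilate the signal
that a slow rotator needs for denoising. In `"auto"` mode the cycle
period $P$ is first estimated from the autocorrelation of the raw
series (first local maximum, parabolically refined); the smoothing
width is then the largest odd integer $\le \lceil P/2 \rceil$ and the
minimum trough separation is $\max(1, \lfloor 0.6 P \rfloor)$.
Explicitly supplied values are always honoured verbatim.

## 6. Trajectory tracking

`track_trajectory()` localises the cell per frame by frame differencing
(consecutive-frame absolute difference, Otsu-thresholded) to find
motion candidates, gates them against a constant-velocity prediction,
and refines the accepted position to the centroid of the cell's
segmented component in the *current* frame — the frame-difference blob
itself straddles two frames and lags the true position by half a step.
If no candidate passes the gate the tracker coasts on the prediction
for up to `coastdown` frames before declaring the track lost.

## 7. Validation scope

The test-suite and `scripts/acceptance.R` exercise: the 86 rpm
reference scenario (159 frames, troughs read from frames 101–159); a
sweep of 30/60/86/120/155 rpm across five seeds each (relative error
bounded at 7 %); an in-plane rotator via the quarter-box series; both
vignette routes on cell-free frames (CV at least halved; fitted corner
gain within 5 % of truth); linear, circular and two-cell trajectories
(RMS error bounded at 2 px, identities stable); exhaustive-search
agreement of the Otsu threshold; analytic anchor points of every
intensity transform; and byte-level reproducibility of all written
outputs under a fixed seed. All scenes are 96×96 to 200×80 px, 40–159
frames. The accompanying numbers quoted in the README come from
`Rscript scripts/acceptance.R --seed 1`.
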