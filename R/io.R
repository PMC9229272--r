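rgb_to_gray <- function(arr) {
  # classic luma weights; input HxWx{3,4} in [0,1]
  arr[, , 1] * 0.299 + arr[, , 2] * 0.587 + arr[, , 3] * 0.114
}

to_gray255 <- function(x) {
  if (length(dim(x)) == 3) x <- rgb_to_gray(x)
  x * 255
}

#' Read a video into a frame stack
#'
#' Supported dialects: multi-page TIFF (pages in file order), a directory of
#' PNG or TIFF frames (sorted by the numeric part of the filename, so both
#' zero-padded and bare numbering work), or AVI. Colour frames are converted
#' to grayscale with the classic luma weights (0.299, 0.587, 0.114). AVI
#' decoding has no installed backend in this build and raises an informative
#' error; re-encode to a TIFF stack or PNG sequence first.
#'
#' @param path File (TIFF stack) or directory (frame sequence).
#' @param fps Acquisition frame rate to attach, frames/second.
#' @param dialect `"auto"` (from the path), `"tiff_stack"`, `"png_dir"` or
#'   `"avi"`.
#' @return A [frame_stack()].
#' @export
read_frames <- function(path, fps, dialect = c("auto", "tiff_stack", "png_dir", "avi")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    dialect <- if (dir.exists(path)) "png_dir"
      else if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff_stack"
      else if (grepl("\\.avi$", path, ignore.case = TRUE)) "avi"
      else rlang::abort("cannot infer input dialect from path; set `dialect`.")
  }
  if (dialect == "avi") {
    rlang::abort("AVI decoding is not supported in this build; convert to a TIFF stack or PNG sequence.")
  }
  if (!file.exists(path)) rlang::abort(sprintf("input not found: %s", path))
  frames <- switch(dialect,
    tiff_stack = {
      pages <- tiff::readTIFF(path, all = TRUE)
      if (!is.list(pages)) pages <- list(pages)
      lapply(pages, to_gray255)
    },
    png_dir = {
      files <- list.files(path, pattern = "\\.(png|tiff?)$", ignore.case = TRUE,
                          full.names = TRUE)
      if (length(files) == 0) rlang::abort(sprintf("no PNG/TIFF frames in %s", path))
      num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
      files <- files[order(num, basename(files))]
      lapply(files, function(f) {
        if (grepl("\\.png$", f, ignore.case = TRUE)) to_gray255(png::readPNG(f))
        else to_gray255(tiff::readTIFF(f))
      })
    })
  frame_stack(frames, fps)
}

#' Write a frame stack to disk
#'
#' 8-bit grayscale output, either a multi-page TIFF (`path` ending in
#' `.tif`/`.tiff`) or a directory of zero-padded PNG frames. Values are
#' rounded to integers; a written-then-read stack is bit-identical.
#'
#' @param stack A [frame_stack()].
#' @param path Output TIFF file or directory.
#' @return `path`, invisibly.
#' @export
write_frames <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  imgs <- lapply(stack$frames, function(f) round(clip255(f)) / 255)
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(imgs, path, bits.per.sample = 8L)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(imgs)) {
      png::writePNG(imgs[[i]],
                    file.path(path, sprintf("frame_%04d.png", i)))
    }
  }
  invisible(path)
}

#' Write the ground-truth table of a synthetic scene
#'
#' CSV with columns `frame` (1-based), `angle_rad`, `row`, `col`, `area_px`.
#'
#' @param scene A [render_video()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(scene, path) {
  utils::write.csv(scene$truth, path, row.names = FALSE)
  invisible(path)
}

#' Write pipeline results to an output directory
#'
#' Emits `result.json` (all rotation-result fields plus a full configuration
#' echo sufficient to reproduce the run), `series.csv` (frame, area_px) and,
#' when a trajectory is given, `trajectory.csv` (frame, row, col, step_px).
#' Re-running with the same configuration and seed reproduces the files
#' byte-for-byte.
#'
#' @param result A `rotation_result`.
#' @param series An `area_series` tibble (defaults to the one attached to
#'   `result`).
#' @param traj Optional `trajectory` tibble.
#' @param outdir Output directory (created if needed).
#' @param config Optional named list echoed into the JSON under `config`.
#' @return Named character vector of the files written, invisibly.
#' @export
write_results <- function(result, series = attr(result, "series"), traj = NULL,
                          outdir = ".", config = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- c(result = file.path(outdir, "result.json"),
             series = file.path(outdir, "series.csv"))
  payload <- unclass(result)
  payload$config <- config
  jsonlite::write_json(payload, files[["result"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  utils::write.csv(as.data.frame(series), files[["series"]], row.names = FALSE)
  if (!is.null(traj)) {
    files[["trajectory"]] <- file.path(outdir, "trajectory.csv")
    utils::write.csv(as.data.frame(traj), files[["trajectory"]], row.names = FALSE)
  }
  invisible(files)
}

#' Read a result JSON back into a rotation_result
#'
#' @param path Path to a `result.json` written by [write_results()].
#' @return A `rotation_result` (the configuration echo is kept in attribute
#'   `config`).
#' @export
read_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  config <- x$config
  x$config <- NULL
  out <- structure(x, class = "rotation_result")
  attr(out, "config") <- config
  out
}
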