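#' Frame stacks: time series of 8-bit film images
#'
#' A `trfd_frame_stack` holds the raw time-resolved film measurement: an
#' ordered sequence of single-channel (red-channel) 8-bit images recorded by
#' the high-speed camera, together with the frame rate, the physical pixel
#' pitch on the film plane, and optionally the frame index at which the beam
#' starts.
#'
#' Pixel values (PV) are integers in `[0, 255]` stored as a 3-D `raw` array
#' `[row, column, frame]` (one byte per pixel, as the camera records them);
#' compare or convert with `as.integer()`. Rows map to the y axis (row `i`
#' is at `origin_y + (i - 0.5) * pitch`, y up) and columns to the x axis,
#' matching [scalar_map()].
#'
#' @param frames 3-D integer or raw array `[ny, nx, n_frames]`, or a list of
#'   equally sized matrices, with values in `[0, 255]`.
#' @param fps Frame rate in frames per second (> 0).
#' @param pixel_pitch_mm Physical pixel pitch in mm (> 0); the default 0.14 mm
#'   corresponds to a 9 x 9 cm camera area imaged at 640 x 640 pixels.
#' @param beam_start_index Optional 1-based index of the first frame at or
#'   after beam start.
#' @param origin_mm Numeric length-2, physical (x, y) of the lower-left grid
#'   corner in mm. Defaults to centring the image on the isocenter.
#'
#' @return A `trfd_frame_stack` object.
#' @export
frame_stack <- function(frames, fps, pixel_pitch_mm = 0.14,
                        beam_start_index = NULL, origin_mm = NULL) {
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (ncol(dims) == 0) stop_trfd("`frames` is empty")
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop_trfd("all frames must share one shape", "trfd_shape_error")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(dims[1, ])))
  }
  if (length(dim(frames)) == 2L) dim(frames) <- c(dim(frames), 1L)
  if (length(dim(frames)) != 3L) stop_trfd("`frames` must be a 3-D array")
  if (!is.raw(frames)) {
    if (anyNA(frames) || min(frames) < 0 || max(frames) > 255) {
      stop_trfd("pixel values must be integers in [0, 255]", "trfd_range_error")
    }
    if (any(frames != floor(frames))) {
      stop_trfd("pixel values must be integers (8-bit)", "trfd_range_error")
    }
    d <- dim(frames)
    frames <- as.raw(frames)
    dim(frames) <- d
  }
  if (!is.numeric(fps) || length(fps) != 1L || fps <= 0) {
    stop_trfd("`fps` must be a positive scalar")
  }
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop_trfd("`pixel_pitch_mm` must be positive")
  }
  ny <- dim(frames)[1]; nx <- dim(frames)[2]
  if (is.null(origin_mm)) {
    origin_mm <- c(-nx * pixel_pitch_mm / 2, -ny * pixel_pitch_mm / 2)
  }
  structure(
    list(frames = frames, fps = fps, pixel_pitch_mm = pixel_pitch_mm,
         beam_start_index = beam_start_index, origin_mm = origin_mm),
    class = "trfd_frame_stack")
}

#' @export
print.trfd_frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<trfd_frame_stack> %d frames of %d x %d px @ %g fps (%.3g s), pitch %g mm\n",
    d[3], d[1], d[2], x$fps, d[3] / x$fps, x$pixel_pitch_mm))
  if (!is.null(x$beam_start_index)) {
    cat(sprintf("  beam start at frame %d\n", x$beam_start_index))
  }
  invisible(x)
}

#' @rdname frame_stack
#' @param x A `trfd_frame_stack`.
#' @export
n_frames <- function(x) dim(x$frames)[3]

#' @rdname frame_stack
#' @export
frame_times <- function(x) (seq_len(n_frames(x)) - 1) / x$fps

#' Read and write frame stacks
#'
#' A frame stack on disk is a directory of zero-padded 8-bit grayscale PNGs
#' (`frame_000001.png`, ...) plus a `meta.json` sidecar holding `fps`,
#' `pixel_pitch_mm` and optionally `beam_start_index` and `origin_mm`.
#' Alternatively `path` may point to a single multi-page 8-bit TIFF with the
#' sidecar `<path>.json` next to it. Round trips are bit-exact.
#'
#' @param path Directory (PNG stack) or `.tif` file (multi-page TIFF).
#' @return [read_frame_stack()] returns a `trfd_frame_stack`;
#'   [write_frame_stack()] returns `path` invisibly.
#' @export
read_frame_stack <- function(path) {
  if (dir.exists(path)) {
    meta_file <- file.path(path, "meta.json")
    if (!file.exists(meta_file)) {
      stop_trfd(sprintf("metadata sidecar not found: %s", meta_file),
                "trfd_io_error")
    }
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    files <- sort(list.files(path, pattern = "^frame_\\d+\\.png$",
                             full.names = TRUE))
    if (length(files) == 0) stop_trfd("no frame_*.png images found", "trfd_io_error")
    mats <- lapply(files, function(f) {
      img <- png::readPNG(f)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      # readPNG rescales to [0,1]; undo and restore y-up row order
      m <- round(img * 255)
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    })
    dims <- vapply(mats, dim, integer(2))
    if (any(dims != dims[, 1])) {
      stop_trfd("inconsistent frame shapes in stack", "trfd_shape_error")
    }
  } else if (file.exists(path)) {
    meta_file <- paste0(path, ".json")
    if (!file.exists(meta_file)) {
      stop_trfd(sprintf("metadata sidecar not found: %s", meta_file),
                "trfd_io_error")
    }
    meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
    pages <- tiff::readTIFF(path, all = TRUE)
    mats <- lapply(pages, function(img) {
      if (length(dim(img)) == 3L) img <- img[, , 1]
      m <- round(img * 255)
      m[rev(seq_len(nrow(m))), , drop = FALSE]
    })
  } else {
    stop_trfd(sprintf("path not found: %s", path), "trfd_io_error")
  }
  frame_stack(mats, fps = meta$fps, pixel_pitch_mm = meta$pixel_pitch_mm,
              beam_start_index = meta$beam_start_index,
              origin_mm = meta$origin_mm)
}

#' @rdname read_frame_stack
#' @param stack A `trfd_frame_stack`.
#' @param format `"png"` (directory of PNGs) or `"tiff"` (one multi-page file).
#' @export
write_frame_stack <- function(stack, path, format = c("png", "tiff")) {
  format <- match.arg(format)
  meta <- list(fps = stack$fps, pixel_pitch_mm = stack$pixel_pitch_mm,
               beam_start_index = stack$beam_start_index,
               origin_mm = stack$origin_mm)
  nf <- n_frames(stack)
  # flip back to image row order (row 1 = top) for the on-disk raster
  as_img <- function(i) {
    m <- stack$frames[, , i]
    m <- matrix(as.integer(m), nrow = dim(stack$frames)[1])
    m[rev(seq_len(nrow(m))), , drop = FALSE] / 255
  }
  if (format == "png") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(meta, file.path(path, "meta.json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
    for (i in seq_len(nf)) {
      png::writePNG(as_img(i),
                    file.path(path, sprintf("frame_%06d.png", i)))
    }
  } else {
    tiff::writeTIFF(lapply(seq_len(nf), as_img), path, bits.per.sample = 8L)
    jsonlite::write_json(meta, paste0(path, ".json"),
                         auto_unbox = TRUE, null = "null", digits = NA)
  }
  invisible(path)
}
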