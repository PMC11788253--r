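#' Scalar maps: 2-D physical-units grids with validity masks
#'
#' A `trfd_scalar_map` carries a 2-D field (dose, delta-t, dose rate, gamma)
#' on a uniform grid with physical geometry. Element `[i, j]` sits at
#' `x = origin_mm[1] + (j - 0.5) * pixel_pitch_mm`,
#' `y = origin_mm[2] + (i - 0.5) * pixel_pitch_mm` (x right, y up, isocenter
#' at the map center by default). The `mask` flags pixels whose value is
#' meaningful; masked-out pixels may hold `NA`.
#'
#' @param values Numeric matrix.
#' @param pixel_pitch_mm Grid spacing in mm (> 0).
#' @param origin_mm Physical (x, y) of the lower-left grid corner, mm.
#'   Defaults to centring the grid on (0, 0).
#' @param mask Logical matrix of the same shape; default all `TRUE`.
#' @return A `trfd_scalar_map`.
#' @export
scalar_map <- function(values, pixel_pitch_mm, origin_mm = NULL, mask = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    stop_trfd("`pixel_pitch_mm` must be positive")
  }
  if (is.null(origin_mm)) {
    origin_mm <- c(-ncol(values) * pixel_pitch_mm / 2,
                   -nrow(values) * pixel_pitch_mm / 2)
  }
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(values), ncol(values))
  }
  mask <- matrix(as.logical(mask), nrow(values), ncol(values))
  if (any(mask & !is.finite(values))) {
    stop_trfd("non-finite values on masked-in pixels", "trfd_range_error")
  }
  structure(list(values = values, pixel_pitch_mm = pixel_pitch_mm,
                 origin_mm = as.numeric(origin_mm), mask = mask),
            class = "trfd_scalar_map")
}

#' @export
print.trfd_scalar_map <- function(x, ...) {
  rng <- if (any(x$mask)) range(x$values[x$mask]) else c(NA, NA)
  cat(sprintf(
    "<trfd_scalar_map> %d x %d px @ %g mm, %d masked-in, range [%.4g, %.4g]\n",
    nrow(x$values), ncol(x$values), x$pixel_pitch_mm, sum(x$mask),
    rng[1], rng[2]))
  invisible(x)
}

# pixel-center coordinate vectors
map_x <- function(m) m$origin_mm[1] + (seq_len(ncol(m$values)) - 0.5) * m$pixel_pitch_mm
map_y <- function(m) m$origin_mm[2] + (seq_len(nrow(m$values)) - 0.5) * m$pixel_pitch_mm

#' Convert a scalar map to a tidy tibble
#'
#' @param x A `trfd_scalar_map`.
#' @param ... Unused.
#' @return A tibble with columns `x_mm`, `y_mm`, `value`, `mask`.
#' @export
as_tibble.trfd_scalar_map <- function(x, ...) {
  tibble(
    x_mm = rep(map_x(x), each = nrow(x$values)),
    y_mm = rep(map_y(x), times = ncol(x$values)),
    value = as.vector(x$values),
    mask = as.vector(x$mask))
}

#' Read and write scalar maps
#'
#' Two dialects, lossless within float precision: a CSV matrix (row 1 of the
#' file is the top image row) plus a `<path>.json` geometry sidecar holding
#' `pixel_pitch_mm`, `origin_mm` and the mask (as 0/1, omitted when all in),
#' or a 32-bit float TIFF with the same sidecar (masked-out pixels stored as
#' NaN).
#'
#' @param path File path; dialect chosen by extension (`.csv` or `.tif`/`.tiff`).
#' @return [read_scalar_map()] returns a `trfd_scalar_map`.
#' @export
read_scalar_map <- function(path) {
  meta_file <- paste0(path, ".json")
  if (!file.exists(meta_file)) {
    stop_trfd(sprintf("geometry sidecar not found: %s", meta_file),
              "trfd_io_error")
  }
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  if (is.null(meta$pixel_pitch_mm) || is.null(meta$origin_mm)) {
    stop_trfd("sidecar lacks pixel_pitch_mm/origin_mm", "trfd_io_error")
  }
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    vals <- as.matrix(read.csv(path, header = FALSE))
    dimnames(vals) <- NULL
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  } else {
    vals <- tiff::readTIFF(path, as.is = FALSE)
    if (length(dim(vals)) == 3L) vals <- vals[, , 1]
    vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
    # TIFF stores the [0, 1]-normalized field; undo via the sidecar range
    if (!is.null(meta$value_range)) {
      vals <- vals * diff(meta$value_range) + meta$value_range[1]
    }
  }
  mask <- if (!is.null(meta$mask)) {
    matrix(as.logical(meta$mask), nrow(vals), ncol(vals))
  } else !is.na(vals) & is.finite(vals)
  scalar_map(vals, meta$pixel_pitch_mm, meta$origin_mm, mask)
}

#' @rdname read_scalar_map
#' @param map A `trfd_scalar_map`.
#' @export
write_scalar_map <- function(map, path) {
  meta <- list(pixel_pitch_mm = map$pixel_pitch_mm,
               origin_mm = map$origin_mm)
  if (!all(map$mask)) meta$mask <- as.integer(map$mask)
  vals <- map$values
  vals[!map$mask] <- NA_real_
  is_csv <- grepl("\\.csv$", path, ignore.case = TRUE)
  if (!is_csv) {
    # float TIFF holds a [0, 1]-normalized field; range goes in the sidecar
    rng <- range(vals[is.finite(vals)], 0)
    if (diff(rng) == 0) rng[2] <- rng[1] + 1
    meta$value_range <- rng
  }
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  vals <- vals[rev(seq_len(nrow(vals))), , drop = FALSE]
  if (is_csv) {
    write.table(vals, path, sep = ",", row.names = FALSE, col.names = FALSE)
  } else {
    v <- (vals - rng[1]) / diff(rng)
    v[is.na(v)] <- 0
    tiff::writeTIFF(v, path, bits.per.sample = 32L, reduce = FALSE)
  }
  invisible(path)
}

#' Heat-map plot of a scalar map
#'
#' @param object A `trfd_scalar_map`.
#' @param ... Unused.
#' @param name Fill-scale label.
#' @return A ggplot object.
#' @export
autoplot.trfd_scalar_map <- function(object, ..., name = "value") {
  df <- as_tibble(object)
  df$value[!df$mask] <- NA_real_
  ggplot2::ggplot(df, ggplot2::aes(.data$x_mm, .data$y_mm, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = name, na.value = "grey90") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x [mm]", y = "y [mm]") +
    ggplot2::theme_minimal()
}
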