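#' Spot lists: ordered PBS delivery specifications
#'
#' A spot list is the plain-text beam-delivery specification used by
#' pencil-beam-scanning gantries: one spot per line with its lateral position
#' (x, y in mm at isocenter) and its monitor-unit (MU) weight. The line order
#' is the delivery order. In R a spot list is a tibble with columns `x_mm`,
#' `y_mm`, `mu` and class `trfd_spot_list`, so it pipes through dplyr verbs;
#' delivery order is the row order.
#'
#' @param x_mm,y_mm Spot positions in mm.
#' @param mu Monitor units per spot (> 0).
#' @return A `trfd_spot_list` tibble.
#' @export
spot_list <- function(x_mm, y_mm, mu) {
  out <- tibble(x_mm = as.numeric(x_mm), y_mm = as.numeric(y_mm),
                mu = as.numeric(mu))
  validate_spot_list(out)
}

validate_spot_list <- function(x) {
  if (nrow(x) == 0) stop_trfd("spot list is empty", "trfd_parse_error")
  if (anyNA(x)) stop_trfd("spot list contains non-numeric fields",
                          "trfd_parse_error")
  if (any(x$mu <= 0)) stop_trfd("all spot MU values must be positive",
                                "trfd_parse_error")
  class(x) <- unique(c("trfd_spot_list", class(x)))
  x
}

#' Parse, read and write plain-text spot lists
#'
#' The on-disk format is whitespace-separated `x_mm y_mm mu`, one spot per
#' line; blank lines and lines starting with `#` are ignored.
#'
#' @param text Character scalar (whole file) or vector of lines.
#' @return A `trfd_spot_list` tibble, one row per spot, in delivery order.
#' @export
parse_spot_list <- function(text) {
  lines <- unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) stop_trfd("spot list is empty", "trfd_parse_error")
  fields <- strsplit(lines, "\\s+")
  n <- lengths(fields)
  if (any(n != 3L)) {
    stop_trfd(sprintf("line %d does not have 3 fields",
                      which(n != 3L)[1]), "trfd_parse_error")
  }
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(3)))
  if (anyNA(vals)) stop_trfd("non-numeric field in spot list",
                             "trfd_parse_error")
  spot_list(vals[1, ], vals[2, ], vals[3, ])
}

#' @rdname parse_spot_list
#' @param path File path (conventionally `*.spots.txt`).
#' @export
read_spot_list <- function(path) {
  if (!file.exists(path)) stop_trfd(sprintf("file not found: %s", path),
                                    "trfd_io_error")
  parse_spot_list(readLines(path))
}

#' @rdname parse_spot_list
#' @param spots A `trfd_spot_list`.
#' @param comment Optional character vector written as `#` header lines.
#' @export
write_spot_list <- function(spots, path, comment = NULL) {
  spots <- validate_spot_list(as_tibble(spots))
  lines <- c(
    if (length(comment)) paste("#", comment),
    sprintf("%.6g %.6g %.6g", spots$x_mm, spots$y_mm, spots$mu))
  writeLines(lines, path)
  invisible(path)
}

#' Reorder the delivery sequence of a spot list
#'
#' Changing the delivery order leaves the final dose distribution untouched
#' but reshapes the time structure, and with it the per-pixel PBS dose rate —
#' the degree of freedom exploited by dose-rate-optimized scan patterns.
#'
#' @param spots A `trfd_spot_list`.
#' @param order Integer permutation of `1:nrow(spots)`, or `"snake"` for the
#'   standard boustrophedon order: rows sorted by descending y, alternating x
#'   direction row by row (first row left to right).
#' @return The reordered `trfd_spot_list`.
#' @export
reorder_spot_list <- function(spots, order) {
  spots <- validate_spot_list(as_tibble(spots))
  n <- nrow(spots)
  if (is.character(order) && identical(order, "snake")) {
    idx <- snake_order(spots$x_mm, spots$y_mm)
  } else {
    idx <- as.integer(order)
    if (length(idx) != n || !setequal(idx, seq_len(n))) {
      stop_trfd("`order` is not a permutation of the spot indices")
    }
  }
  validate_spot_list(spots[idx, ])
}

snake_order <- function(x, y) {
  rows <- match(y, sort(unique(y), decreasing = TRUE))
  ord <- order(rows, ifelse(rows %% 2 == 1, x, -x))
  ord
}
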