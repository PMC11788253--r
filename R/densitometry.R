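#' Pixel value to optical density
#'
#' Standard transmission densitometry with the camera's full-scale value as
#' the incident intensity: `OD = log10(2^b / (PV + 1))`. A saturated pixel
#' (`PV = 2^b - 1`) has OD 0; OD increases as the film darkens.
#'
#' @param pv Pixel values (scalar, vector, matrix or array) in
#'   `[0, 2^bit_depth - 1]`.
#' @param bit_depth Bits per channel; 8 for the red channel used here.
#' @return Optical densities, same shape as `pv`.
#' @export
pv_to_od <- function(pv, bit_depth = 8) {
  if (is.raw(pv)) {
    d <- dim(pv)
    pv <- as.integer(pv)
    dim(pv) <- d
  }
  full <- 2^bit_depth
  if (min(pv) < 0 || max(pv) > full - 1) {
    stop_trfd(sprintf("pixel values must lie in [0, %d]", full - 1),
              "trfd_range_error")
  }
  log10(full / (pv + 1))
}

#' @rdname pv_to_od
#' @param od Optical densities (>= 0).
#' @return [od_to_pv()] returns the rounded integer pixel value
#'   `2^b / 10^OD - 1`; it inverts [pv_to_od()] exactly on integer PV.
#' @export
od_to_pv <- function(od, bit_depth = 8) {
  if (min(od) < 0) stop_trfd("OD must be non-negative", "trfd_range_error")
  pv <- round(2^bit_depth / 10^od - 1)
  pmin(pmax(pv, 0), 2^bit_depth - 1)
}

#' Net optical density of a frame stack
#'
#' Subtracts the first frame's OD per pixel, referencing each pixel to its own
#' pre-irradiation transmission so that frame 1 has net OD exactly 0.
#'
#' @param stack A [frame_stack()] with at least 2 frames.
#' @param bit_depth Bits per channel.
#' @return A numeric array shaped like `stack$frames` with the per-pixel
#'   OD change relative to the first frame.
#' @export
net_od <- function(stack, bit_depth = 8) {
  if (n_frames(stack) < 2) {
    stop_trfd("net OD needs at least 2 frames", "trfd_shape_error")
  }
  od <- pv_to_od(stack$frames, bit_depth)
  sweep(od, c(1, 2), od[, , 1])
}

#' Fit the net-OD to dose calibration curve
#'
#' Fits `D = a + b * OD_net + c * OD_net^m` by least squares. The exponent
#' `m` is profiled: for each candidate `m` in `(1, 5]` the remaining
#' parameters are an exact linear solve, and a 1-D golden-section search picks
#' the `m` minimizing the residual sum of squares. When the power term is not
#' identifiable (data consistent with a straight line) `c` collapses to ~0 and
#' the fit is flagged.
#'
#' @param points Data frame with columns `od_net` and `dose` (Gy); at least 5
#'   points spanning a monotone OD range including near zero.
#' @param m_bounds Search interval for the exponent.
#' @return A `trfd_calibration` object with elements `a`, `b`, `c`, `m`,
#'   `rms` (residual RMS, Gy), `m_identifiable`, `od_range`, and the data.
#' @export
fit_od_to_dose <- function(points, m_bounds = c(1 + 1e-6, 5)) {
  points <- as_tibble(points)
  if (!all(c("od_net", "dose") %in% names(points))) {
    stop_trfd("`points` needs columns od_net and dose")
  }
  od <- as.numeric(points$od_net); dose <- as.numeric(points$dose)
  if (length(od) < 5) {
    stop_trfd("need at least 5 calibration points", "trfd_fit_error")
  }
  if (any(od < 0)) stop_trfd("negative od_net in calibration points",
                             "trfd_range_error")
  pw <- function(x, m) ifelse(x > 0, x^m, 0)  # 0^m := 0
  rss_m <- function(m) {
    X <- cbind(1, od, pw(od, m))
    sum(lm.fit(X, dose)$residuals^2)
  }
  opt <- optimize(rss_m, m_bounds, tol = 1e-10)
  m <- opt$minimum
  fit <- lm.fit(cbind(1, od, pw(od, m)), dose)
  cf <- unname(fit$coefficients)
  cf[is.na(cf)] <- 0
  rms <- sqrt(mean(fit$residuals^2))
  # m is unidentifiable when the power term contributes nothing
  lin_rss <- sum(lm.fit(cbind(1, od), dose)$residuals^2)
  scale2 <- sum((dose - mean(dose))^2)
  m_ident <- (lin_rss - opt$objective) > 1e-10 * max(scale2, 1)
  cal <- structure(
    list(a = cf[1], b = cf[2], c = cf[3], m = m, rms = rms,
         m_identifiable = m_ident, od_range = range(od),
         points = tibble(od_net = od, dose = dose)),
    class = "trfd_calibration")
  chk <- seq(max(1e-6, cal$od_range[1]), max(cal$od_range[2], 1e-5),
             length.out = 200)
  if (any(diff(apply_calibration(chk, cal)) <= 0)) {
    stop_trfd("fitted curve is not increasing on the data range",
              "trfd_fit_error")
  }
  cal
}

#' @rdname fit_od_to_dose
#' @param a,b,c,m Calibration parameters, for constructing a calibration
#'   object directly (e.g. from published values): intercept `a` (Gy), linear
#'   coefficient `b` (Gy/OD), power coefficient `c` and exponent `m`.
#' @param od_range OD range over which the curve is considered valid.
#' @export
calibration_params <- function(a, b, c, m, od_range = c(0, 2)) {
  if (m <= 0) stop_trfd("`m` must be positive")
  cal <- structure(list(a = a, b = b, c = c, m = m, rms = NA_real_,
                        m_identifiable = TRUE, od_range = od_range,
                        points = NULL),
                   class = "trfd_calibration")
  chk <- seq(max(1e-6, od_range[1]), od_range[2], length.out = 200)
  if (any(diff(apply_calibration(chk, cal)) <= 0)) {
    stop_trfd("OD to dose mapping must be increasing on od_range")
  }
  cal
}

#' @export
print.trfd_calibration <- function(x, ...) {
  cat(sprintf(
    "<trfd_calibration> D = %.4g + %.4g OD + %.4g OD^%.4g  (rms %.3g Gy)\n",
    x$a, x$b, x$c, x$m, x$rms))
  if (!x$m_identifiable) cat("  note: power term unidentifiable (linear data)\n")
  invisible(x)
}

#' @export
tidy.trfd_calibration <- function(x, ...) {
  tibble(term = c("a", "b", "c", "m"),
         estimate = c(x$a, x$b, x$c, x$m),
         unit = c("Gy", "Gy/OD", "Gy/OD^m", ""))
}

#' @export
glance.trfd_calibration <- function(x, ...) {
  tibble(rms = x$rms,
         n = if (is.null(x$points)) NA_integer_ else nrow(x$points),
         m_identifiable = x$m_identifiable)
}

#' Convert net OD to relative dose
#'
#' Evaluates the fitted calibration curve elementwise. Slightly negative
#' OD values (camera noise around zero dose) are clipped to 0 before the
#' fractional power; values below `-neg_tol` raise an error.
#'
#' @param od_net Net OD (any shape).
#' @param params A `trfd_calibration`.
#' @param neg_tol Most negative tolerated od_net.
#' @return Dose in Gy, same shape.
#' @export
apply_calibration <- function(od_net, params, neg_tol = 0.02) {
  if (min(od_net) < -neg_tol) {
    stop_trfd("od_net below tolerance (negative beyond noise)",
              "trfd_range_error")
  }
  od <- pmax(od_net, 0)
  params$a + params$b * od + params$c * od^params$m
}

#' Invert the calibration curve (dose to net OD)
#'
#' Vectorized bisection on the monotone branch; the round trip
#' `apply_calibration(invert_calibration(D))` holds to better than 1e-9 Gy.
#'
#' @param dose Dose in Gy, any shape; must lie within the calibrated range
#'   `[a, apply_calibration(od_max)]`.
#' @param params A `trfd_calibration`.
#' @param od_max Upper end of the monotone OD search interval; defaults to
#'   1.5x the fitted OD range.
#' @return Net OD, same shape as `dose`.
#' @export
invert_calibration <- function(dose, params, od_max = NULL) {
  if (is.null(od_max)) od_max <- 1.5 * max(params$od_range[2], 0.1)
  dmax <- apply_calibration(od_max, params)
  if (min(dose) < params$a - 1e-12 || max(dose) > dmax + 1e-12) {
    stop_trfd(sprintf("dose outside calibrated range [%.4g, %.4g] Gy",
                      params$a, dmax), "trfd_range_error")
  }
  lo <- rep(0, length(dose)); hi <- rep(od_max, length(dose))
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    up <- apply_calibration(mid, params) < dose
    lo[up] <- mid[up]
    hi[!up] <- mid[!up]
  }
  out <- (lo + hi) / 2
  out[dose <= params$a] <- 0
  if (!is.null(dim(dose))) dim(out) <- dim(dose)
  out
}

# fast monotone lookup inverse, used by the synthetic-footage forward model
# where downstream 8-bit quantization dwarfs the interpolation error
invert_calibration_lookup <- function(params, od_max, n = 20000L) {
  od_grid <- seq(0, od_max, length.out = n)
  dose_grid <- apply_calibration(od_grid, params)
  function(dose) {
    out <- approx(dose_grid, od_grid, xout = pmax(dose, dose_grid[1]),
                  rule = 2)$y
    if (!is.null(dim(dose))) dim(out) <- dim(dose)
    out
  }
}

#' Flatbed-scanner 2-D calibration (OD and lateral position)
#'
#' Conventional (integrated) film dosimetry on a flatbed scanner needs a 2-D
#' correction: dose depends on net OD (3rd-order polynomial) and on the
#' lateral scan position (2nd-order), because the scanner's light path varies
#' across the bed. The model is
#' `D = sum_{i=0..3} sum_{j=0..2} C[i+1, j+1] OD^i L^j`,
#' fitted by linear least squares.
#'
#' @param samples Data frame with columns `od_net`, `lateral_mm`, `dose`;
#'   must cover at least 3 lateral positions and 4 OD levels.
#' @return A `trfd_scanner_calibration` with the 4 x 3 coefficient matrix.
#' @export
fit_scanner_calibration <- function(samples) {
  samples <- as_tibble(samples)
  od <- samples$od_net; lat <- samples$lateral_mm; dose <- samples$dose
  if (length(unique(lat)) < 3) {
    stop_trfd("need samples at >= 3 lateral positions", "trfd_fit_error")
  }
  if (length(unique(od)) < 4) {
    stop_trfd("need samples at >= 4 OD levels", "trfd_fit_error")
  }
  X <- scanner_basis(od, lat)
  cf <- lm.fit(X, dose)$coefficients
  cf[is.na(cf)] <- 0
  structure(list(coeffs = matrix(cf, 4, 3),
                 od_range = range(od), lateral_range = range(lat)),
            class = "trfd_scanner_calibration")
}

scanner_basis <- function(od, lat) {
  cols <- lapply(0:2, function(j) sapply(0:3, function(i) od^i * lat^j))
  do.call(cbind, cols)
}

#' @rdname fit_scanner_calibration
#' @param od_net,lateral_mm Points at which to evaluate (recycled together).
#' @param cal A `trfd_scanner_calibration`.
#' @export
apply_scanner_calibration <- function(od_net, lateral_mm, cal) {
  shape <- dim(od_net)
  out <- as.vector(scanner_basis(as.vector(od_net),
                                 as.vector(lateral_mm)) %*% as.vector(cal$coeffs))
  if (!is.null(shape)) dim(out) <- shape
  out
}
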