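#' Parameters for delta-t extraction
#'
#' The per-position delivery time window Δt follows the PBS dose-rate
#' construction: the accumulation curve of each pixel is normalized to 100%
#' using the mean of its final tail window (the last second of recording,
#' where coloration has stabilized), then the first upward crossings of the
#' lower and upper thresholds give t1 and t2 by linear interpolation, and
#' `Δt = t2 - t1`.
#'
#' @param lower_frac,upper_frac Threshold fractions of the plateau; the
#'   defaults 0.10/0.90 correspond to the dose threshold d = 10%.
#' @param tail_window_s Tail averaging window in s (1 s = 240 frames at
#'   240 fps).
#' @param d_threshold Dose threshold d for the PBS dose rate: a fraction of
#'   the maximum dose (default 0.10) or an absolute value in Gy (see
#'   [pbs_dose_rate()]).
#' @return A `trfd_delta_t_params` list.
#' @export
delta_t_params <- function(lower_frac = 0.10, upper_frac = 0.90,
                           tail_window_s = 1.0, d_threshold = 0.10) {
  if (!(0 < lower_frac && lower_frac < upper_frac && upper_frac < 1)) {
    stop_trfd("need 0 < lower_frac < upper_frac < 1")
  }
  if (tail_window_s <= 0) stop_trfd("`tail_window_s` must be positive")
  structure(list(lower_frac = lower_frac, upper_frac = upper_frac,
                 tail_window_s = tail_window_s, d_threshold = d_threshold),
            class = "trfd_delta_t_params")
}

#' Normalize an accumulation curve to its stabilized plateau
#'
#' Scales the curve so that the mean over the final `tail_window_s` equals
#' 100 (percent of the final, maximum dose of that pixel).
#'
#' @param curve Numeric vector (or time-by-pixel matrix) of accumulated dose.
#' @param fps Sampling rate of the curve in 1/s.
#' @param tail_window_s Tail window in s; the curve must be longer than this.
#' @return For a vector: the normalized curve, or `NULL` if the tail mean is
#'   not positive (pixel never irradiated). For a matrix: a list with
#'   `values` (normalized columns; columns with non-positive tail are NA) and
#'   `ok` (logical per column).
#' @export
normalize_accumulation <- function(curve, fps, tail_window_s = 1.0) {
  vec <- is.null(dim(curve))
  v <- if (vec) matrix(curve, ncol = 1) else curve
  n <- nrow(v)
  nt <- round(tail_window_s * fps)
  if (n <= nt) stop_trfd("curve not longer than the tail window",
                         "trfd_shape_error")
  tail_mean <- colMeans(v[(n - nt + 1):n, , drop = FALSE])
  ok <- is.finite(tail_mean) & tail_mean > 0
  scl <- ifelse(ok, 100 / tail_mean, NA_real_)
  out <- sweep(v, 2, scl, `*`)
  if (vec) {
    if (!ok[1]) return(NULL)
    return(drop(out))
  }
  list(values = out, ok = ok)
}

#' Threshold-crossing times of a normalized accumulation curve
#'
#' A running-maximum envelope is applied first (dose accumulation is
#' physically monotone; the envelope makes noisy crossings unique), then the
#' first upward crossing of each threshold is located by linear interpolation
#' between the bracketing samples. Sample `i` is at time `(i - 1) / fps`.
#'
#' @param curve Normalized curve (plateau = 100), vector or time-by-pixel
#'   matrix.
#' @param fps Sampling rate in 1/s.
#' @param lower_frac,upper_frac Thresholds as fractions of the plateau.
#' @return For a vector: `c(t1, t2)` in s. For a matrix: a 2-row matrix.
#'   `NA` where a threshold is never reached.
#' @export
threshold_crossings <- function(curve, fps, lower_frac = 0.1,
                                upper_frac = 0.9) {
  vec <- is.null(dim(curve))
  v <- if (vec) matrix(curve, ncol = 1) else curve
  env <- if (nrow(v) > 1) apply(v, 2, cummax) else v
  out <- rbind(cross_time(env, fps, 100 * lower_frac),
               cross_time(env, fps, 100 * upper_frac))
  rownames(out) <- c("t1", "t2")
  if (vec) c(t1 = unname(out[1, 1]), t2 = unname(out[2, 1])) else out
}

# first upward crossing of `thr` per column of monotone matrix `env`
cross_time <- function(env, fps, thr) {
  n <- nrow(env)
  # index of first sample >= thr (0 if none): count below then +1
  below <- colSums(env < thr)
  first <- below + 1L
  hit <- !is.na(first) & first <= n
  t <- rep(NA_real_, ncol(env))
  if (!any(hit)) return(t)
  f <- first[hit]
  cols <- which(hit)
  y1 <- env[cbind(f, cols)]
  at_start <- f == 1L
  t0 <- numeric(length(f))
  # crossing inside segment (f-1, f): interpolate; at f == 1 the curve
  # already starts above thr
  seg <- !at_start
  if (any(seg)) {
    y0 <- env[cbind(f[seg] - 1L, cols[seg])]
    frac <- (thr - y0) / (y1[seg] - y0)
    frac[!is.finite(frac)] <- 1
    t0[seg] <- (f[seg] - 2L + frac) / fps
  }
  t0[at_start] <- 0
  t[hit] <- t0
  t
}

#' Per-pixel delta-t map from a dose-accumulation stack
#'
#' Applies tail normalization and threshold-crossing extraction to every
#' pixel of a dose-accumulation-over-time stack. Pixels whose plateau is not
#' positive (never irradiated) are masked out, not errors.
#'
#' @param acc 3-D numeric array `[ny, nx, n_samples]` of per-pixel dose
#'   accumulation, or a time-by-pixel matrix plus explicit `ny`, `nx`.
#' @param fps Sampling rate in 1/s.
#' @param params A [delta_t_params()].
#' @param pixel_pitch_mm,origin_mm Map geometry (see [scalar_map()]).
#' @return A `trfd_delta_t_map`: scalar maps `delta_t`, `t1`, `t2` (s) with a
#'   shared validity mask.
#' @export
delta_t_map <- function(acc, fps, params = delta_t_params(),
                        pixel_pitch_mm = 1, origin_mm = NULL) {
  if (length(dim(acc)) == 3L) {
    ny <- dim(acc)[1]; nx <- dim(acc)[2]; nt <- dim(acc)[3]
    m <- matrix(aperm(acc, c(3, 1, 2)), nrow = nt)
  } else {
    stop_trfd("`acc` must be a 3-D array [ny, nx, n_samples]")
  }
  if (nt <= round(params$tail_window_s * fps)) {
    stop_trfd("stack shorter than the tail window", "trfd_shape_error")
  }
  res <- delta_t_from_matrix(m, fps, params)
  shape <- function(v) matrix(v, ny, nx)
  mk <- shape(res$ok)
  dt_new(delta_t = shape(res$dt), t1 = shape(res$t1), t2 = shape(res$t2),
         mask = mk, pixel_pitch_mm = pixel_pitch_mm, origin_mm = origin_mm)
}

# shared worker: columns are pixels
delta_t_from_matrix <- function(m, fps, params) {
  norm <- normalize_accumulation(m, fps, params$tail_window_s)
  cr <- threshold_crossings(norm$values, fps, params$lower_frac,
                            params$upper_frac)
  ok <- norm$ok & is.finite(cr[1, ]) & is.finite(cr[2, ])
  dt <- cr[2, ] - cr[1, ]
  dt[!ok] <- NA_real_
  list(dt = dt, t1 = cr[1, ], t2 = cr[2, ], ok = ok)
}

dt_new <- function(delta_t, t1, t2, mask, pixel_pitch_mm, origin_mm) {
  if (is.null(origin_mm)) {
    origin_mm <- c(-ncol(delta_t) * pixel_pitch_mm / 2,
                   -nrow(delta_t) * pixel_pitch_mm / 2)
  }
  structure(list(
    delta_t = scalar_map(delta_t, pixel_pitch_mm, origin_mm, mask),
    t1 = scalar_map(t1, pixel_pitch_mm, origin_mm, mask),
    t2 = scalar_map(t2, pixel_pitch_mm, origin_mm, mask),
    mask = mask, pixel_pitch_mm = pixel_pitch_mm, origin_mm = origin_mm),
    class = "trfd_delta_t_map")
}

#' @export
print.trfd_delta_t_map <- function(x, ...) {
  v <- x$delta_t$values[x$mask]
  cat(sprintf(
    "<trfd_delta_t_map> %d x %d px @ %g mm, %d valid px, delta-t [%.4g, %.4g] s\n",
    nrow(x$mask), ncol(x$mask), x$pixel_pitch_mm, sum(x$mask),
    if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
autoplot.trfd_delta_t_map <- function(object, ...) {
  autoplot(object$delta_t, name = "delta-t [s]")
}

#' PBS dose rate map (Folkerts definition)
#'
#' The PBS dose rate at a position is `ΔD / Δt`. With a fractional threshold
#' `d` the delta dose is `ΔD = (1 - 2 d) * D_max`; with an absolute threshold
#' in Gy it is `ΔD = D_max - 2 d`. Without a dose map the rate is returned in
#' %/s of the local maximum (`ΔD = 100 (1 - 2 d)`).
#'
#' @param dtm A [delta_t_map()].
#' @param dose Optional co-registered dose [scalar_map()] (Gy) giving D_max
#'   per pixel.
#' @param d Threshold: fraction of D_max (`absolute = FALSE`) or Gy.
#' @param absolute Interpret `d` as Gy rather than a fraction.
#' @return A [scalar_map()] in Gy/s (or %/s in relative mode); pixels with
#'   `Δt = 0` are masked out.
#' @export
pbs_dose_rate <- function(dtm, dose = NULL, d = 0.10, absolute = FALSE) {
  dt <- dtm$delta_t$values
  mask <- dtm$mask & is.finite(dt) & dt > 0
  if (is.null(dose)) {
    if (absolute) stop_trfd("absolute threshold needs a dose map")
    dd <- matrix(100 * (1 - 2 * d), nrow(dt), ncol(dt))
  } else {
    if (!identical(dim(dose$values), dim(dt))) {
      stop_trfd("dose map and delta-t map shapes differ", "trfd_shape_error")
    }
    dmax <- dose$values
    if (absolute) {
      if (any(mask & (dmax <= 2 * d))) {
        stop_trfd("absolute threshold d >= D_max / 2 at evaluated pixels",
                  "trfd_range_error")
      }
      dd <- dmax - 2 * d
    } else {
      dd <- (1 - 2 * d) * dmax
    }
    mask <- mask & dose$mask
  }
  rate <- ifelse(mask, dd / dt, NA_real_)
  scalar_map(rate, dtm$pixel_pitch_mm, dtm$origin_mm, mask)
}

#' In-field mask (isodose line)
#'
#' The treatment field is the region at or above a fraction of the maximum
#' dose; the conventional in-field region is the 50% isodose line.
#'
#' @param dose A dose [scalar_map()] with a positive maximum.
#' @param frac Isodose fraction.
#' @return Logical matrix.
#' @export
infield_mask <- function(dose, frac = 0.5) {
  v <- dose$values[dose$mask]
  if (!length(v) || max(v) <= 0) {
    stop_trfd("dose map has no positive values", "trfd_range_error")
  }
  dose$mask & !is.na(dose$values) & dose$values >= frac * max(v)
}

#' Delta-t distribution statistics
#'
#' Mean and 5th/50th/95th percentiles of the masked-in delta-t values;
#' percentiles use linear interpolation between order statistics.
#'
#' @param dtm A [delta_t_map()].
#' @param mask Optional logical matrix restricting the evaluation (e.g. the
#'   in-field mask); combined with the map's own validity mask.
#' @return A one-row tibble with `mean`, `p5`, `p50`, `p95` (s) and `n`.
#' @export
delta_t_statistics <- function(dtm, mask = NULL) {
  m <- dtm$mask
  if (!is.null(mask)) m <- m & mask
  v <- dtm$delta_t$values[m]
  if (!length(v)) stop_trfd("empty mask: no delta-t values to summarize",
                            "trfd_range_error")
  q <- quantile(v, c(0.05, 0.5, 0.95), type = 7, names = FALSE)
  tibble(mean = mean(v), p5 = q[1], p50 = q[2], p95 = q[3], n = length(v))
}
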