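#' Machine model for PBS delivery simulation
#'
#' Commissioning constants of the delivery system as used by the simulator:
#' the dose-per-MU line versus nozzle current (the monitor chamber saturates
#' above ~20 nA, making dose/MU current-dependent), the constant time-per-MU,
#' and the Gaussian spot sigma in the measurement plane. The defaults
#' describe the package's reference synthetic machine: the dose/MU line runs
#' through (25 nA, 0.04 Gy/MU) and (215 nA, 0.06 Gy/MU), time/MU is
#' 1e-3 s/MU, and sigma is 3.8 mm.
#'
#' @param dose_per_mu_intercept Gy/MU at zero current.
#' @param dose_per_mu_slope Gy/MU per nA.
#' @param time_per_mu Delivery time per MU in s (> 0), constant above the
#'   saturation current.
#' @param spot_sigma_mm Gaussian spot sigma in mm.
#' @param min_spot_duration_s Minimum deliverable spot duration; shorter
#'   spots trigger a warning.
#' @param transition_time_s Dead time between consecutive spots (default 0;
#'   dead time is normally absorbed by the global time scaling to the
#'   measured beam time).
#' @param saturation_current_nA Informational: current above which the
#'   monitor chamber saturates.
#' @return A `trfd_machine_model`.
#' @export
machine_model <- function(dose_per_mu_intercept = 0.04 - 25 * 2 / 190 * 1e-2,
                          dose_per_mu_slope = (0.06 - 0.04) / (215 - 25),
                          time_per_mu = 1e-3,
                          spot_sigma_mm = 3.8,
                          min_spot_duration_s = 0.003,
                          transition_time_s = 0,
                          saturation_current_nA = 20) {
  if (time_per_mu <= 0) stop_trfd("`time_per_mu` must be positive")
  if (spot_sigma_mm <= 0) stop_trfd("`spot_sigma_mm` must be positive")
  if (transition_time_s < 0) stop_trfd("`transition_time_s` must be >= 0")
  structure(list(dose_per_mu_intercept = dose_per_mu_intercept,
                 dose_per_mu_slope = dose_per_mu_slope,
                 time_per_mu = time_per_mu, spot_sigma_mm = spot_sigma_mm,
                 min_spot_duration_s = min_spot_duration_s,
                 transition_time_s = transition_time_s,
                 saturation_current_nA = saturation_current_nA),
            class = "trfd_machine_model")
}

#' @rdname machine_model
#' @param machine A `trfd_machine_model`.
#' @param nozzle_current_nA Nozzle current in nA.
#' @return [dose_per_mu()] returns the single-spot peak dose per MU (Gy/MU)
#'   at the given current.
#' @export
dose_per_mu <- function(machine, nozzle_current_nA) {
  machine$dose_per_mu_intercept + machine$dose_per_mu_slope * nozzle_current_nA
}

#' Simulation grids
#'
#' @param extent_mm Length-1 or -2 physical extent (x, y) in mm.
#' @param pixel_pitch_mm Grid spacing; 0.1 mm is the simulation default.
#' @param center_mm Physical (x, y) of the grid center.
#' @return A grid spec: `nx`, `ny`, `pixel_pitch_mm`, `origin_mm`.
#' @export
sim_grid <- function(extent_mm, pixel_pitch_mm = 0.1, center_mm = c(0, 0)) {
  if (pixel_pitch_mm <= 0) stop_trfd("`pixel_pitch_mm` must be positive")
  extent_mm <- rep(extent_mm, length.out = 2)
  nx <- max(1L, round(extent_mm[1] / pixel_pitch_mm))
  ny <- max(1L, round(extent_mm[2] / pixel_pitch_mm))
  list(nx = nx, ny = ny, pixel_pitch_mm = pixel_pitch_mm,
       origin_mm = c(center_mm[1] - nx * pixel_pitch_mm / 2,
                     center_mm[2] - ny * pixel_pitch_mm / 2))
}

grid_xy <- function(grid) {
  list(x = grid$origin_mm[1] + (seq_len(grid$nx) - 0.5) * grid$pixel_pitch_mm,
       y = grid$origin_mm[2] + (seq_len(grid$ny) - 0.5) * grid$pixel_pitch_mm)
}

#' Simulate 2-D dose accumulation over time from a spot list
#'
#' Spots are delivered sequentially in list order. Spot i lasts
#' `mu_i * time_per_mu` seconds at a constant dose rate, separated by
#' `transition_time_s` gaps; its spatial profile is a Gaussian
#' `peak * exp(-r^2 / (2 sigma^2))` with
#' `peak = mu_i * dose_per_mu(machine, current)`. The per-pixel accumulation
#' is represented analytically as piecewise-linear events and sampled on
#' demand, so the 0.1 mm / 10 kHz default resolution costs nothing until a
#' curve is materialized.
#'
#' @param spots A [spot_list()].
#' @param machine A [machine_model()].
#' @param nozzle_current_nA Nozzle current in nA (> 0).
#' @param grid A [sim_grid()]; must contain every spot center. Defaults to
#'   the pattern bounding box plus a 4-sigma margin at 0.1 mm.
#' @param sample_rate_hz Default sampling rate for materialized curves.
#' @return A `trfd_sim` with an `events` tibble
#'   (`t_start_s`, `t_end_s`, `x_mm`, `y_mm`, `peak_dose_gy`).
#' @export
simulate_delivery <- function(spots, machine, nozzle_current_nA,
                              grid = NULL, sample_rate_hz = 10000) {
  spots <- validate_spot_list(as_tibble(spots))
  if (nozzle_current_nA <= 0) stop_trfd("`nozzle_current_nA` must be positive")
  if (sample_rate_hz <= 0) stop_trfd("`sample_rate_hz` must be positive")
  sig <- machine$spot_sigma_mm
  if (is.null(grid)) {
    ext <- c(diff(range(spots$x_mm)), diff(range(spots$y_mm))) + 8 * sig
    grid <- sim_grid(ext, 0.1,
                     c(mean(range(spots$x_mm)), mean(range(spots$y_mm))))
  }
  xy <- grid_xy(grid)
  if (min(spots$x_mm) < min(xy$x) - grid$pixel_pitch_mm / 2 ||
      max(spots$x_mm) > max(xy$x) + grid$pixel_pitch_mm / 2 ||
      min(spots$y_mm) < min(xy$y) - grid$pixel_pitch_mm / 2 ||
      max(spots$y_mm) > max(xy$y) + grid$pixel_pitch_mm / 2) {
    stop_trfd("grid too small: spot center outside extent", "trfd_shape_error")
  }
  dpm <- dose_per_mu(machine, nozzle_current_nA)
  dur <- spots$mu * machine$time_per_mu
  if (any(dur < machine$min_spot_duration_s)) {
    warn(sprintf("%d spot(s) shorter than the minimum spot duration (%g s)",
                 sum(dur < machine$min_spot_duration_s),
                 machine$min_spot_duration_s))
  }
  gaps <- machine$transition_time_s
  t_start <- cumsum(c(0, head(dur, -1) + gaps))
  events <- tibble(t_start_s = t_start, t_end_s = t_start + dur,
                   x_mm = spots$x_mm, y_mm = spots$y_mm,
                   peak_dose_gy = spots$mu * dpm)
  structure(list(events = events, grid = grid,
                 sample_rate_hz = sample_rate_hz,
                 spot_sigma_mm = sig, machine = machine,
                 nozzle_current_nA = nozzle_current_nA),
            class = "trfd_sim")
}

#' @export
print.trfd_sim <- function(x, ...) {
  cat(sprintf(
    "<trfd_sim> %d spots, beam time %.4g s, grid %d x %d @ %g mm, sigma %g mm\n",
    nrow(x$events), total_beam_time(x), x$grid$ny, x$grid$nx,
    x$grid$pixel_pitch_mm, x$spot_sigma_mm))
  invisible(x)
}

#' @rdname simulate_delivery
#' @param sim A `trfd_sim`.
#' @return [total_beam_time()] returns the simulated delivery time in s
#'   (last event end).
#' @export
total_beam_time <- function(sim) max(sim$events$t_end_s)

# spot weight matrix: rows = pixels of `grid` (column-major), cols = spots
spot_weights <- function(events, grid, sigma) {
  xy <- grid_xy(grid)
  wx <- outer(xy$x, events$x_mm, function(x, xs) (x - xs)^2)
  wy <- outer(xy$y, events$y_mm, function(y, ys) (y - ys)^2)
  # pixel index = iy + ny*(ix-1), matching as.vector of [ny, nx] matrices
  w <- matrix(0, grid$ny * grid$nx, nrow(events))
  for (s in seq_len(nrow(events))) {
    w[, s] <- as.vector(exp(-(outer(wy[, s], wx[, s], `+`)) / (2 * sigma^2)))
  }
  w
}

#' Final (time-integrated) dose map of a simulated delivery
#'
#' @param sim A `trfd_sim`.
#' @param grid Optional alternative evaluation grid (the analytic events can
#'   be evaluated anywhere, e.g. on the camera grid).
#' @return A dose [scalar_map()] in Gy.
#' @export
final_dose_map <- function(sim, grid = NULL) {
  grid <- grid %||% sim$grid
  w <- spot_weights(sim$events, grid, sim$spot_sigma_mm)
  dose <- matrix(w %*% sim$events$peak_dose_gy, grid$ny, grid$nx)
  scalar_map(dose, grid$pixel_pitch_mm, grid$origin_mm)
}

#' Materialize per-pixel accumulation curves
#'
#' Samples the piecewise-linear accumulation at the given times for every
#' pixel of the grid. Intended for small grids and oracle checks; the
#' analytic path ([sim_delta_t()]) never needs full materialization.
#'
#' @param sim A `trfd_sim`.
#' @param times Sample times in s.
#' @param grid Optional evaluation grid.
#' @return Matrix `[length(times), n_pixels]`, pixels in column-major map
#'   order.
#' @export
sample_accumulation <- function(sim, times, grid = NULL) {
  grid <- grid %||% sim$grid
  ev <- sim$events
  w <- spot_weights(ev, grid, sim$spot_sigma_mm)
  out <- matrix(0, length(times), nrow(w))
  for (s in seq_len(nrow(ev))) {
    frac <- pmin(pmax((times - ev$t_start_s[s]) /
                        (ev$t_end_s[s] - ev$t_start_s[s]), 0), 1)
    out <- out + outer(frac, w[, s] * ev$peak_dose_gy[s])
  }
  out
}

#' Linearly rescale a simulation to a measured beam time
#'
#' All event times are multiplied by `measured_total_time_s` divided by the
#' simulated total; doses are unchanged. This maps the constant-time-per-MU
#' simulation onto the beam time actually observed by the beam monitor.
#'
#' @param sim A `trfd_sim`.
#' @param measured_total_time_s Measured delivery time in s (> 0).
#' @return The rescaled `trfd_sim`.
#' @export
scale_time <- function(sim, measured_total_time_s) {
  if (measured_total_time_s <= 0) {
    stop_trfd("`measured_total_time_s` must be positive", "trfd_range_error")
  }
  f <- measured_total_time_s / total_beam_time(sim)
  sim$events$t_start_s <- sim$events$t_start_s * f
  sim$events$t_end_s <- sim$events$t_end_s * f
  sim
}

#' Simulated delta-t map
#'
#' Per-pixel accumulation curves are piecewise linear in time, so the tail
#' normalization and threshold crossings of the measurement pipeline have an
#' exact closed-form solution: the plateau equals the final dose, and each
#' crossing is solved within the linear segment that brackets it.
#'
#' @param sim A `trfd_sim`.
#' @param params A [delta_t_params()].
#' @param grid Optional evaluation grid (defaults to the simulation grid).
#' @return A [delta_t_map()]-style `trfd_delta_t_map`.
#' @export
sim_delta_t <- function(sim, params = delta_t_params(), grid = NULL) {
  grid <- grid %||% sim$grid
  ev <- sim$events
  w <- spot_weights(ev, grid, sim$spot_sigma_mm)
  peaks <- ev$peak_dose_gy
  # breakpoints: all event starts/ends, deduplicated, sorted
  bp <- sort(unique(c(ev$t_start_s, ev$t_end_s)))
  npx <- nrow(w)
  acc <- matrix(0, length(bp), npx)
  for (s in seq_len(nrow(ev))) {
    frac <- pmin(pmax((bp - ev$t_start_s[s]) /
                        (ev$t_end_s[s] - ev$t_start_s[s]), 0), 1)
    acc <- acc + outer(frac, w[, s] * peaks[s])
  }
  total <- acc[length(bp), ]
  ok <- total > 0
  t_of <- function(frac_of_total) {
    thr <- frac_of_total * total
    t <- rep(NA_real_, npx)
    for (k in seq_len(length(bp) - 1)) {
      lo <- acc[k, ]; hi <- acc[k + 1, ]
      sel <- is.na(t) & ok & (hi >= thr) & (lo < thr)
      if (any(sel)) {
        f <- (thr[sel] - lo[sel]) / (hi[sel] - lo[sel])
        t[sel] <- bp[k] + f * (bp[k + 1] - bp[k])
      }
    }
    t[is.na(t) & ok & acc[1, ] >= thr] <- bp[1]
    t
  }
  t1 <- t_of(params$lower_frac)
  t2 <- t_of(params$upper_frac)
  ok <- ok & !is.na(t1) & !is.na(t2)
  dt <- t2 - t1
  dt[!ok] <- NA_real_
  shape <- function(v) matrix(v, grid$ny, grid$nx)
  dt_new(shape(dt), shape(t1), shape(t2), shape(ok),
         grid$pixel_pitch_mm, grid$origin_mm)
}

#' Fit a 2-D Gaussian to a single-spot dose map
#'
#' Least-squares fit of amplitude, center, per-axis sigmas and a flat
#' background; returns the mean of sigma_x and sigma_y as the spot sigma,
#' the commissioning input of the simulator.
#'
#' @param dose A dose [scalar_map()] containing one dominant spot.
#' @param min_r2 Fit-quality threshold; a flat or multi-modal map fails it.
#' @return A `trfd_spot_fit`: `sigma_mm`, `sigma_x_mm`, `sigma_y_mm`,
#'   `center_mm`, `amplitude`, `background`, `r_squared`.
#' @export
fit_spot_sigma <- function(dose, min_r2 = 0.9) {
  v <- dose$values; msk <- dose$mask & is.finite(v)
  if (!any(msk) || max(v[msk]) <= min(v[msk])) {
    stop_trfd("dose map is flat or empty", "trfd_fit_error")
  }
  xs <- map_x(dose); ys <- map_y(dose)
  df <- data.frame(
    x = rep(xs, each = nrow(v))[as.vector(msk)],
    y = rep(ys, times = ncol(v))[as.vector(msk)],
    z = v[msk])
  i0 <- which.max(df$z)
  wz <- pmax(df$z - min(df$z), 0)
  sx0 <- sqrt(sum(wz * (df$x - df$x[i0])^2) / sum(wz))
  start <- list(A = max(df$z) - min(df$z), x0 = df$x[i0], y0 = df$y[i0],
                sx = max(sx0, dose$pixel_pitch_mm),
                sy = max(sx0, dose$pixel_pitch_mm), bg = min(df$z))
  fit <- minpack.lm::nlsLM(
    z ~ A * exp(-((x - x0)^2 / (2 * sx^2) + (y - y0)^2 / (2 * sy^2))) + bg,
    data = df, start = start,
    lower = c(0, -Inf, -Inf, 1e-3, 1e-3, -Inf),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  r2 <- 1 - sum(residuals(fit)^2) / sum((df$z - mean(df$z))^2)
  if (!is.finite(r2) || r2 < min_r2) {
    stop_trfd(sprintf(
      "Gaussian fit quality too low (R^2 = %.3f): flat or multi-modal map", r2),
      "trfd_fit_error")
  }
  structure(list(sigma_mm = mean(c(cf[["sx"]], cf[["sy"]])),
                 sigma_x_mm = cf[["sx"]], sigma_y_mm = cf[["sy"]],
                 center_mm = c(cf[["x0"]], cf[["y0"]]),
                 amplitude = cf[["A"]], background = cf[["bg"]],
                 r_squared = r2),
            class = "trfd_spot_fit")
}

#' @export
print.trfd_spot_fit <- function(x, ...) {
  cat(sprintf(
    "<trfd_spot_fit> sigma %.4g mm (x %.4g, y %.4g), center (%.3g, %.3g) mm, R2 %.4f\n",
    x$sigma_mm, x$sigma_x_mm, x$sigma_y_mm, x$center_mm[1], x$center_mm[2],
    x$r_squared))
  invisible(x)
}

#' @export
tidy.trfd_spot_fit <- function(x, ...) {
  tibble(term = c("sigma", "sigma_x", "sigma_y", "x0", "y0", "amplitude",
                  "background"),
         estimate = c(x$sigma_mm, x$sigma_x_mm, x$sigma_y_mm, x$center_mm,
                      x$amplitude, x$background))
}

#' Field-to-spot central-axis dose ratio
#'
#' Ratio between the superposed central-axis dose of a uniform-MU pattern and
#' the peak dose of a single spot: the analytic Gaussian sum
#' `sum_i exp(-d_i^2 / (2 sigma^2))` over distances d_i from the pattern
#' centroid. Used to convert a measured field dose into a single-spot peak
#' dose during commissioning.
#'
#' @param pattern A uniform-MU [spot_list()].
#' @param sigma_mm Spot sigma in mm.
#' @return Dimensionless ratio (>= 1 for a pattern containing its centroid).
#' @export
field_to_spot_ratio <- function(pattern, sigma_mm) {
  pattern <- validate_spot_list(as_tibble(pattern))
  if (diff(range(pattern$mu)) > 1e-9 * max(pattern$mu)) {
    stop_trfd("pattern must have uniform MU weights", "trfd_range_error")
  }
  cx <- mean(range(pattern$x_mm)); cy <- mean(range(pattern$y_mm))
  d2 <- (pattern$x_mm - cx)^2 + (pattern$y_mm - cy)^2
  sum(exp(-d2 / (2 * sigma_mm^2)))
}

#' Commission the dose-per-MU line from field-dose measurements
#'
#' Each measurement gives the central-axis dose of a uniform pattern at one
#' nozzle current. The single-spot peak dose is `field_dose /`
#' [field_to_spot_ratio()], the dose per MU divides by the per-spot MU, and a
#' linear least-squares fit against current yields the machine line.
#'
#' @param measurements Data frame with columns `current_nA`, `field_dose_gy`,
#'   `mu_per_spot`; at least 2 distinct currents.
#' @param pattern The [spot_list()] pattern used for all measurements.
#' @param sigma_mm Spot sigma in mm.
#' @return List with `intercept` (Gy/MU), `slope` (Gy/MU/nA) and the per-point
#'   tibble.
#' @export
commission_dose_per_mu <- function(measurements, pattern, sigma_mm) {
  m <- as_tibble(measurements)
  if (length(unique(m$current_nA)) < 2) {
    stop_trfd("need measurements at >= 2 distinct currents", "trfd_fit_error")
  }
  ratio <- field_to_spot_ratio(pattern, sigma_mm)
  dpm <- m$field_dose_gy / ratio / m$mu_per_spot
  cf <- lm.fit(cbind(1, m$current_nA), dpm)$coefficients
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       points = tibble(current_nA = m$current_nA, dose_per_mu = dpm))
}

#' @rdname commission_dose_per_mu
#' @param total_mu Total MU per delivery.
#' @param beam_time_s Measured delivery times in s.
#' @return [commission_time_per_mu()] returns the mean time per MU (s/MU).
#' @export
commission_time_per_mu <- function(total_mu, beam_time_s) {
  mean(beam_time_s / total_mu)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
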