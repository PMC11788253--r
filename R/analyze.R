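#' Full TRFD analysis of a frame stack
#'
#' Runs the complete measurement chain per pixel: pixel value to optical
#' density, net OD against the first frame, OD to relative dose through the
#' calibration curve, deconvolution of the post-irradiation coloration
#' kernel, integration of the recovered pulse to a dose-accumulation curve,
#' tail normalization and threshold-crossing extraction of delta-t. Pixels
#' are processed in blocks so full-length recordings (60+ s at 240 fps)
#' stay within memory.
#'
#' @param stack A [frame_stack()].
#' @param cal A `trfd_calibration`.
#' @param rf A [response_function()].
#' @param params A [delta_t_params()].
#' @param smooth_window_s Moving-average window (s) applied to each pixel's
#'   dose-over-time trace before deconvolution; the default 25 ms (six frames
#'   at 240 fps) suppresses camera noise at a time scale well below typical
#'   delivery windows.
#' @param neg_tol Most negative tolerated net OD (camera noise floor).
#' @param chunk_px Pixels per processing block.
#' @return A `trfd_analysis`: `delta_t_map` (a `trfd_delta_t_map`),
#'   `dose` (final relative dose [scalar_map()], the stabilized response
#'   tail), `fps`, and the parameters used.
#' @export
trfd_analyze <- function(stack, cal, rf, params = delta_t_params(),
                         smooth_window_s = 0.025, neg_tol = 0.02,
                         chunk_px = 1024L) {
  d <- dim(stack$frames)
  ny <- d[1]; nx <- d[2]; nt <- d[3]
  fps <- stack$fps
  if (nt <= round(params$tail_window_s * fps)) {
    stop_trfd("recording shorter than the tail window", "trfd_shape_error")
  }
  k <- discretize_kernel(rf, fps, n_lags = nt)
  g <- reciprocal_series(k, nt)
  nt_tail <- round(params$tail_window_s * fps)
  w <- max(1L, round(smooth_window_s * fps))
  if (w %% 2 == 0) w <- w + 1L

  npx <- ny * nx
  dt_v <- t1_v <- t2_v <- rep(NA_real_, npx)
  ok_v <- rep(FALSE, npx)
  dose_v <- rep(NA_real_, npx)
  for (j0 in seq(1, npx, by = chunk_px)) {
    j1 <- min(j0 + chunk_px - 1L, npx)
    # time x pixels block, extracted without copying the whole stack
    idx <- outer((j0:j1) - 1, (seq_len(nt) - 1) * as.numeric(npx), `+`) + 1
    pv <- t(matrix(as.integer(stack$frames[idx]), nrow = j1 - j0 + 1L))
    od <- pv_to_od(pv)
    od <- sweep(od, 2, od[1, ])
    od <- pmax(pmin(od, Inf), -neg_tol)    # clip sub-noise negatives
    dose <- apply_calibration(od, cal, neg_tol = neg_tol)
    if (w > 1) dose <- apply_moving_average(dose, w)
    pulse <- causal_convolve(dose, g)
    acc <- apply(pulse, 2, cumsum)
    res <- delta_t_from_matrix(acc, fps, params)
    dt_v[j0:j1] <- res$dt; t1_v[j0:j1] <- res$t1; t2_v[j0:j1] <- res$t2
    ok_v[j0:j1] <- res$ok
    dose_v[j0:j1] <- colMeans(dose[(nt - nt_tail + 1):nt, , drop = FALSE])
  }
  shape <- function(v) matrix(v, ny, nx)
  dtm <- dt_new(shape(dt_v), shape(t1_v), shape(t2_v), shape(ok_v),
                stack$pixel_pitch_mm, stack$origin_mm)
  structure(list(
    delta_t_map = dtm,
    dose = scalar_map(shape(dose_v), stack$pixel_pitch_mm, stack$origin_mm),
    fps = fps, params = params, smooth_window_s = smooth_window_s),
    class = "trfd_analysis")
}

#' @export
print.trfd_analysis <- function(x, ...) {
  cat("<trfd_analysis>\n")
  print(x$delta_t_map)
  print(x$dose)
  invisible(x)
}

#' End-to-end pre-treatment verification
#'
#' The complete verification workflow for one plan: analyze the measured
#' footage, simulate the delivery from the spot list, optionally rescale the
#' simulation to the measured beam time, register measurement to simulation
#' on the dose maps, compare the delta-t distributions with a local gamma
#' evaluation over the in-field (50% isodose) region, and summarize the
#' delta-t statistics of both with their ratios.
#'
#' @param stack Measured [frame_stack()] (or a path readable by
#'   [read_frame_stack()]).
#' @param spots The delivered [spot_list()] (or a path).
#' @param machine A [machine_model()].
#' @param cal A `trfd_calibration`.
#' @param rf A [response_function()].
#' @param nozzle_current_nA Nozzle current of the delivery.
#' @param criteria A [gamma_criteria()].
#' @param params A [delta_t_params()].
#' @param measured_beam_time_s Optional beam time from the external monitor;
#'   when given, the simulation is linearly rescaled to it.
#' @param pass_threshold Verification passes when the gamma pass rate reaches
#'   this fraction.
#' @param infield_frac Isodose fraction defining the evaluated region.
#' @param ... Passed on to [trfd_analyze()].
#' @return A `trfd_report` with elements `gamma`, `stats` (tibble of delta-t
#'   statistics for measurement, simulation and their ratio), `shift_mm`,
#'   `pass`, and the inputs' parameters.
#' @export
trfd_verify <- function(stack, spots, machine, cal, rf, nozzle_current_nA,
                        criteria = gamma_criteria(),
                        params = delta_t_params(),
                        measured_beam_time_s = NULL,
                        pass_threshold = 0.90, infield_frac = 0.5, ...) {
  if (is.character(stack)) stack <- read_frame_stack(stack)
  if (is.character(spots)) spots <- read_spot_list(spots)
  ana <- trfd_analyze(stack, cal, rf, params = params, ...)
  sim <- simulate_delivery(spots, machine, nozzle_current_nA)
  if (!is.null(measured_beam_time_s)) {
    sim <- scale_time(sim, measured_beam_time_s)
  }
  # camera-matched evaluation grid for the simulated reference
  cam_grid <- list(nx = ncol(ana$dose$values), ny = nrow(ana$dose$values),
                   pixel_pitch_mm = ana$dose$pixel_pitch_mm,
                   origin_mm = ana$dose$origin_mm)
  sim_dose <- final_dose_map(sim, cam_grid)
  reg <- register_maps(ana$dose, sim_dose)
  dtm_meas <- shift_map(ana$delta_t_map, reg$dx_mm, reg$dy_mm)
  dose_meas <- shift_map(ana$dose, reg$dx_mm, reg$dy_mm)
  dtm_sim <- sim_delta_t(sim, params, cam_grid)
  mask <- infield_mask(sim_dose, infield_frac)
  gam <- local_gamma(dtm_meas, dtm_sim, criteria, mask = mask)
  gam$shift_applied_mm <- c(reg$dx_mm, reg$dy_mm)
  st_m <- delta_t_statistics(dtm_meas, mask)
  st_s <- delta_t_statistics(dtm_sim, mask)
  stats <- dplyr::bind_rows(
    dplyr::mutate(st_m, source = "measured"),
    dplyr::mutate(st_s, source = "simulated"),
    tibble(mean = st_m$mean / st_s$mean, p5 = st_m$p5 / st_s$p5,
           p50 = st_m$p50 / st_s$p50, p95 = st_m$p95 / st_s$p95,
           n = st_m$n, source = "ratio"))
  structure(list(
    gamma = gam, stats = stats[, c("source", "mean", "p5", "p50", "p95", "n")],
    shift_mm = c(reg$dx_mm, reg$dy_mm), registration_ncc = reg$ncc,
    pass = gam$pass_rate >= pass_threshold,
    pass_threshold = pass_threshold,
    criteria = criteria, params = params,
    measured = list(delta_t_map = dtm_meas, dose = dose_meas),
    simulated = list(delta_t_map = dtm_sim, dose = sim_dose)),
    class = "trfd_report")
}

#' @export
print.trfd_report <- function(x, ...) {
  cat(sprintf("<trfd_report> %s: gamma pass rate %.1f%% (threshold %.0f%%)\n",
              if (x$pass) "PASS" else "FAIL", 100 * x$gamma$pass_rate,
              100 * x$pass_threshold))
  cat(sprintf("  registration shift (%.2f, %.2f) mm, ncc %.3f\n",
              x$shift_mm[1], x$shift_mm[2], x$registration_ncc))
  print(x$stats)
  invisible(x)
}

#' @export
glance.trfd_report <- function(x, ...) {
  r <- x$stats[x$stats$source == "ratio", ]
  tibble(pass = x$pass, pass_rate = x$gamma$pass_rate,
         n_evaluated = x$gamma$n_evaluated,
         ratio_mean = r$mean, ratio_p5 = r$p5, ratio_p50 = r$p50,
         ratio_p95 = r$p95,
         shift_x_mm = x$shift_mm[1], shift_y_mm = x$shift_mm[2])
}

#' Serialize / reload a verification report
#'
#' The JSON report keeps the scalar summary (pass rate, statistics, shift,
#' criteria); maps are written separately with [write_scalar_map()].
#'
#' @param report A `trfd_report`.
#' @param path Output JSON path.
#' @export
write_report <- function(report, path) {
  out <- list(
    pass = report$pass, pass_threshold = report$pass_threshold,
    pass_rate = report$gamma$pass_rate,
    n_evaluated = report$gamma$n_evaluated,
    shift_mm = report$shift_mm, registration_ncc = report$registration_ncc,
    criteria = unclass(report$criteria), params = unclass(report$params),
    stats = report$stats)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
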