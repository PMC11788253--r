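#' Synthetic-footage configuration
#'
#' Acquisition parameters of the simulated camera/film instrument: an 8-bit
#' red-channel recording at 240 fps that starts before beam-on and continues
#' 60 s past beam start so the post-irradiation coloration stabilizes.
#'
#' @param pv_baseline Pixel value of unirradiated film under box
#'   illumination (0 < PV < 255).
#' @param noise_sigma_pv Additive Gaussian pixel noise in PV, applied before
#'   rounding; 1 PV is a conservative 8-bit sensor floor.
#' @param fps Frame rate, frames/s.
#' @param pre_roll_s Recording time before beam start, s.
#' @param post_roll_s Recording time after beam start, s; must cover the
#'   response-kernel support used in analysis.
#' @param pixel_pitch_mm Camera pixel pitch on the film plane; 0.14 mm
#'   corresponds to a 9 cm field of view over 640 pixels.
#' @param seed Integer seed making the noise bit-reproducible.
#' @return A `trfd_footage_config`.
#' @export
footage_config <- function(pv_baseline = 220, noise_sigma_pv = 1.0,
                           fps = 240, pre_roll_s = 1.0, post_roll_s = 60.0,
                           pixel_pitch_mm = 0.14, seed = NULL) {
  if (pv_baseline <= 0 || pv_baseline >= 255) {
    stop_trfd("`pv_baseline` must lie in (0, 255)")
  }
  if (fps <= 0) stop_trfd("`fps` must be positive")
  if (noise_sigma_pv < 0) stop_trfd("`noise_sigma_pv` must be >= 0")
  structure(list(pv_baseline = pv_baseline, noise_sigma_pv = noise_sigma_pv,
                 fps = fps, pre_roll_s = pre_roll_s, post_roll_s = post_roll_s,
                 pixel_pitch_mm = pixel_pitch_mm, seed = seed),
            class = "trfd_footage_config")
}

#' Forward model: synthesize camera footage from a simulated delivery
#'
#' Stands in for the film/camera instrument. Per camera pixel the delivered
#' pulse is binned into frame intervals, convolved with the coloration kernel
#' normalized to 1 at `post_roll_s` (so the stabilized response tail equals
#' the pixel's final dose), converted to net OD through the inverse
#' calibration curve, added to the unirradiated baseline OD, turned back into
#' a pixel value, and finally degraded by Gaussian noise, rounding and
#' clipping to the 8-bit range.
#'
#' @param sim A [simulate_delivery()] result.
#' @param cal A `trfd_calibration`; the delivered dose must stay inside its
#'   invertible range.
#' @param rf A [response_function()]; `post_roll_s` must be at least its
#'   `duration_s`.
#' @param cfg A [footage_config()].
#' @param grid Optional camera grid ([sim_grid()] at the camera pitch);
#'   defaults to the simulation extent resampled to the camera pitch.
#' @param chunk_px Pixels per processing block (memory/time trade-off).
#' @return A [frame_stack()] with `beam_start_index` set.
#' @export
synthesize_footage <- function(sim, cal, rf, cfg = footage_config(),
                               grid = NULL, chunk_px = 1024L) {
  if (cfg$post_roll_s < rf$duration_s) {
    stop_trfd("`post_roll_s` is shorter than the response-kernel support",
              "trfd_range_error")
  }
  if (is.null(grid)) {
    ext <- c(sim$grid$nx, sim$grid$ny) * sim$grid$pixel_pitch_mm
    ctr <- sim$grid$origin_mm + ext / 2
    grid <- sim_grid(ext, cfg$pixel_pitch_mm, ctr)
  }
  fps <- cfg$fps
  ev <- sim$events
  beam_end <- max(ev$t_end_s)
  n_pre <- round(cfg$pre_roll_s * fps)
  n_total <- n_pre + ceiling((beam_end + cfg$post_roll_s) * fps)
  # temporal weights: dose fraction of each event landing in each beam frame
  n_beam <- ceiling(beam_end * fps)
  f_lo <- (seq_len(n_beam) - 1) / fps
  f_hi <- seq_len(n_beam) / fps
  W <- matrix(0, n_beam, nrow(ev))
  for (s in seq_len(nrow(ev))) {
    ov <- pmin(f_hi, ev$t_end_s[s]) - pmax(f_lo, ev$t_start_s[s])
    W[, s] <- pmax(ov, 0) / (ev$t_end_s[s] - ev$t_start_s[s])
  }
  Wp <- W * rep(ev$peak_dose_gy, each = n_beam)

  khat <- discretize_kernel(rf, fps, n_lags = n_total)
  khat <- khat / eval_kernel(rf, cfg$post_roll_s)
  od0 <- pv_to_od(cfg$pv_baseline)
  od_max <- 1.5 * max(cal$od_range[2], 0.1)
  dose_max <- apply_calibration(od_max, cal)
  inv <- invert_calibration_lookup(cal, od_max)

  sgw <- spot_weights(ev, grid, sim$spot_sigma_mm)  # npx x nspots
  npx <- nrow(sgw)
  frames <- matrix(raw(1), npx, n_total)  # reshaped to [ny, nx, n] at the end

  have_seed <- !is.null(cfg$seed)
  if (have_seed) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
    }, add = TRUE)
    set.seed(cfg$seed)
  }

  for (j0 in seq(1, npx, by = chunk_px)) {
    j1 <- min(j0 + chunk_px - 1L, npx)
    pulse <- matrix(0, n_total, j1 - j0 + 1L)
    pulse[n_pre + seq_len(n_beam), ] <- Wp %*% t(sgw[j0:j1, , drop = FALSE])
    if (max(colSums(pulse)) > dose_max) {
      stop_trfd("delivered dose exceeds the calibration range",
                "trfd_range_error")
    }
    resp <- causal_convolve(pulse, khat)
    od <- od0 + inv(resp)
    pv <- 2^8 / 10^od - 1
    if (cfg$noise_sigma_pv > 0) {
      pv <- pv + rnorm(length(pv), sd = cfg$noise_sigma_pv)
    }
    pv <- round(pv)
    storage.mode(pv) <- "integer"
    frames[j0:j1, ] <- as.raw(t(pmin(pmax(pv, 0L), 255L)))
  }
  dim(frames) <- c(grid$ny, grid$nx, n_total)
  frame_stack(frames, fps = fps, pixel_pitch_mm = grid$pixel_pitch_mm,
              beam_start_index = n_pre + 1L, origin_mm = grid$origin_mm)
}

#' QA-grid scenario: uniform square spot pattern
#'
#' The standard verification field: a square pattern (default 3 x 3 cm at
#' 5 mm spacing, i.e. 7 x 7 spots) of equally MU-weighted spots in snake
#' order, with the per-spot MU chosen so the central-axis field dose equals
#' `total_dose_gy` under the machine model.
#'
#' @param field_mm Field side length in mm; `spacing_mm` must divide it.
#' @param spacing_mm Spot spacing in mm.
#' @param total_dose_gy Central-axis field dose in Gy (> 0).
#' @param current_nA Nozzle current in nA (> 0).
#' @param machine A [machine_model()].
#' @return A snake-ordered [spot_list()].
#' @export
scenario_qa_grid <- function(field_mm = 30, spacing_mm = 5, total_dose_gy = 15,
                             current_nA = 120, machine = machine_model()) {
  if (total_dose_gy <= 0 || current_nA <= 0) {
    stop_trfd("dose and current must be positive")
  }
  if (abs(field_mm / spacing_mm - round(field_mm / spacing_mm)) > 1e-9) {
    stop_trfd("`spacing_mm` must divide `field_mm`")
  }
  half <- field_mm / 2
  pos <- seq(-half, half, by = spacing_mm)
  g <- expand.grid(x_mm = pos, y_mm = pos)
  pattern <- spot_list(g$x_mm, g$y_mm, mu = rep(1, nrow(g)))
  ratio <- field_to_spot_ratio(pattern, machine$spot_sigma_mm)
  mu <- total_dose_gy / ratio / dose_per_mu(machine, current_nA)
  pattern$mu <- rep(mu, nrow(pattern))
  reorder_spot_list(pattern, "snake")
}

#' Revisit scenario: targets delivered in installments
#'
#' Three target positions on the y axis (+15, 0, -15 mm), each finally
#' receiving `dose_per_target_gy`, delivered in `n_steps` equal installments
#' by sweeping the targets in a snake pattern starting at +15 mm. The center
#' target therefore accumulates its dose in 1, 2 or 3 steps with pauses in
#' between — the scenario that verifies revisiting a spot leaves the
#' accumulation measurement unbiased.
#'
#' @param n_steps 1, 2 or 3 installments per target.
#' @param dose_per_target_gy Final peak dose per target in Gy.
#' @param current_nA Nozzle current in nA.
#' @param machine A [machine_model()].
#' @param target_spacing_mm Spacing between targets on the y axis.
#' @return A [spot_list()] of `3 * n_steps` spots in delivery order.
#' @export
scenario_revisit <- function(n_steps, dose_per_target_gy = 10,
                             current_nA = 120, machine = machine_model(),
                             target_spacing_mm = 15) {
  if (!n_steps %in% 1:3) stop_trfd("`n_steps` must be 1, 2 or 3")
  ys <- c(target_spacing_mm, 0, -target_spacing_mm)
  seq_y <- unlist(lapply(seq_len(n_steps), function(k) {
    if (k %% 2 == 1) ys else rev(ys)
  }))
  mu <- dose_per_target_gy / n_steps / dose_per_mu(machine, current_nA)
  spot_list(x_mm = rep(0, length(seq_y)), y_mm = seq_y,
            mu = rep(mu, length(seq_y)))
}
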