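test_that("single-spot simulation reproduces peak dose and beam time", {
  m <- machine_model(dose_per_mu_intercept = 0.05, dose_per_mu_slope = 0,
                     time_per_mu = 1e-3)
  sim <- simulate_delivery(spot_list(0, 0, 100), m, 120)
  expect_equal(total_beam_time(sim), 0.1)
  dose <- final_dose_map(sim)
  expect_equal(max(dose$values), 5.0, tolerance = 5e-4)  # grid-center offset

  # sequential timing with and without transition gaps
  sp3 <- spot_list(c(0, 5, 10), c(0, 0, 0), rep(50, 3))
  expect_equal(total_beam_time(simulate_delivery(sp3, m, 120)), 0.15)
  m2 <- machine_model(dose_per_mu_intercept = 0.05, dose_per_mu_slope = 0,
                      time_per_mu = 1e-3, transition_time_s = 2e-3)
  expect_equal(total_beam_time(simulate_delivery(sp3, m2, 120)), 0.154)

  expect_error(simulate_delivery(sp3, m, -5))
  expect_error(simulate_delivery(sp3, m, 120, grid = sim_grid(c(4, 4))),
               class = "trfd_shape_error")
  expect_warning(simulate_delivery(spot_list(0, 0, 1), m, 120),
                 "minimum spot duration")
})

test_that("dose is conserved within discretization error", {
  m <- machine_model(dose_per_mu_intercept = 0.05, dose_per_mu_slope = 0)
  sim <- simulate_delivery(spot_list(0, 0, 100), m, 120,
                           grid = sim_grid(c(60, 60), 0.1))
  dose <- final_dose_map(sim)
  integral <- sum(dose$values) * 0.1^2
  expect_equal(integral, 2 * pi * 3.8^2 * 5.0, tolerance = 1e-3)
})

test_that("field-to-spot ratio matches the brute-force Gaussian sum", {
  pat <- grid_pattern(7, 5)
  # independent brute force over all spot pairs
  brute <- sum(exp(-(pat$x_mm^2 + pat$y_mm^2) / (2 * 3.8^2)))
  expect_equal(field_to_spot_ratio(pat, 3.8), brute, tolerance = 1e-12)
  expect_equal(field_to_spot_ratio(pat, 3.8), 3.629323, tolerance = 1e-6)
  expect_equal(field_to_spot_ratio(spot_list(0, 0, 1), 3.8), 1.0)
  # strictly increasing in sigma for a multi-spot pattern
  sig <- c(2, 3, 3.8, 5, 8)
  expect_true(all(diff(vapply(sig, function(s) field_to_spot_ratio(pat, s),
                              numeric(1))) > 0))
})

test_that("time scaling stretches delta-t exactly and keeps dose", {
  m <- machine_model()
  sp <- grid_pattern(3, 5, mu = 60)
  sim <- simulate_delivery(sp, m, 120)
  dt1 <- sim_delta_t(sim)
  sim2 <- scale_time(sim, 2 * total_beam_time(sim))
  dt2 <- sim_delta_t(sim2)
  expect_equal(dt2$delta_t$values[dt2$mask], 2 * dt1$delta_t$values[dt1$mask],
               tolerance = 1e-12)
  expect_equal(final_dose_map(sim2)$values, final_dose_map(sim)$values)
  # identity scaling
  sim3 <- scale_time(sim, total_beam_time(sim))
  expect_equal(sim3$events, sim$events)
  expect_error(scale_time(sim, 0), class = "trfd_range_error")
})

test_that("simulated delta-t agrees with a brute-force curve sampler", {
  set.seed(13)
  m <- machine_model()
  p <- delta_t_params()
  for (rep in 1:10) {
    n <- sample(1:9, 1)
    sp <- spot_list(runif(n, -8, 8), runif(n, -8, 8), runif(n, 30, 120))
    sim <- simulate_delivery(sp, m, 120, grid = sim_grid(c(30, 30), 3))
    dtm <- sim_delta_t(sim)
    # oracle: sample curves densely, normalize to the final value, interpolate
    tt <- seq(0, total_beam_time(sim), length.out = 4000)
    acc <- sample_accumulation(sim, tt)
    for (px in sample(ncol(acc), 12)) {
      total <- acc[length(tt), px]
      if (total <= 0) next
      t1o <- approx(acc[, px] + (1:4000) * 1e-12, tt, xout = 0.1 * total)$y
      t2o <- approx(acc[, px] + (1:4000) * 1e-12, tt, xout = 0.9 * total)$y
      expect_equal(dtm$delta_t$values[px], t2o - t1o, tolerance = 5e-3)
    }
  }
})

test_that("midpoint pixel between consecutive spots spans both deliveries", {
  m <- machine_model(dose_per_mu_intercept = 0.05, dose_per_mu_slope = 0,
                     time_per_mu = 1e-3, transition_time_s = 5e-3)
  sp <- spot_list(c(-2, 2), c(0, 0), c(100, 100))
  # odd pixel count so that x = y = 0 is exactly a pixel center
  sim <- simulate_delivery(sp, m, 120, grid = sim_grid(c(20.5, 20.5), 0.5))
  dtm <- sim_delta_t(sim)
  ix <- 21L; iy <- 21L
  expect_equal(trfd:::grid_xy(sim$grid)$x[ix], 0)
  # symmetric midpoint: equal halves at [0, 0.1] and [0.105, 0.205]:
  # t1 = 20% point of first ramp, t2 = 80% point of second
  expect_equal(dtm$delta_t$values[iy, ix], 0.205 - 0.02 - 0.02,
               tolerance = 1e-9)
})

test_that("well-separated spots keep their single-spot delta-t", {
  m <- machine_model(dose_per_mu_intercept = 0.05, dose_per_mu_slope = 0,
                     time_per_mu = 1e-3)
  w <- 0.1
  sp <- spot_list(c(-40, 40), c(0, 0), c(100, 100))  # > 20 sigma apart
  sim <- simulate_delivery(sp, m, 120, grid = sim_grid(c(100, 20), 1))
  dtm <- sim_delta_t(sim)
  dose <- final_dose_map(sim)
  msk <- infield_mask(dose)
  expect_equal(unname(dtm$delta_t$values[msk]),
               rep(0.8 * w, sum(msk)), tolerance = 1e-6)
})

test_that("2D Gaussian fit recovers the spot sigma", {
  g <- sim_grid(c(30, 30), 0.14)
  xy <- trfd:::grid_xy(g)
  mk <- function(sx, sy) scalar_map(
    outer(xy$y, xy$x, function(y, x)
      6 * exp(-(x^2 / (2 * sx^2) + y^2 / (2 * sy^2)))),
    0.14, g$origin_mm)
  fit <- fit_spot_sigma(mk(3.8, 3.8))
  expect_equal(fit$sigma_mm, 3.8, tolerance = 0.005)
  # anisotropic spots report the mean of the axis sigmas
  fit2 <- fit_spot_sigma(mk(3.6, 4.0))
  expect_equal(fit2$sigma_mm, 3.8, tolerance = 0.01)
  expect_equal(fit2$sigma_x_mm, 3.6, tolerance = 0.02)
  expect_equal(fit2$sigma_y_mm, 4.0, tolerance = 0.02)
  expect_error(fit_spot_sigma(scalar_map(matrix(0, 10, 10), 1)),
               class = "trfd_fit_error")
})

test_that("dose-per-MU commissioning fits the machine line", {
  pat <- grid_pattern(7, 5)
  ratio <- field_to_spot_ratio(pat, 3.8)
  # two exact points define the line
  meas <- tibble::tibble(
    current_nA = c(25, 215),
    mu_per_spot = c(80, 80),
    field_dose_gy = c(0.04, 0.06) * 80 * ratio)
  fit <- commission_dose_per_mu(meas, pat, 3.8)
  expect_equal(fit$slope, 0.02 / 190, tolerance = 1e-9)
  expect_equal(fit$intercept + 25 * fit$slope, 0.04, tolerance = 1e-9)

  # four noiseless currents from a known line
  cur <- c(25, 60, 120, 215)
  meas4 <- tibble::tibble(
    current_nA = cur, mu_per_spot = 50,
    field_dose_gy = (0.037 + 1e-4 * cur) * 50 * ratio)
  fit4 <- commission_dose_per_mu(meas4, pat, 3.8)
  expect_equal(fit4$intercept, 0.037, tolerance = 1e-9)
  expect_equal(fit4$slope, 1e-4, tolerance = 1e-9)

  expect_error(commission_dose_per_mu(meas4[1, ], pat, 3.8),
               class = "trfd_fit_error")
  # time per MU helper
  expect_equal(commission_time_per_mu(c(1000, 2000), c(1.0, 2.0)), 1e-3)
})
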