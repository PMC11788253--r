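# piecewise-linear crossing oracle: exact threshold time on the raw
# breakpoint representation of a curve
cross_oracle <- function(t_bp, v_bp, thr) {
  for (k in seq_len(length(t_bp) - 1)) {
    if (v_bp[k] < thr && v_bp[k + 1] >= thr) {
      return(t_bp[k] + (thr - v_bp[k]) / (v_bp[k + 1] - v_bp[k]) *
               (t_bp[k + 1] - t_bp[k]))
    }
  }
  if (v_bp[1] >= thr) return(t_bp[1])
  NA_real_
}

test_that("tail normalization scales the plateau to 100", {
  fs <- 100
  curve <- c(seq(0, 5, length.out = 50), rep(5, 150))
  norm <- normalize_accumulation(curve, fs, tail_window_s = 1)
  expect_equal(tail(norm, 1), 100)
  expect_equal(norm, curve * 20)

  expect_null(normalize_accumulation(rep(0, 200), fs, 1))
  expect_error(normalize_accumulation(1:10, fs, 1), class = "trfd_shape_error")

  # noisy tail: scale equals 100 / tail mean
  set.seed(4)
  noisy <- c(seq(0, 2, length.out = 100), 2 + rnorm(100, sd = 0.01))
  nn <- normalize_accumulation(noisy, fs, 1)
  expect_equal(mean(tail(nn, 100)), 100, tolerance = 1e-9)
})

test_that("threshold crossings match closed forms and the oracle", {
  fs <- 1000
  # linear ramp 0 -> 100 over 0.1 s then flat
  tt <- seq(0, 0.3, by = 1 / fs)
  curve <- pmin(tt / 0.1, 1) * 100
  cr <- threshold_crossings(curve, fps = fs)
  expect_equal(unname(cr["t1"]), 0.01, tolerance = 1e-9)
  expect_equal(unname(cr["t2"]), 0.09, tolerance = 1e-9)

  # one-sample step: delta-t below one sample period
  step <- c(rep(0, 501), rep(100, 300))
  crs <- threshold_crossings(step, fps = fs)
  expect_lt(crs["t2"] - crs["t1"], 1 / fs + 1e-12)
  expect_equal(unname(crs["t1"]), 0.5, tolerance = 1.1 / fs)

  # two half-deliveries with a pause: t2 lands in the second ramp
  t_bp <- c(0, 0.1, 0.6, 0.7)
  v_bp <- c(0, 50, 50, 100)
  curve2 <- approx(t_bp, v_bp, xout = seq(0, 1, by = 1 / fs), rule = 2)$y
  cr2 <- threshold_crossings(curve2, fps = fs)
  expect_equal(unname(cr2["t1"]), cross_oracle(t_bp, v_bp, 10),
               tolerance = 1e-6)
  expect_equal(unname(cr2["t2"]), cross_oracle(t_bp, v_bp, 90),
               tolerance = 1e-6)
  expect_equal(unname(cr2["t2"] - cr2["t1"]), 0.66, tolerance = 1e-6)

  # threshold never reached
  expect_true(is.na(threshold_crossings(c(0, 50, 50), fps = fs)["t2"]))
})

test_that("delta-t equals 0.8 of the ramp width for random ramps", {
  set.seed(21)
  for (i in 1:10) {
    fs <- sample(c(240, 1000, 5000), 1)
    w <- runif(1, 0.05, 0.5)
    tt <- seq(0, w + 2, by = 1 / fs)
    curve <- pmin(tt / w, 1)
    cr <- threshold_crossings(100 * curve, fps = fs)
    expect_equal(unname(cr["t2"] - cr["t1"]), 0.8 * w, tolerance = 1e-9)
  }
})

test_that("delta-t is invariant under positive rescaling of the curve", {
  fs <- 240
  set.seed(8)
  tt <- seq(0, 2, by = 1 / fs)
  curve <- cumsum(runif(length(tt)))
  p <- delta_t_params()
  base <- threshold_crossings(normalize_accumulation(curve, fs, 1), fs)
  for (s in c(0.01, 3, 1e4)) {
    scl <- threshold_crossings(normalize_accumulation(s * curve, fs, 1), fs)
    expect_equal(scl, base, tolerance = 1e-12)
  }
})

test_that("delta-t maps mask unirradiated pixels and keep geometry", {
  fs <- 240
  nt <- 500
  acc <- array(0, c(4, 4, nt))
  ramp <- pmin(seq(0, nt - 1) / (0.1 * fs), 1) * 6
  for (i in 1:4) for (j in 1:4) if (j <= 2) acc[i, j, ] <- ramp
  dtm <- delta_t_map(acc, fs, pixel_pitch_mm = 0.5)
  expect_s3_class(dtm, "trfd_delta_t_map")
  expect_equal(sum(dtm$mask), 8)
  expect_equal(dtm$delta_t$values[1, 1], 0.8 * 0.1, tolerance = 1e-9)
  expect_true(all(is.na(dtm$delta_t$values[, 3:4])))
  # delta_t = t2 - t1 >= 0 on masked-in pixels
  d <- dtm$t2$values - dtm$t1$values
  expect_true(all(d[dtm$mask] >= 0))
  expect_error(delta_t_map(acc[, , 1:100], fs), class = "trfd_shape_error")
})

test_that("PBS dose rate follows the Folkerts ratio", {
  # uniform delta-t map of 0.08 s with a 10 Gy dose map
  dtm <- trfd:::dt_new(matrix(0.08, 3, 3), matrix(0.01, 3, 3),
                       matrix(0.09, 3, 3), matrix(TRUE, 3, 3), 1, NULL)
  dose <- scalar_map(matrix(10, 3, 3), 1)
  rate <- pbs_dose_rate(dtm, dose, d = 0.10)
  expect_equal(rate$values, matrix(100, 3, 3))

  # relative mode: 80% / 0.4 s = 200 %/s
  dtm2 <- trfd:::dt_new(matrix(0.4, 2, 2), matrix(0, 2, 2),
                        matrix(0.4, 2, 2), matrix(TRUE, 2, 2), 1, NULL)
  expect_equal(pbs_dose_rate(dtm2, d = 0.10)$values, matrix(200, 2, 2))

  # absolute threshold: (10 - 2*0.1) / 0.08
  rate3 <- pbs_dose_rate(dtm, dose, d = 0.1, absolute = TRUE)
  expect_equal(rate3$values, matrix((10 - 0.2) / 0.08, 3, 3))
  expect_error(pbs_dose_rate(dtm, scalar_map(matrix(0.15, 3, 3), 1),
                             d = 0.1, absolute = TRUE),
               class = "trfd_range_error")

  # zero delta-t pixels are masked, not divided
  dt0 <- trfd:::dt_new(matrix(c(0, 0.1, 0.1, 0.1), 2, 2), matrix(0, 2, 2),
                       matrix(0.1, 2, 2), matrix(TRUE, 2, 2), 1, NULL)
  r0 <- pbs_dose_rate(dt0)
  expect_false(r0$mask[1, 1])
  expect_true(all(r0$mask[c(2, 3, 4)]))
})

test_that("in-field mask is the isodose disc of a Gaussian spot", {
  g <- sim_grid(c(20, 20), 0.1)
  xy <- trfd:::grid_xy(g)
  dose <- outer(xy$y, xy$x, function(y, x) 10 * exp(-(x^2 + y^2) / (2 * 3.8^2)))
  mp <- scalar_map(dose, 0.1, g$origin_mm)
  msk <- infield_mask(mp, 0.5)
  r_half <- 3.8 * sqrt(2 * log(2))
  expect_equal(r_half, 4.474, tolerance = 1e-3)
  rr <- sqrt(outer(xy$y^2, xy$x^2, `+`))
  expect_true(all(msk[rr <= r_half - 0.15]))
  expect_false(any(msk[rr >= r_half + 0.15]))

  # uniform map: all in; frac = 1 keeps only maxima
  uni <- scalar_map(matrix(5, 3, 3), 1)
  expect_true(all(infield_mask(uni)))
  pk <- scalar_map(matrix(c(1, 2, 3, 9), 2, 2), 1)
  expect_equal(sum(infield_mask(pk, 1)), 1)
  expect_error(infield_mask(scalar_map(matrix(0, 2, 2), 1)),
               class = "trfd_range_error")
})

test_that("delta-t statistics use interpolated percentiles", {
  dtm <- trfd:::dt_new(matrix(0.3, 3, 3), matrix(0, 3, 3), matrix(0.3, 3, 3),
                       matrix(TRUE, 3, 3), 1, NULL)
  st <- delta_t_statistics(dtm)
  expect_equal(unlist(st[, c("mean", "p5", "p50", "p95")]),
               c(mean = 0.3, p5 = 0.3, p50 = 0.3, p95 = 0.3))

  vals <- matrix(as.numeric(1:100), 10, 10)
  dtm2 <- trfd:::dt_new(vals, vals * 0, vals, matrix(TRUE, 10, 10), 1, NULL)
  st2 <- delta_t_statistics(dtm2)
  expect_equal(st2$p50, 50.5)
  expect_equal(st2$p5, unname(quantile(1:100, 0.05)))

  expect_error(delta_t_statistics(dtm2, matrix(FALSE, 10, 10)),
               class = "trfd_range_error")
})
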