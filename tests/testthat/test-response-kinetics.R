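test_that("kernel evaluation matches the logarithmic law", {
  rf <- ref_rf()
  expect_equal(eval_kernel(rf, 0), 7.5e-3 + 5.7e-4 * log10(5.4e-2),
               tolerance = 1e-12)
  expect_equal(eval_kernel(rf, 0), 6.777e-3, tolerance = 1e-4)
  expect_equal(eval_kernel(rf, 60), 7.5e-3 + 5.7e-4 * log10(60.054),
               tolerance = 1e-12)
  expect_equal(eval_kernel(rf, 60), 8.514e-3, tolerance = 1e-4)
  # darkening grows for positive late gradient
  tt <- seq(0, 60, by = 0.25)
  expect_true(all(diff(eval_kernel(rf, tt)) > 0))
  # zero late gradient collapses to a constant
  rf0 <- response_function(0.01, 0.05, 0)
  expect_equal(eval_kernel(rf0, c(0, 1, 50)), rep(0.01, 3))
  expect_error(response_function(1, -0.1, 1))
  expect_error(eval_kernel(rf, -1), class = "trfd_range_error")
})

test_that("convolution is causal, linear, and matches a brute-force oracle", {
  rf <- ref_rf(duration_s = 2)
  fs <- 100
  k <- trfd:::discretize_kernel(rf, fs, n_lags = 50)

  # unit impulse reproduces the sampled kernel
  p <- rep(0, 50); p[1] <- 1
  r <- convolve_response(pulse_train(p, fs), rf)
  expect_equal(r$values, k[1:50], tolerance = 1e-12)

  # two impulses superpose (linearity)
  p2 <- rep(0, 50); p2[1] <- 1; p2[11] <- 1
  r2 <- convolve_response(pulse_train(p2, fs), rf)
  expect_equal(r2$values, k[1:50] + c(rep(0, 10), k[1:40]), tolerance = 1e-12)

  # zero in, zero out
  expect_equal(convolve_response(pulse_train(rep(0, 30), fs), rf)$values,
               rep(0, 30))

  # random pulse against the direct-sum oracle
  set.seed(11)
  p3 <- runif(80)
  r3 <- convolve_response(pulse_train(p3, fs), rf)
  expect_equal(r3$values, conv_oracle(p3, trfd:::discretize_kernel(rf, fs, 80)),
               tolerance = 1e-10)

  # causality: a late change never affects earlier samples
  p4 <- p3; p4[60] <- p4[60] + 5
  r4 <- convolve_response(pulse_train(p4, fs), rf)
  expect_equal(r4$values[1:59], r3$values[1:59], tolerance = 1e-12)
})

test_that("deconvolution inverts convolution to numerical precision", {
  rf <- ref_rf(duration_s = 5)
  fs <- 240
  set.seed(5)
  for (n in c(64, 200, 1000)) {
    p <- runif(n)
    r <- convolve_response(pulse_train(p, fs), rf)
    p2 <- deconvolve_response(r, rf)
    expect_lt(max(abs(p2$values - p)) / max(p), 1e-9)
  }

  # block pulse with the reference kernel
  p <- rep(0, 1200); p[101:124] <- 183
  r <- convolve_response(pulse_train(p, fs), rf)
  p2 <- deconvolve_response(r, rf)
  expect_lt(max(abs(p2$values - p)), 1e-6)

  # matrix (multi-pixel) deconvolution agrees with per-column
  pm <- matrix(runif(300), 100, 3)
  rm_ <- convolve_response(pulse_train(pm, fs), rf)
  back <- deconvolve_response(rm_, rf)
  expect_equal(back$values, pm, tolerance = 1e-9)

  expect_error(deconvolve_response(response_curve(1, fs), rf),
               class = "trfd_shape_error")
})

test_that("noisy responses deconvolve to the documented noise floor", {
  rf <- ref_rf(duration_s = 5)
  fs <- 240
  set.seed(9)
  p <- rep(0, 800); p[101:148] <- 2
  r <- convolve_response(pulse_train(p, fs), rf)
  noisy <- response_curve(r$values + rnorm(800, sd = 1e-4), fs)
  back <- deconvolve_response(noisy, rf)
  # re-convolution reproduces the noisy input exactly (exact solve)
  again <- convolve_response(back, rf)
  expect_lt(max(abs(again$values - noisy$values)), 1e-8)
  # the recovered pulse may go negative: that is the documented behavior
  expect_true(any(back$values < 0))
})

test_that("ridge-regularized deconvolution approximates the pulse", {
  rf <- ref_rf(duration_s = 1)
  fs <- 50
  p <- rep(0, 100); p[11:20] <- 1
  r <- convolve_response(pulse_train(p, fs), rf)
  back <- deconvolve_response(r, rf, reg_lambda = 1e-10)
  expect_equal(back$values, p, tolerance = 1e-3)
})

test_that("accumulation is the running integral of the pulse", {
  fs <- 100
  p <- pulse_train(c(rep(2, 10), rep(0, 5)), fs)
  acc <- accumulate(p)
  expect_equal(acc, c(2 * (1:10), rep(20, 5)))
  # impulse gives a step
  expect_equal(accumulate(pulse_train(c(0, 5, 0, 0), fs)), c(0, 5, 5, 5))
  # non-negative pulse gives monotone accumulation
  set.seed(2)
  acc2 <- accumulate(pulse_train(runif(50), fs))
  expect_true(all(diff(acc2) >= 0))
})

test_that("response-function fit recovers the generating kernel", {
  rf <- ref_rf()
  fs <- 240
  n <- 61 * fs
  p <- rep(0, n); p[1:24] <- 183  # 0.1 s block at 183 nA
  r <- convolve_response(pulse_train(p, fs), rf)
  fit <- fit_response_function(r, pulse_train(p, fs))
  expect_equal(fit$offset, 7.5e-3, tolerance = 0.05)
  expect_equal(fit$a_shift, 5.4e-2, tolerance = 0.05)
  expect_equal(fit$c_slope, 5.7e-4, tolerance = 0.05)
  expect_lt(fit$rms, 1e-10)

  # impulse case: response equals the sampled kernel
  p2 <- rep(0, n); p2[1] <- 1
  r2 <- convolve_response(pulse_train(p2, fs), rf)
  fit2 <- fit_response_function(r2, pulse_train(p2, fs))
  expect_equal(fit2$a_shift, rf$a_shift, tolerance = 1e-6)

  expect_error(fit_response_function(r, pulse_train(rep(0, n), fs)),
               class = "trfd_fit_error")
})

test_that("fit tolerates additive response noise within 5%", {
  rf <- ref_rf()
  fs <- 240
  n <- 61 * fs
  p <- rep(0, n); p[1:24] <- 183
  r <- convolve_response(pulse_train(p, fs), rf)
  set.seed(31)
  noisy <- response_curve(r$values + rnorm(n, sd = 1e-3 * max(r$values)), fs)
  fit <- fit_response_function(noisy, pulse_train(p, fs))
  expect_equal(fit$offset, rf$offset, tolerance = 0.05)
  expect_equal(fit$a_shift, rf$a_shift, tolerance = 0.05)
  expect_equal(fit$c_slope, rf$c_slope, tolerance = 0.05)
})
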