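#' Film response function (post-irradiation coloration kernel)
#'
#' Radiochromic film keeps darkening after the beam stops. The package models
#' the coloration caused by an instantaneous dose deposit as a logarithmic
#' kernel `k(t) = offset + c_slope * log10(t + a_shift)`: a fast initial
#' response (governed by `a_shift`, in seconds) followed by a slow logarithmic
#' growth (`c_slope`, per decade). A measured coloration trace is then the
#' causal convolution of the delivered pulse with this kernel, and undoing the
#' post-irradiation effect is a deconvolution.
#'
#' @param offset Dimensionless kernel offset.
#' @param a_shift Early-response time shift in s (> 0 so the log argument is
#'   positive at t = 0).
#' @param c_slope Late-response gradient per decade.
#' @param duration_s Kernel support length in s; 60 s matches the
#'   stabilization window over which recordings continue after beam start.
#' @return A `trfd_response_function`.
#' @export
response_function <- function(offset, a_shift, c_slope, duration_s = 60) {
  if (a_shift <= 0) stop_trfd("`a_shift` must be positive")
  if (duration_s <= 0) stop_trfd("`duration_s` must be positive")
  structure(list(offset = offset, a_shift = a_shift, c_slope = c_slope,
                 duration_s = duration_s, rms = NA_real_),
            class = "trfd_response_function")
}

#' @export
print.trfd_response_function <- function(x, ...) {
  cat(sprintf(
    "<trfd_response_function> k(t) = %.4g + %.4g log10(t + %.4g), support %g s\n",
    x$offset, x$c_slope, x$a_shift, x$duration_s))
  if (is.finite(x$rms)) cat(sprintf("  fit residual rms %.3g\n", x$rms))
  invisible(x)
}

#' @export
tidy.trfd_response_function <- function(x, ...) {
  tibble(term = c("offset", "a_shift", "c_slope"),
         estimate = c(x$offset, x$a_shift, x$c_slope),
         unit = c("", "s", "1/decade"))
}

#' @export
glance.trfd_response_function <- function(x, ...) {
  tibble(rms = x$rms, duration_s = x$duration_s)
}

#' @rdname response_function
#' @param rf A `trfd_response_function`.
#' @param times Times in s (>= 0).
#' @return [eval_kernel()] returns the kernel values at `times`.
#' @export
eval_kernel <- function(rf, times) {
  if (min(times) < 0) stop_trfd("kernel times must be >= 0", "trfd_range_error")
  rf$offset + rf$c_slope * log10(times + rf$a_shift)
}

# kernel sampled at t = i/fs over its nominal support, or over `n_lags`
# samples when the record is longer (the log law holds for all t >= 0;
# truncating to zero would make old deposits "un-color")
discretize_kernel <- function(rf, sample_rate_hz, n_lags = NULL) {
  n <- max(ceiling(rf$duration_s * sample_rate_hz) + 1, n_lags %||% 0)
  eval_kernel(rf, (seq_len(n) - 1) / sample_rate_hz)
}

#' Pulse trains and response curves
#'
#' Light containers for regularly sampled time series: a `pulse_train` holds
#' the dose (or current) deposited per sample step; a `response_curve` holds
#' the film reading per step. `values` may be a vector (one pixel or a
#' spatial average) or a matrix with time in rows and pixels in columns.
#'
#' @param values Numeric vector or time-by-pixel matrix.
#' @param sample_rate_hz Sampling rate (> 0).
#' @return A `trfd_pulse_train` / `trfd_response_curve`.
#' @export
pulse_train <- function(values, sample_rate_hz) {
  if (sample_rate_hz <= 0) stop_trfd("`sample_rate_hz` must be positive")
  structure(list(values = values, sample_rate_hz = sample_rate_hz),
            class = "trfd_pulse_train")
}

#' @rdname pulse_train
#' @export
response_curve <- function(values, sample_rate_hz) {
  if (sample_rate_hz <= 0) stop_trfd("`sample_rate_hz` must be positive")
  structure(list(values = values, sample_rate_hz = sample_rate_hz),
            class = "trfd_response_curve")
}

# causal FFT convolution of each column of x with kernel k, truncated to
# nrow(x); x may be a vector
causal_convolve <- function(x, k) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1)
  n <- nrow(x)
  L <- nextn(n + length(k) - 1, 2)
  K <- fft(c(k, rep(0, L - length(k))))
  out <- matrix(0, n, ncol(x))
  chunk <- max(1L, floor(2^24 / L))  # bound scratch memory
  for (j0 in seq(1, ncol(x), by = chunk)) {
    j1 <- min(j0 + chunk - 1L, ncol(x))
    xp <- rbind(x[, j0:j1, drop = FALSE],
                matrix(0, L - n, j1 - j0 + 1L))
    conv <- Re(mvfft(mvfft(xp) * K, inverse = TRUE)) / L
    out[, j0:j1] <- conv[seq_len(n), , drop = FALSE]
  }
  if (vec) out <- drop(out)
  out
}

#' Forward model: convolve a pulse with the film response
#'
#' The film reading is the causal discrete convolution
#' `response[n] = sum_{i <= n} pulse[i] * k(n - i)`, evaluated per pixel and
#' truncated to the pulse length.
#'
#' @param pulse A [pulse_train()].
#' @param rf A [response_function()], discretized at the pulse's sample rate.
#' @return A [response_curve()] of the same length/shape as the pulse.
#' @export
convolve_response <- function(pulse, rf) {
  n <- if (is.null(dim(pulse$values))) length(pulse$values) else nrow(pulse$values)
  k <- discretize_kernel(rf, pulse$sample_rate_hz, n_lags = n)
  response_curve(causal_convolve(pulse$values, k), pulse$sample_rate_hz)
}

# coefficients of the truncated power-series reciprocal of k (length n),
# i.e. the first row generator of the inverse lower-triangular Toeplitz
# system, by Newton iteration (each step doubles the valid length)
reciprocal_series <- function(k, n) {
  if (k[1] == 0) stop_trfd("kernel leading sample is zero (non-invertible)",
                           "trfd_fit_error")
  scale <- k[1]
  k <- k / scale
  g <- 1
  len <- 1L
  while (len < n) {
    len2 <- min(2L * len, n)
    L <- nextn(2L * len2, 2)
    K <- fft(c(k[seq_len(min(len2, length(k)))],
               rep(0, L - min(len2, length(k)))))
    G <- fft(c(g, rep(0, L - length(g))))
    kg <- Re(fft(K * G, inverse = TRUE))[seq_len(len2)] / L
    corr <- -kg
    corr[1] <- 2 - kg[1]
    CR <- fft(c(corr, rep(0, L - len2)))
    g <- (Re(fft(G * CR, inverse = TRUE)) / L)[seq_len(len2)]
    len <- len2
  }
  g / scale
}

#' Undo the post-irradiation coloration: deconvolution
#'
#' Recovers the delivered pulse from a measured response. With
#' `reg_lambda = 0` this is the exact solve of the causal (lower-triangular
#' Toeplitz) convolution system — algebraically identical to polynomial long
#' division — implemented via a Newton power-series reciprocal of the kernel
#' and FFT convolution, so whole pixel blocks deconvolve in O(N log N). With
#' `reg_lambda > 0` a ridge-regularized least-squares solve is used instead
#' (dense; intended for single curves, not frame stacks).
#'
#' The exact solve amplifies measurement noise and the recovered pulse may
#' contain negative samples; an optional centered moving average
#' (`smooth_window_s`) can be applied to the response first.
#'
#' @param response A [response_curve()] (>= 2 samples).
#' @param rf The [response_function()] used in delivery.
#' @param reg_lambda Ridge penalty (>= 0).
#' @param smooth_window_s Moving-average window in s applied to the response
#'   before deconvolution (0 = off).
#' @return A [pulse_train()]; convolving it back reproduces the (smoothed)
#'   input to numerical precision when `reg_lambda = 0`.
#' @export
deconvolve_response <- function(response, rf, reg_lambda = 0,
                                smooth_window_s = 0) {
  v <- response$values
  vec <- is.null(dim(v))
  if (vec) v <- matrix(v, ncol = 1)
  n <- nrow(v)
  if (n < 2) stop_trfd("response shorter than 2 samples", "trfd_shape_error")
  if (smooth_window_s > 0) {
    w <- max(1L, round(smooth_window_s * response$sample_rate_hz))
    if (w %% 2 == 0) w <- w + 1L
    v <- apply_moving_average(v, w)
  }
  k <- discretize_kernel(rf, response$sample_rate_hz, n_lags = n)
  if (k[1] == 0) stop_trfd("kernel leading sample is zero (non-invertible)",
                           "trfd_fit_error")
  if (reg_lambda == 0) {
    g <- reciprocal_series(k, n)
    out <- causal_convolve(v, g)
  } else {
    k <- k[seq_len(min(length(k), n))]
    K <- matrix(0, n, n)
    idx <- which(lower.tri(K, diag = TRUE), arr.ind = TRUE)
    K[idx] <- k[idx[, 1] - idx[, 2] + 1]
    A <- crossprod(K) + diag(reg_lambda, n)
    out <- solve(A, crossprod(K, v))
  }
  if (vec) out <- drop(out)
  pulse_train(out, response$sample_rate_hz)
}

# centered moving average per column, edges shrink symmetrically
apply_moving_average <- function(v, w) {
  if (w <= 1) return(v)
  h <- (w - 1L) %/% 2L
  cs <- apply(rbind(0, v), 2, cumsum)
  n <- nrow(v)
  i <- seq_len(n)
  lo <- pmax(i - h, 1L); hi <- pmin(i + h, n)
  (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1L)
}

#' Dose accumulation: integrate a pulse over time
#'
#' The relative dose accumulation is the running integral of the recovered
#' pulse — a cumulative sum at the pulse sampling, whose final value is the
#' total delivered (relative) dose.
#'
#' @param pulse A [pulse_train()].
#' @return Numeric vector/matrix of the same shape: the accumulation curve.
#' @export
accumulate <- function(pulse) {
  v <- pulse$values
  if (is.null(dim(v))) cumsum(v) else apply(v, 2, cumsum)
}

#' Fit the film response function from a known pulse
#'
#' Given a measured response and the pulse that generated it (e.g. a block
#' pulse of known nozzle current and duration from the reference monitor),
#' least-squares fits the kernel parameters (offset, a_shift, c_slope) so
#' that `pulse (*) k` matches the response.
#'
#' @param response A [response_curve()] (vector-valued; spatially averaged
#'   in-field trace), covering at least `duration_s` past the pulse end.
#' @param pulse The known [pulse_train()] at the same sample rate.
#' @param duration_s Kernel support for the fitted function.
#' @param init Optional named list with starting values `offset`, `a_shift`,
#'   `c_slope`.
#' @return A [response_function()] with the residual RMS in `$rms`.
#' @export
fit_response_function <- function(response, pulse, duration_s = 60,
                                  init = NULL) {
  if (pulse$sample_rate_hz != response$sample_rate_hz) {
    stop_trfd("pulse and response sample rates differ", "trfd_shape_error")
  }
  p <- as.numeric(pulse$values)
  r <- as.numeric(response$values)
  if (all(p == 0)) stop_trfd("pulse is all zero", "trfd_fit_error")
  if (length(p) < length(r)) p <- c(p, rep(0, length(r) - length(p)))
  if (length(p) > length(r)) {
    stop_trfd("pulse longer than response", "trfd_shape_error")
  }
  fs <- pulse$sample_rate_hz
  n_support <- ceiling(duration_s * fs) + 1
  pulse_end <- max(which(p != 0))
  if (length(r) < pulse_end + n_support - 1) {
    stop_trfd("response does not cover duration_s past the pulse end",
              "trfd_fit_error")
  }
  if (is.null(init)) {
    init <- list(offset = mean(tail(r, max(1, round(fs)))) / sum(p),
                 a_shift = 0.05, c_slope = 1e-3)
  }
  tt <- (seq_along(r) - 1) / fs  # kernel over all lags present in the record
  model <- function(offset, a_shift, c_slope) {
    causal_convolve(p, offset + c_slope * log10(tt + a_shift))
  }
  dat <- data.frame(r = r)
  fit <- minpack.lm::nlsLM(
    r ~ model(offset, a_shift, c_slope),
    data = dat, start = init,
    lower = c(-Inf, 1e-4, -Inf), upper = c(Inf, 10, Inf),
    control = minpack.lm::nls.lm.control(maxiter = 300))
  cf <- coef(fit)
  rf <- response_function(cf[["offset"]], cf[["a_shift"]], cf[["c_slope"]],
                          duration_s = duration_s)
  rf$rms <- sqrt(mean(residuals(fit)^2))
  rf
}
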