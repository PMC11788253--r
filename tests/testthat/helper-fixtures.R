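# Shared fixtures, built in code.

# published-style calibration curve and coloration kernel used across tests
ref_cal <- function() calibration_params(-7.48e-3, 24.5, 33.5, 1.80)
ref_rf <- function(duration_s = 60) {
  response_function(offset = 7.5e-3, a_shift = 5.4e-2, c_slope = 5.7e-4,
                    duration_s = duration_s)
}

# OD values of the 9-level calibration series, found by inverting the curve
ref_cal_points <- function() {
  cal <- ref_cal()
  dose <- c(0, 0.5, 1, 2, 5, 10, 20, 30, 50)
  od <- vapply(dose, function(D) {
    if (D <= cal$a) return(0)
    uniroot(function(x) apply_calibration(x, cal) - D, c(0, 5),
            tol = 1e-14)$root
  }, numeric(1))
  tibble::tibble(od_net = od, dose = dose)
}

# brute-force causal convolution (independent of the FFT path)
conv_oracle <- function(p, k) {
  n <- length(p)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- seq_len(i)
    lag <- i - j + 1
    kk <- ifelse(lag <= length(k), k[lag], 0)
    out[i] <- sum(p[j] * kk)
  }
  out
}

# small uniform-MU square pattern
grid_pattern <- function(n_side = 7, spacing = 5, mu = 1) {
  pos <- seq(-(n_side - 1) / 2, (n_side - 1) / 2) * spacing
  g <- expand.grid(x = pos, y = pos)
  spot_list(g$x, g$y, rep(mu, nrow(g)))
}
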