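# exhaustive gamma oracle: same candidate-lattice semantics as local_gamma,
# plain loops, no search-radius cutoff and no early stopping
gamma_oracle <- function(eval_map, ref_map, dd, dta, step, mask = NULL) {
  em <- eval_map$values
  xs <- trfd:::map_x(eval_map); ys <- trfd:::map_y(eval_map)
  msk <- eval_map$mask
  if (!is.null(mask)) msk <- msk & mask
  half <- max(dim(em)) * eval_map$pixel_pitch_mm  # covers the whole map
  offs <- expand.grid(dx = seq(-half, half, by = step),
                      dy = seq(-half, half, by = step))
  out <- matrix(NA_real_, nrow(em), ncol(em))
  for (i in seq_len(nrow(em))) for (j in seq_len(ncol(em))) {
    if (!msk[i, j]) next
    g2 <- Inf
    for (k in seq_len(nrow(offs))) {
      vr <- trfd:::bilinear_ref(ref_map$values, ref_map,
                                xs[j] + offs$dx[k], ys[i] + offs$dy[k])
      if (is.na(vr) || vr <= 0) next
      g2 <- min(g2, (offs$dx[k]^2 + offs$dy[k]^2) / dta^2 +
                  (em[i, j] - vr)^2 / (dd * vr)^2)
    }
    out[i, j] <- sqrt(g2)
  }
  out
}

# smooth positive synthetic field on an n x n grid
smooth_map <- function(n, pitch, seed, base = 1) {
  set.seed(seed)
  xs <- (seq_len(n) - 0.5) * pitch
  f <- function(x, y) base + 0.3 * sin(x / 3) + 0.2 * cos(y / 4) +
    0.1 * sin((x + y) / 5)
  scalar_map(outer(xs, xs, function(y, x) f(x, y)), pitch,
             origin_mm = c(0, 0))
}
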