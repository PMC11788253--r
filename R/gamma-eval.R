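#' Gamma evaluation criteria
#'
#' @param value_frac Value criterion as a fraction of the reference value
#'   (local mode) or of the reference maximum (global mode); 0.10 = 10%.
#' @param distance_mm Distance-to-agreement criterion in mm.
#' @param search_radius_factor Search radius in multiples of `distance_mm`;
#'   at 3, any reference point beyond the radius already contributes
#'   gamma > 3, so no gamma <= 1 decision can change.
#' @param local Use local normalization (the criterion scales with the
#'   reference value at each candidate point).
#' @param value_floor Minimum reference value for a candidate point to be
#'   evaluated (same units as the maps); pixels with no candidate above the
#'   floor are excluded.
#' @return A `trfd_gamma_criteria`.
#' @export
gamma_criteria <- function(value_frac = 0.10, distance_mm = 2.0,
                           search_radius_factor = 3, local = TRUE,
                           value_floor = 0) {
  if (value_frac <= 0) stop_trfd("`value_frac` must be positive")
  if (distance_mm <= 0) stop_trfd("`distance_mm` must be positive")
  structure(list(value_frac = value_frac, distance_mm = distance_mm,
                 search_radius_factor = search_radius_factor, local = local,
                 value_floor = value_floor),
            class = "trfd_gamma_criteria")
}

#' Register two maps by their dose distributions
#'
#' Finds the translation of the measured map that maximizes the normalized
#' cross-correlation with the simulated map (masked-in overlap only), with
#' sub-pixel refinement by parabolic interpolation of the correlation peak.
#' Matching is done on the dose maps; the resulting shift is then applied to
#' the measured delta-t map before the gamma evaluation.
#'
#' @param measured,simulated Dose [scalar_map()]s on grids of equal pitch.
#' @param max_shift_mm Search window half-width in mm.
#' @return List with `dx_mm`, `dy_mm` (add to the measured map's coordinates
#'   to align it with the simulation) and `ncc` (peak correlation).
#' @export
register_maps <- function(measured, simulated, max_shift_mm = 5) {
  if (abs(measured$pixel_pitch_mm - simulated$pixel_pitch_mm) > 1e-9) {
    stop_trfd("register_maps needs equal pixel pitches", "trfd_shape_error")
  }
  pp <- measured$pixel_pitch_mm
  if (!any(measured$mask & measured$values > 0) ||
      !any(simulated$mask & simulated$values > 0)) {
    stop_trfd("both maps need positive signal", "trfd_range_error")
  }
  # integer offset between the two grids' origins
  base_shift <- round((simulated$origin_mm - measured$origin_mm) / pp)
  nshift <- ceiling(max_shift_mm / pp)
  shifts <- -nshift:nshift
  ncc <- matrix(NA_real_, length(shifts), length(shifts))
  mv <- measured$values; mv[!measured$mask] <- NA
  sv <- simulated$values; sv[!simulated$mask] <- NA
  for (a in seq_along(shifts)) {
    for (b in seq_along(shifts)) {
      # measured pixel (i, j) aligned with simulated pixel (i + oy, j + ox)
      ox <- -base_shift[1] + shifts[b]
      oy <- -base_shift[2] + shifts[a]
      ncc[a, b] <- masked_ncc(mv, sv, oy, ox)
    }
  }
  if (all(is.na(ncc))) stop_trfd("maps do not overlap", "trfd_range_error")
  pk <- which(ncc == max(ncc, na.rm = TRUE), arr.ind = TRUE)[1, ]
  if (pk[1] %in% c(1, length(shifts)) || pk[2] %in% c(1, length(shifts))) {
    stop_trfd("correlation peak at search boundary: registration failed",
              "trfd_range_error")
  }
  sub <- function(i, j, di) {
    y0 <- ncc[i, j]
    ym <- ncc[i - di[1], j - di[2]]; yp <- ncc[i + di[1], j + di[2]]
    if (is.na(ym) || is.na(yp)) return(0)
    den <- ym - 2 * y0 + yp
    if (den >= 0) 0 else 0.5 * (ym - yp) / den
  }
  # measured pixel (i, j) matches simulated pixel (i + oy, j + ox), so the
  # physical translation includes the origin difference
  oy <- -base_shift[2] + shifts[pk[1]] + sub(pk[1], pk[2], c(1, 0))
  ox <- -base_shift[1] + shifts[pk[2]] + sub(pk[1], pk[2], c(0, 1))
  dx <- (simulated$origin_mm[1] - measured$origin_mm[1]) + ox * pp
  dy <- (simulated$origin_mm[2] - measured$origin_mm[2]) + oy * pp
  # shifting the measured grid by (dx, dy) aligns it with the simulation
  list(dx_mm = dx, dy_mm = dy, ncc = max(ncc, na.rm = TRUE))
}

masked_ncc <- function(a, b, oy, ox) {
  na <- dim(a); nb <- dim(b)
  i_a <- max(1, 1 - oy):min(na[1], nb[1] - oy)
  j_a <- max(1, 1 - ox):min(na[2], nb[2] - ox)
  if (length(i_a) < 2 || length(j_a) < 2) return(NA_real_)
  av <- a[i_a, j_a]; bv <- b[i_a + oy, j_a + ox]
  keep <- !is.na(av) & !is.na(bv)
  if (sum(keep) < 9) return(NA_real_)
  av <- av[keep] - mean(av[keep]); bv <- bv[keep] - mean(bv[keep])
  den <- sqrt(sum(av^2) * sum(bv^2))
  if (den == 0) return(NA_real_)
  sum(av * bv) / den
}

#' Shift a map's physical coordinates
#'
#' @param map A [scalar_map()] or `trfd_delta_t_map`.
#' @param dx_mm,dy_mm Translation applied to the map's origin.
#' @return The shifted object (values untouched).
#' @export
shift_map <- function(map, dx_mm, dy_mm) {
  if (inherits(map, "trfd_delta_t_map")) {
    map$origin_mm <- map$origin_mm + c(dx_mm, dy_mm)
    for (f in c("delta_t", "t1", "t2")) {
      map[[f]]$origin_mm <- map[[f]]$origin_mm + c(dx_mm, dy_mm)
    }
    return(map)
  }
  map$origin_mm <- map$origin_mm + c(dx_mm, dy_mm)
  map
}

#' Local 2-D gamma evaluation
#'
#' For each masked-in evaluated pixel at position r_m with value v_m, the
#' gamma value is the minimum over candidate reference positions r_s of
#' `sqrt(|r_m - r_s|^2 / dta^2 + (v_m - v_r(r_s))^2 / (dd * v_r(r_s))^2)`
#' with `dta = distance_mm` and `dd = value_frac` (local normalization: the
#' value criterion scales with the reference value at the candidate point;
#' in global mode the denominator uses the reference maximum). Candidates
#' live on a refined lattice of step `distance_mm / 10` centered on the
#' evaluated pixel, out to `search_radius_factor * distance_mm`; reference
#' values are bilinearly interpolated. Candidates below `value_floor` or
#' outside the reference grid are skipped. Offsets are visited in order of
#' increasing distance and the search stops once the spatial term alone
#' exceeds every pixel's current minimum, which leaves the result identical
#' to the full search.
#'
#' @param eval_map Evaluated map: [scalar_map()] or `trfd_delta_t_map`
#'   (its `delta_t` component is used).
#' @param ref_map Reference map, same kind, on its own grid.
#' @param criteria A [gamma_criteria()].
#' @param mask Optional logical matrix further restricting evaluated pixels
#'   (e.g. the in-field mask).
#' @return A `trfd_gamma`: `gamma` [scalar_map()], `pass_rate`,
#'   `n_evaluated`, `shift_applied_mm`.
#' @export
local_gamma <- function(eval_map, ref_map, criteria = gamma_criteria(),
                        mask = NULL) {
  if (inherits(eval_map, "trfd_delta_t_map")) eval_map <- eval_map$delta_t
  if (inherits(ref_map, "trfd_delta_t_map")) ref_map <- ref_map$delta_t
  emask <- eval_map$mask
  if (!is.null(mask)) emask <- emask & mask
  if (!any(emask)) stop_trfd("empty evaluation mask", "trfd_range_error")
  ev <- eval_map$values
  if (any(emask & !is.finite(ev))) {
    stop_trfd("non-finite evaluated values inside the mask",
              "trfd_range_error")
  }
  rv <- ref_map$values
  rv[!ref_map$mask] <- NA_real_

  dta <- criteria$distance_mm
  dd <- criteria$value_frac
  step <- dta / 10
  radius <- criteria$search_radius_factor * dta
  offs <- expand.grid(dx = seq(-radius, radius, by = step),
                      dy = seq(-radius, radius, by = step))
  offs$r2 <- offs$dx^2 + offs$dy^2
  offs <- offs[offs$r2 <= radius^2 + 1e-12, ]
  offs <- offs[order(offs$r2), ]

  xe <- map_x(eval_map); ye <- map_y(eval_map)
  sel <- which(emask)
  iy <- ((sel - 1) %% nrow(ev)) + 1
  ix <- ((sel - 1) %/% nrow(ev)) + 1
  px <- xe[ix]; py <- ye[iy]
  vm <- ev[sel]
  # pixels whose local reference value is below the floor are not evaluated
  vr0 <- bilinear_ref(rv, ref_map, px, py)
  keep <- !is.na(vr0) & vr0 >= criteria$value_floor
  sel <- sel[keep]; px <- px[keep]; py <- py[keep]; vm <- vm[keep]
  if (!length(sel)) stop_trfd("no evaluable pixels (reference below floor)",
                              "trfd_range_error")
  gmax <- if (criteria$local) NULL else max(rv, na.rm = TRUE)

  g2 <- rep(Inf, length(sel))
  evaluated <- rep(FALSE, length(sel))
  for (k in seq_len(nrow(offs))) {
    d2 <- offs$r2[k] / dta^2
    if (d2 > max(g2[evaluated], if (all(evaluated)) -Inf else Inf)) break
    vr <- bilinear_ref(rv, ref_map, px + offs$dx[k], py + offs$dy[k])
    valid <- !is.na(vr) & vr >= criteria$value_floor
    if (!any(valid)) next
    den <- if (criteria$local) dd * vr[valid] else dd * gmax
    cand <- d2 + ((vm[valid] - vr[valid]) / den)^2
    cand[!is.finite(cand)] <- Inf
    g2v <- g2[valid]
    g2[valid] <- pmin(g2v, cand)
    evaluated <- evaluated | valid
  }
  gam <- sqrt(g2)
  gam[!evaluated] <- NA_real_
  gmat <- matrix(NA_real_, nrow(ev), ncol(ev))
  gmat[sel] <- gam
  n_eval <- sum(evaluated)
  if (n_eval == 0) stop_trfd("no evaluable pixels (reference below floor)",
                             "trfd_range_error")
  # boundary tolerance: a pixel exactly on the criterion (gamma = 1) passes
  # regardless of floating-point representation
  pass <- sum(gam[evaluated] <= 1 + 1e-9) / n_eval
  structure(list(
    gamma = scalar_map(gmat, eval_map$pixel_pitch_mm, eval_map$origin_mm,
                       !is.na(gmat)),
    pass_rate = pass, n_evaluated = n_eval,
    shift_applied_mm = c(0, 0), criteria = criteria),
    class = "trfd_gamma")
}

# bilinear interpolation of the reference raster at physical points;
# NA outside the grid or where any corner is NA
bilinear_ref <- function(rv, ref, x, y) {
  pp <- ref$pixel_pitch_mm
  fx <- (x - ref$origin_mm[1]) / pp - 0.5
  fy <- (y - ref$origin_mm[2]) / pp - 0.5
  jx <- floor(fx); jy <- floor(fy)
  wx <- fx - jx; wy <- fy - jy
  n <- nrow(rv); m <- ncol(rv)
  out <- rep(NA_real_, length(x))
  ok <- jx >= 0 & jx <= m - 2 & jy >= 0 & jy <= n - 2
  # points exactly on the last row/column collapse onto the edge cell
  edgex <- jx == m - 1 & wx <= 1e-9
  edgey <- jy == n - 1 & wy <= 1e-9
  jx2 <- jx; jy2 <- jy
  jx2[edgex] <- m - 2; jy2[edgey] <- n - 2
  wx[edgex] <- 1; wy[edgey] <- 1
  ok <- jx2 >= 0 & jx2 <= m - 2 & jy2 >= 0 & jy2 <= n - 2
  if (!any(ok)) return(out)
  ro <- jy2[ok] + 1; co <- jx2[ok] + 1
  v00 <- rv[cbind(ro, co)]
  v10 <- rv[cbind(ro + 1, co)]
  v01 <- rv[cbind(ro, co + 1)]
  v11 <- rv[cbind(ro + 1, co + 1)]
  wxo <- wx[ok]; wyo <- wy[ok]
  out[ok] <- (1 - wyo) * ((1 - wxo) * v00 + wxo * v01) +
    wyo * ((1 - wxo) * v10 + wxo * v11)
  out
}

#' @export
print.trfd_gamma <- function(x, ...) {
  cat(sprintf(
    "<trfd_gamma> %.1f%% pass (gamma <= 1) over %d pixels [%g%% / %g mm, %s]\n",
    100 * x$pass_rate, x$n_evaluated, 100 * x$criteria$value_frac,
    x$criteria$distance_mm, if (x$criteria$local) "local" else "global"))
  invisible(x)
}

#' @rdname local_gamma
#' @param result A `trfd_gamma`.
#' @return [pass_rate()] returns the fraction of evaluated pixels with
#'   gamma <= 1.
#' @export
pass_rate <- function(result) {
  if (result$n_evaluated < 1) stop_trfd("no evaluated pixels",
                                        "trfd_range_error")
  result$pass_rate
}

#' @export
glance.trfd_gamma <- function(x, ...) {
  tibble(pass_rate = x$pass_rate, n_evaluated = x$n_evaluated,
         value_frac = x$criteria$value_frac,
         distance_mm = x$criteria$distance_mm, local = x$criteria$local)
}

#' @export
autoplot.trfd_gamma <- function(object, ...) {
  autoplot(object$gamma, name = "gamma")
}
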