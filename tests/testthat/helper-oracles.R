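# Shared fixtures and independent oracles for the test suite.
# Oracles deliberately use naive formulations (explicit loops, direct
# definitions) so they stay independent of the package's optimized paths.

# a small map object on a regular grid
make_map <- function(values, spacing = 0.1, x0 = 0, y0 = 0) {
  structure(list(
    x = x0 + seq(0, by = spacing, length.out = ncol(values)),
    y = y0 + seq(0, by = spacing, length.out = nrow(values)),
    spacing = spacing, values = values, notes = character()),
    class = "fluence_map")
}

# smooth positive random field (for synthetic dose maps)
smooth_field <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(stats::rnorm(n * n), n)
  for (i in 1:3)
    v <- (v + rbind(v[-1, ], v[n, ]) + rbind(v[1, ], v[-n, ]) +
            cbind(v[, -1], v[, n]) + cbind(v[, 1], v[, -n])) / 5
  v
}

# Brute-force gamma oracle: per evaluated point, exhaustive search over
# the full dta/10-resampled reference (vectorized only along x), with
# the same 3*dta search radius the definition states.
gamma_oracle <- function(ev, ref, crit) {
  dta <- crit$dta / 10
  step <- min(dta / 10, 0.02)
  xf <- seq(ref$x[1], ref$x[length(ref$x)], by = step)
  yf <- seq(ref$y[1], ref$y[length(ref$y)], by = step)
  # naive bilinear resampling, row by row
  rv <- matrix(NA_real_, length(yf), length(xf))
  for (i in seq_along(yf)) {
    fy <- (yf[i] - ref$y[1]) / ref$spacing
    i0 <- pmin(floor(fy), length(ref$y) - 2)
    wy <- fy - i0
    for (j in seq_along(xf)) {
      fx <- (xf[j] - ref$x[1]) / ref$spacing
      j0 <- min(floor(fx), length(ref$x) - 2)
      wx <- fx - j0
      rv[i, j] <- (1 - wy) * ((1 - wx) * ref$values[i0 + 1, j0 + 1] +
                                wx * ref$values[i0 + 1, j0 + 2]) +
        wy * ((1 - wx) * ref$values[i0 + 2, j0 + 1] +
                wx * ref$values[i0 + 2, j0 + 2])
    }
  }
  mx <- max(ref$values)
  cut <- crit$threshold / 100 * mx
  pts <- expand.grid(y = ev$y, x = ev$x)
  d <- as.vector(ev$values)
  keep <- d >= cut
  pts <- pts[keep, ]
  d <- d[keep]
  r2max <- (3 * dta)^2
  out <- numeric(length(d))
  for (k in seq_along(d)) {
    best <- Inf
    for (i in seq_along(yf)) {
      dy2 <- (yf[i] - pts$y[k])^2
      if (dy2 > r2max + 1e-12) next
      dx2 <- (xf - pts$x[k])^2
      ok <- dy2 + dx2 <= r2max + 1e-12
      if (!any(ok)) next
      tol <- if (crit$normalization == "global")
        crit$dose_tolerance / 100 * mx
      else crit$dose_tolerance / 100 * rv[i, ok]
      g2 <- ((d[k] - rv[i, ok]) / tol)^2 + (dy2 + dx2[ok]) / dta^2
      best <- min(best, g2)
    }
    out[k] <- sqrt(best)
  }
  out
}

# Brute-force fine-time-step integration of a uniform sweeping gap:
# Riemann sum of static combined fluence maps at n_steps gap positions.
sweep_integral_oracle <- function(gap_cm, x0, params, mach, geom,
                                  c_lo, c_hi, n_steps = 400) {
  g <- fluence_grid(c(x0 - 2.2, x0 + 2.2), c(-3.5, 3.5), 0.1)
  acc <- NULL
  cs <- c_lo + (seq_len(n_steps) - 0.5) / n_steps * (c_hi - c_lo)
  for (cc in cs) {
    ap <- rect_field_aperture(mach, cc - gap_cm / 2, cc + gap_cm / 2,
                              -3, 3)
    f <- dual_layer_fluence(ap, params, mach, g)
    acc <- if (is.null(acc)) f$values / n_steps
      else acc + f$values / n_steps
  }
  fmap <- structure(list(x = g$x, y = g$y, spacing = g$spacing,
                         values = acc, notes = character()),
                    class = "fluence_map")
  d <- dose_plane(fmap, geom, mach)
  point_dose(d, c(x0 * geom$magnification, 0),
             detector = detector_kernel("farmer"))
}
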