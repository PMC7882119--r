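# Random modulated test plans (VMAT, sliding-window VMAT, sliding-window
# IMRT) with chamber points and cylindrical diode-array samples.

# smooth random series on [0,1], n samples, zero-ish mean, O(1) amplitude
.smooth_series <- function(n, k = 3) {
  t <- seq(0, 1, length.out = n)
  v <- rep(0, n)
  for (j in seq_len(k))
    v <- v + stats::rnorm(1, 0, 1 / j) *
      sin(2 * pi * (j * t + stats::runif(1)))
  v
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# per-layer leaf rows opened for a plan of half-extent hy
.plan_rows <- function(machine, hy) {
  lapply(stats::setNames(c("proximal", "distal"),
                         c("proximal", "distal")), function(lay) {
    rows <- layer_rows(machine, lay, c(-hy - 1, hy + 1))
    ctr <- (rows$y_lo + rows$y_hi) / 2
    rows[ctr > -hy & ctr < hy, , drop = FALSE]
  })
}

# build control points from per-layer position arrays
# xl, xr: list(proximal=, distal=) of [n_rows x n_cp] matrices
.cps_from_tracks <- function(rows, xl, xr, weights, angles) {
  n_cp <- length(weights)
  lapply(seq_len(n_cp), function(j) {
    aps <- lapply(stats::setNames(names(rows), names(rows)), function(lay) {
      a <- rows[[lay]]
      a$x_left <- xl[[lay]][, j]
      a$x_right <- xr[[lay]][, j]
      rownames(a) <- NULL
      a
    })
    control_point(aps, mu_weight = weights[j], gantry_angle = angles[j])
  })
}

.gen_one_plan <- function(machine, technique, hx, hy, total_mu, min_gap,
                          label) {
  rows <- .plan_rows(machine, hy)
  if (technique == "vmat") {
    n_cp <- 25
    angles <- seq(-180, 180, length.out = n_cp)
    weights <- c(0, stats::runif(n_cp - 1, 0.7, 1.3))
    tracks <- lapply(rows, function(rr) {
      nr <- nrow(rr)
      xl <- xr <- matrix(0, nr, n_cp)
      for (r in seq_len(nr)) {
        ctr <- .clamp(stats::rnorm(1, 0, 1) + 1.3 * .smooth_series(n_cp),
                      -hx + 1, hx - 1)
        gap <- .clamp(1.2 + 1.3 * .smooth_series(n_cp), min_gap + 0.2,
                      2 * hx)
        xl[r, ] <- .clamp(ctr - gap / 2, -hx, hx - min_gap)
        xr[r, ] <- .clamp(ctr + gap / 2, xl[r, ] + min_gap, hx)
      }
      list(xl = xl, xr = xr)
    })
  } else {
    # sliding-window: all leaves sweep the field in one direction
    per_beam <- if (technique == "dmlc") 7 else 25
    beams <- if (technique == "dmlc") seq(0, 320, by = 40) else 0
    n_cp <- per_beam * length(beams)
    angles <- if (technique == "dmlc") rep(beams, each = per_beam)
      else seq(-180, 180, length.out = n_cp)
    weights <- if (technique == "dmlc")
      as.vector(vapply(beams, function(b)
        c(0, stats::runif(per_beam - 1, 0.7, 1.3)),
        numeric(per_beam)))
      else c(0, stats::runif(n_cp - 1, 0.7, 1.3))
    tracks <- lapply(rows, function(rr) {
      nr <- nrow(rr)
      xl <- xr <- matrix(0, nr, n_cp)
      for (r in seq_len(nr)) {
        for (bi in seq_along(beams)) {
          j0 <- (bi - 1) * per_beam
          inc <- stats::runif(per_beam - 1, 0.3, 1)
          cum <- c(0, cumsum(inc) / sum(inc))
          lead <- -hx + 0.8 + (2 * hx - 0.8) * cum
          gap <- .clamp(1.2 + 1.1 * .smooth_series(per_beam),
                        min_gap + 0.3, 2.5)
          trail <- cummax(lead - gap)
          lead <- pmax(lead, trail + min_gap)
          xl[r, j0 + seq_len(per_beam)] <- .clamp(trail, -hx, hx)
          xr[r, j0 + seq_len(per_beam)] <- .clamp(lead, -hx, hx)
        }
      }
      list(xl = xl, xr = xr)
    })
  }
  cps <- .cps_from_tracks(rows,
                          lapply(tracks, `[[`, "xl"),
                          lapply(tracks, `[[`, "xr"),
                          weights, angles)
  mlc_plan(cps, total_mu = total_mu, label = label,
           arc = technique != "dmlc")
}

# diode positions of the virtual cylindrical array (radius r_cyl):
# a helical trace over the irradiated band, mapped to the measurement
# plane as (x = r sin(theta), y = z)
.array_points <- function(n_det, xmax, zmax, r_cyl = 10.5) {
  th_m <- asin(min(1, xmax / r_cyl))
  u <- ((seq_len(n_det) - 1) * 0.6180339887) %% 1
  arc <- rep(c(1, 2), length.out = n_det)
  theta <- ifelse(arc == 1, -th_m + 2 * th_m * u,
                  pi - th_m + 2 * th_m * u)
  z <- -zmax + 2 * zmax * ((seq_len(n_det) - 0.5) / n_det)
  data.frame(theta = theta, z = z, x = r_cyl * sin(theta), y = z)
}

#' Virtual modulated plan suite
#'
#' Generates seeded random modulated plans of one technique (traditional
#' VMAT, sliding-window VMAT, or sliding-window IMRT at nine equidistant
#' gantry angles), all respecting the machine's kinematic limits. For
#' each plan the suite carries: two chamber points - one at the isocenter
#' (high dose) and one in a lower-dose, low-gradient location whose
#' noise-free dose ratio to the isocenter lies in 0.4-0.8 - with noisy
#' "measured" doses, and samples of a cylindrical diode array at 10.5 cm
#' radius (581-1009 diodes over the irradiated band).
#'
#' @param gt a [ground_truth()].
#' @param n_plans number of plans.
#' @param technique `"vmat"`, `"sw_vmat"` or `"dmlc"`.
#' @param modulation MU per cGy of prescription (1.5-10).
#' @param prescription_cgy prescription dose, cGy (sets total MU =
#'   `modulation * prescription_cgy`).
#' @param spacing dose-grid spacing, cm.
#' @return A list of class `plan_suite`: `plans` (list of [mlc_plan()]),
#'   `chambers` (data frame: `plan`, `role`, `x`, `y`, `dose_true`,
#'   `dose`), `arrays` (list of data frames with diode coordinates and
#'   doses), plus `technique`, `modulation`.
#' @export
gen_plan_suite <- function(gt, n_plans = 5,
                           technique = c("vmat", "sw_vmat", "dmlc"),
                           modulation = 6, prescription_cgy = 200,
                           spacing = 0.1) {
  technique <- match.arg(technique)
  stopifnot(inherits(gt, "ground_truth"))
  if (modulation < 1.5 || modulation > 10)
    stop("modulation target must lie in [1.5, 10] MU/cGy")
  geom <- beam_geometry(90, 10, gt$machine)
  total_mu <- modulation * prescription_cgy
  seed <- .session_seed(gt, paste0("plans-", technique),
                        c(n_plans, modulation))
  res <- .with_seed(seed, {
    plans <- list(); chambers <- list(); arrays <- list()
    for (i in seq_len(n_plans)) {
      ok <- FALSE
      for (try in 1:20) {
        hx <- stats::runif(1, 3.5, 4.5)
        hy <- stats::runif(1, 3.5, 4.5)
        label <- sprintf("%s-%02d", technique, i)
        pl <- .gen_one_plan(gt$machine, technique, hx, hy, total_mu,
                            gt$true_params$dynamic_min_gap, label)
        v <- validate_aperture(pl, gt$machine, gt$true_params)
        if (!v$valid) next
        dm <- .plan_dose_map(pl, gt$true_params, gt$machine, geom,
                             spacing = spacing)
        d_high <- point_dose(dm, c(0, 0))
        ratio <- dm$values / d_high
        gx <- t(apply(ratio, 1, function(r) c(0, diff(r))))
        gy <- apply(ratio, 2, function(r) c(0, diff(r)))
        grad <- sqrt(gx^2 + gy^2)
        xs <- matrix(dm$x, nrow = length(dm$y), ncol = length(dm$x),
                     byrow = TRUE)
        ys <- matrix(dm$y, nrow = length(dm$y), ncol = length(dm$x))
        cand <- which(ratio > 0.42 & ratio < 0.78 &
                        abs(xs) < 6 & abs(ys) < 6 & grad < 0.02)
        if (!length(cand))
          cand <- which(ratio > 0.4 & ratio < 0.8 &
                          abs(xs) < 6 & abs(ys) < 6 & grad < 0.05)
        if (!length(cand)) next
        target <- stats::runif(1, 0.45, 0.75)
        j <- cand[which.min(abs(ratio[cand] - target))]
        p_low <- c(xs[j], ys[j])
        d_low <- point_dose(dm, p_low)
        if (d_low / d_high < 0.4 || d_low / d_high > 0.8) next
        nf <- .noise_factors(2, gt$noise_sd)
        chambers[[length(chambers) + 1]] <- data.frame(
          plan = label, role = c("high", "low"),
          x = c(0, p_low[1]), y = c(0, p_low[2]),
          dose_true = c(d_high, d_low),
          dose = c(d_high, d_low) * nf)
        n_det <- sample(581:1009, 1)
        pts <- .array_points(n_det, xmax = hx + 0.6, zmax = hy + 0.6)
        pts$dose_true <- .interp_map(dm, pts$x, pts$y)
        pts$dose <- pts$dose_true *
          .noise_factors(nrow(pts), gt$noise_sd)
        pts$plan <- label
        arrays[[length(arrays) + 1]] <- pts
        plans[[length(plans) + 1]] <- pl
        ok <- TRUE
        break
      }
      if (!ok)
        stop(sprintf(
          paste0("could not generate a deliverable %s plan at ",
                 "%.1f MU/cGy within kinematic limits"),
          technique, modulation))
    }
    list(plans = plans,
         chambers = do.call(rbind, chambers),
         arrays = arrays)
  })
  structure(c(res, list(technique = technique, modulation = modulation,
                        spacing = spacing)),
            class = "plan_suite", seed = seed)
}

#' @export
print.plan_suite <- function(x, ...) {
  cat(sprintf("plan suite: %d %s plan(s), %.1f MU/cGy, %d chamber points\n",
              length(x$plans), x$technique, x$modulation,
              nrow(x$chambers)))
  invisible(x)
}
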