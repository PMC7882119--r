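#' Hidden ground-truth machine for the virtual laboratory
#'
#' Bundles the true (to-be-recovered) MLC parameters, the machine
#' geometry, the detector noise level and the master seed. All virtual
#' measurement sessions are pure functions of this object and their
#' arguments: the same seed reproduces every reading bit-identically.
#'
#' The default truth mirrors a commissioned dual-layer MLC: leaf-end
#' offset +0.007 cm, no gain or curvature, flat tip (tip width 0),
#' per-layer transmission 0.47%, tongue-and-groove width 0.05 cm.
#'
#' @param true_params an [mlc_parameters()] object (the hidden truth).
#' @param machine an [machine()] object.
#' @param noise_sd multiplicative lognormal noise sd (fraction; 0.005 =
#'   0.5% chamber repeatability). Set 0 for noise-free sessions.
#' @param seed integer master seed.
#' @return An object of class `ground_truth`.
#' @export
ground_truth <- function(true_params = mlc_parameters(offset = 0.007),
                         machine = dualmlc::machine(),
                         noise_sd = 0.005, seed = 1L) {
  stopifnot(noise_sd >= 0)
  structure(list(true_params = true_params, machine = machine,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "ground_truth")
}

# run code under a local, derived RNG seed; global RNG state is restored
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (has) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# derived session seed: stable small-integer function of the master seed,
# a session tag, and the numeric arguments
.session_seed <- function(gt, tag, args = numeric(0)) {
  t <- sum(utf8ToInt(tag)) %% 997L
  a <- if (length(args)) sum(abs(round(args * 1000))) %% 99991 else 0
  as.integer((as.numeric(gt$seed) * 48271 + t * 131 + a) %% 2147483587)
}

# one multiplicative lognormal noise factor per reading
.noise_factors <- function(n, sd) {
  if (sd <= 0) rep(1, n) else exp(stats::rnorm(n, 0, sd))
}

# dose map of a plan under given model parameters
.plan_dose_map <- function(plan, params, machine, geom,
                           grid = NULL, spacing = 0.1) {
  g <- if (is.null(grid)) default_grid(plan, spacing = spacing) else grid
  f <- accumulate_dynamic_fluence(plan, params, machine, g)
  dose_plane(f, geom, machine)
}

# single sweeping-gap delivery reading: a gap of width gap_cm traverses
# a window of +/- sweep_half around x0 at uniform speed; Farmer chamber
# (2.3 cm line average) at (x0, 0), 10 cm depth / 90 cm SSD by default.
# The window is clamped into the deliverable leaf-travel range
# (independently of the gap, using the protocol's largest 2 cm gap), so
# very off-axis positions see a truncated passage for large gaps - as a
# real chamber near the maximum field edge would.
#
# A uniform sweep is the box average of the static-gap dose over the
# travel window, so the reading is computed from one static dose map:
# reading = (1/L) * int_{c_lo}^{c_hi} P(x0 - c) dc, with P the
# Farmer-line-averaged dose profile of the gap parked at 0 (constant at
# the stacked-leakage level far from the gap). This matches the
# control-point accumulation of the same delivery (see the tests) at a
# fraction of the cost.
.sweep_reading <- function(gap_cm, x0, params, machine, geom,
                           sweep_half = 5, y_half = 3, spacing = 0.1) {
  xmax <- machine$max_field / 2
  c_lo <- max(x0 - sweep_half, -xmax + 1.05)
  c_hi <- min(x0 + sweep_half, xmax - 1.05)
  if (c_hi <= c_lo)
    stop("sweep window is empty within the leaf travel range")
  m <- geom$magnification
  half_extent <- gap_cm / 2 + 2.5
  g <- fluence_grid(c(-half_extent, half_extent),
                    c(-y_half - 0.5, y_half + 0.5), spacing)
  ap <- rect_field_aperture(machine, -gap_cm / 2, gap_cm / 2,
                            -y_half, y_half)
  d <- dose_plane(dual_layer_fluence(ap, params, machine, g),
                  geom, machine)
  # Farmer line average (2.3 cm in Y) per x column: pixel rows covering
  # |y| <= 1.15 average the box exactly on an aligned 0.1 cm grid
  rows <- which(abs(d$y) <= 1.15 * m + 1e-9)
  P <- colMeans(d$values[rows, , drop = FALSE])
  leak <- pdd(geom$depth, machine) *
    params$layer_transmission[["proximal"]] *
    params$layer_transmission[["distal"]]
  # integrate P over v = (x0 - c) * m for c in [c_lo, c_hi]
  v_lo <- (x0 - c_hi) * m
  v_hi <- (x0 - c_lo) * m
  xs <- d$x
  h <- xs[2] - xs[1]
  cum <- c(0, cumsum((P[-1] + P[-length(P)]) / 2 * h))
  cum_at <- function(v) {
    v <- pmin(pmax(v, xs[1]), xs[length(xs)])
    stats::approx(xs, cum, v)$y
  }
  inner_lo <- max(v_lo, xs[1])
  inner_hi <- min(v_hi, xs[length(xs)])
  inner <- if (inner_hi > inner_lo) cum_at(inner_hi) - cum_at(inner_lo)
    else 0
  outer_len <- (v_hi - v_lo) - max(0, inner_hi - inner_lo)
  (inner + leak * outer_len) / ((c_hi - c_lo) * m)
}

# static 10 x 10 reference reading (cross-calibration field)
.reference_reading <- function(params, machine, geom, spacing = 0.1) {
  ap <- rect_field_aperture(machine, -5, 5, -5, 5)
  g <- fluence_grid(c(-2, 2), c(-3.8, 3.8), spacing)
  f <- dual_layer_fluence(ap, params, machine, g)
  d <- dose_plane(f, geom, machine)
  point_dose(d, c(0, 0), detector = detector_kernel("farmer"))
}

# closed-field (both layers blocked) leakage reading at x0
.leakage_reading <- function(params, machine, geom) {
  tr <- params$layer_transmission
  pdd(geom$depth, machine) * tr[["proximal"]] * tr[["distal"]]
}

#' Virtual sweeping-gap ion-chamber session
#'
#' Emulates the dosimetric-leaf-gap measurement: MLC-defined gaps of
#' 2-20 mm sweep a 10 cm window around each off-axis position at uniform
#' speed; a Farmer chamber at 10 cm depth / 90 cm SSD integrates the
#' delivery. Each position also gets a closed-field leakage record and
#' the session carries one static 10 x 10 cm^2 cross-calibration record.
#' Readings are multiplied by lognormal noise of sd `gt$noise_sd`.
#'
#' @param gt a [ground_truth()].
#' @param gaps_mm gap widths, mm (2-20).
#' @param positions_cm chamber off-axis positions along X, cm.
#' @return A `measurement_set` data frame with columns `kind`
#'   (`"sweep"`, `"leakage"`, `"reference"`), `gap_mm`, `position_cm`,
#'   `depth_cm`, `ssd_cm`, `detector`, `leakage`, `reading`.
#' @export
gen_sweep_session <- function(gt, gaps_mm = c(2, 4, 6, 10, 14, 16, 20),
                              positions_cm = c(0, -3, 3, 5, 10, 12, 13)) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(gaps_mm < 2 - 1e-9) || any(gaps_mm > 20 + 1e-9))
    stop("gaps must lie within 2-20 mm")
  if (any(gaps_mm / 10 < gt$true_params$dynamic_min_gap - 1e-9))
    stop(sprintf(
      "gap below the dynamic minimum of %.2f cm: undeliverable",
      gt$true_params$dynamic_min_gap))
  geom <- beam_geometry(90, 10, gt$machine)
  rows <- list()
  for (x0 in positions_cm) {
    for (g_mm in gaps_mm)
      rows[[length(rows) + 1]] <- data.frame(
        kind = "sweep", gap_mm = g_mm, position_cm = x0, depth_cm = 10,
        ssd_cm = 90, detector = "farmer", leakage = FALSE,
        reading = .sweep_reading(g_mm / 10, x0, gt$true_params,
                                 gt$machine, geom))
    rows[[length(rows) + 1]] <- data.frame(
      kind = "leakage", gap_mm = 0, position_cm = x0, depth_cm = 10,
      ssd_cm = 90, detector = "farmer", leakage = TRUE,
      reading = .leakage_reading(gt$true_params, gt$machine, geom))
  }
  rows[[length(rows) + 1]] <- data.frame(
    kind = "reference", gap_mm = NA_real_, position_cm = 0, depth_cm = 10,
    ssd_cm = 90, detector = "farmer", leakage = FALSE,
    reading = .reference_reading(gt$true_params, gt$machine, geom))
  out <- do.call(rbind, rows)
  seed <- .session_seed(gt, "sweep", c(gaps_mm, positions_cm))
  out$reading <- out$reading *
    .with_seed(seed, .noise_factors(nrow(out), gt$noise_sd))
  class(out) <- c("measurement_set", class(out))
  attr(out, "seed") <- seed
  out
}

# apply a detector kernel (1D Gaussian) and per-point noise to a profile
.scan_profile <- function(map, axis, at, sigma, noise_sd) {
  p <- extract_profile(map, axis, at)
  if (sigma > 0)
    p$values <- as.vector(.blur_1d(matrix(p$values, ncol = 1), sigma,
                                   p$positions[2] - p$positions[1]))
  if (noise_sd > 0)
    p$values <- p$values * exp(stats::rnorm(length(p$values), 0, noise_sd))
  p
}

#' Virtual abutting-field session
#'
#' Two abutting 2 x 4 cm^2 (X x Y) fields, each formed by both layers,
#' are scanned separately in X through the field center with the Edge
#' diode (0.08 cm Gaussian response) at 10 cm depth. Each profile is
#' normalized to the center of its own opening; the per-junction result
#' is the sum of the two normalized profiles, averaged over `n_runs`
#' noisy runs. A leaf-end offset error shows up as a peak (overlap) or
#' dip (gap) at the junction.
#'
#' @param gt a [ground_truth()].
#' @param junctions junction X positions, cm (within +/-10).
#' @param n_runs number of averaged scan runs.
#' @param spacing calculation grid spacing, cm.
#' @return A list (class `abutting_session`) with one element per
#'   junction: `junction`, [profile1d()]s `field_a`, `field_b`, `sum`.
#' @export
gen_abutting_session <- function(gt, junctions = c(0, -10, 10),
                                 n_runs = 3, spacing = 0.05) {
  stopifnot(inherits(gt, "ground_truth"))
  if (any(abs(junctions) > 10))
    stop("junctions must lie within +/-10 cm")
  geom <- beam_geometry(90, 10, gt$machine)
  m <- geom$magnification
  seed <- .session_seed(gt, "abutting", c(junctions, n_runs))
  out <- .with_seed(seed, lapply(junctions, function(xj) {
    g <- fluence_grid(c(xj - 4, xj + 4), c(-4, 4), spacing)
    maps <- lapply(list(c(xj - 2, xj), c(xj, xj + 2)), function(b) {
      ap <- rect_field_aperture(gt$machine, b[1], b[2], -2, 2)
      dose_plane(dual_layer_fluence(ap, gt$true_params, gt$machine, g),
                 geom, gt$machine)
    })
    centers <- c(xj - 1, xj + 1) * m
    runs <- lapply(seq_len(n_runs), function(r) {
      ps <- lapply(1:2, function(k) {
        p <- .scan_profile(maps[[k]], "x", 0, 0.08, gt$noise_sd)
        p$values <- p$values / stats::approx(p$positions, p$values,
                                             centers[k])$y
        p
      })
      ps[[1]]$values + ps[[2]]$values
    })
    avg <- Reduce(`+`, runs) / n_runs
    pa <- extract_profile(maps[[1]], "x", 0)
    pb <- extract_profile(maps[[2]], "x", 0)
    pa$meta <- pb$meta <- list(depth = 10, ssd = 90)
    list(junction = xj, field_a = pa, field_b = pb,
         sum = profile1d(pa$positions, avg, axis = "x",
                         meta = list(depth = 10, ssd = 90, runs = n_runs)))
  }))
  structure(out, class = "abutting_session", seed = seed)
}

# bar-pattern apertures for one layer: alternate open/blocked rows
.bar_apertures <- function(machine, layer, y_half = 4, x_half = 4) {
  rows <- layer_rows(machine, layer, c(-y_half, y_half))
  ctr <- (rows$y_lo + rows$y_hi) / 2
  rows <- rows[ctr > -y_half & ctr < y_half, , drop = FALSE]
  parity <- (floor(rows$y_lo / machine$physical_leaf_width + 1e-6) %% 2 == 0)
  mk <- function(keep) {
    a <- rows[keep, , drop = FALSE]
    a$x_left <- rep(-x_half, nrow(a)); a$x_right <- rep(x_half, nrow(a))
    rownames(a) <- NULL
    a
  }
  list(a = mk(parity), b = mk(!parity))
}

#' Virtual complementary bar-pattern session
#'
#' For one layer, two complementary bar patterns (open leaves of one
#' replacing the closed leaves of the other) are scanned with the Edge
#' diode in the Y (in-plane) direction through the central axis. The sum
#' of the two scans is uniform except for tongue-and-groove dips at leaf
#' borders; the other layer is fully open.
#'
#' @param gt a [ground_truth()].
#' @param layer `"proximal"` or `"distal"`.
#' @param spacing calculation grid spacing, cm.
#' @return A list (class `bar_session`): `layer`, [profile1d()]s
#'   `pattern_a`, `pattern_b`, `sum`.
#' @export
gen_bar_session <- function(gt, layer = c("proximal", "distal"),
                            spacing = 0.05) {
  layer <- match.arg(layer)
  stopifnot(inherits(gt, "ground_truth"))
  geom <- beam_geometry(90, 10, gt$machine)
  bars <- .bar_apertures(gt$machine, layer)
  open_other <- rect_field_aperture(gt$machine, -4.5, 4.5, -4.7, 4.7)
  other <- setdiff(c("proximal", "distal"), layer)
  g <- fluence_grid(c(-1.5, 1.5), c(-5, 5), spacing)
  seed <- .session_seed(gt, paste0("bars-", layer))
  profs <- .with_seed(seed, lapply(bars, function(bar) {
    aps <- stats::setNames(list(bar, open_other[[other]]), c(layer, other))
    d <- dose_plane(dual_layer_fluence(aps, gt$true_params, gt$machine, g),
                    geom, gt$machine)
    .scan_profile(d, "y", 0, 0.08, gt$noise_sd)
  }))
  structure(list(layer = layer, pattern_a = profs$a, pattern_b = profs$b,
                 sum = profile1d(profs$a$positions,
                                 profs$a$values + profs$b$values,
                                 axis = "y",
                                 meta = list(depth = 10, ssd = 90))),
            class = "bar_session", seed = seed)
}

#' Virtual static field-edge session
#'
#' Narrow strip fields (width `width`, 4 cm long in Y) centered at the
#' given off-axis positions, each scanned in X with the Edge diode. The
#' commissioning pipeline extracts both field edges by the
#' inflection-point rule and forms midpoint-shift and dosimetric-offset
#' observations versus off-axis position.
#'
#' @param gt a [ground_truth()].
#' @param centers strip centers, cm.
#' @param width strip width, cm.
#' @param spacing grid spacing, cm.
#' @return A list (class `edge_session`) of elements `x_nom`, `width`,
#'   `profile`.
#' @export
gen_edge_session <- function(gt,
                             centers = c(-13, -10, -5, -3, 0, 3, 5, 10, 12, 13),
                             width = 1, spacing = 0.05) {
  stopifnot(inherits(gt, "ground_truth"))
  geom <- beam_geometry(90, 10, gt$machine)
  seed <- .session_seed(gt, "edges", c(centers, width))
  out <- .with_seed(seed, lapply(centers, function(x0) {
    g <- fluence_grid(c(x0 - width / 2 - 1.5, x0 + width / 2 + 1.5),
                      c(-1.5, 1.5), spacing)
    ap <- rect_field_aperture(gt$machine, x0 - width / 2, x0 + width / 2,
                              -2, 2)
    d <- dose_plane(dual_layer_fluence(ap, gt$true_params, gt$machine, g),
                    geom, gt$machine)
    list(x_nom = x0, width = width,
         profile = .scan_profile(d, "x", 0, 0.08, gt$noise_sd))
  }))
  structure(out, class = "edge_session", seed = seed)
}

#' Distilled midpoint-shift observations
#'
#' Generates `(x_nom, midpoint shift)` pairs at the measurement level:
#' the true midpoint shift `gain * x_nom` plus Gaussian positional noise
#' of sd `position_sd` (scan positioning repeatability). Used for
#' replicate studies of the gain decision rule, where re-simulating full
#' profiles per replicate adds nothing.
#'
#' @param gt a [ground_truth()].
#' @param x_noms nominal positions, cm.
#' @param position_sd positional noise sd, cm (default 0.005 = 0.05 mm).
#' @param rep_id integer replicate tag entering the derived seed.
#' @return Data frame with `x_nom`, `dxmp`.
#' @export
gen_midpoint_pairs <- function(gt,
                               x_noms = c(-13, -10, -5, -3, 0, 3, 5, 10, 12, 13),
                               position_sd = 0.005, rep_id = 0) {
  seed <- .session_seed(gt, "midpoints", c(x_noms, position_sd, rep_id))
  dxmp <- midpoint_shift(x_noms, gt$true_params) +
    .with_seed(seed, stats::rnorm(length(x_noms), 0, position_sd))
  data.frame(x_nom = x_noms, dxmp = dxmp)
}
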