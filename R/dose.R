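#' Beam geometry for a planar dose calculation
#'
#' @param ssd source-surface distance, cm.
#' @param depth measurement depth, cm.
#' @param machine an [machine()] object (supplies the SAD).
#' @return An object of class `beam_geometry` with the plane
#'   magnification `(ssd + depth) / sad`.
#' @export
beam_geometry <- function(ssd = 90, depth = 10, machine = machine()) {
  stopifnot(ssd > 0, depth >= 0)
  structure(list(ssd = ssd, depth = depth, sad = machine$sad,
                 magnification = (ssd + depth) / machine$sad),
            class = "beam_geometry")
}

#' Percentage depth dose of the simplified engine
#'
#' Linear buildup from the surface to `d_max`, exponential attenuation
#' beyond, with the attenuation coefficient fixed so that
#' `pdd(10) = 0.63` for the reference 10 x 10 field. The engine's role is
#' relative dosimetry; the depth-dose shape is configuration, not a
#' physics claim.
#'
#' @param depth depth(s), cm.
#' @param machine an [machine()] object.
#' @return Relative dose factor(s), `pdd(d_max) = 1`.
#' @export
pdd <- function(depth, machine = machine()) {
  dm <- machine$d_max
  mu <- -log(0.63) / (10 - dm)
  ifelse(depth <= dm, depth / dm, exp(-mu * (depth - dm)))
}

#' Relative output factor lookup
#'
#' Mild monotone dependence of output on equivalent-square field size,
#' normalized to 1 at a 10 cm equivalent square. Configurable by
#' supplying a different table to the fit routines; the default is a
#' generic small-field rolloff.
#'
#' @param eq_square equivalent square side(s), cm.
#' @return Relative output factor(s).
#' @export
output_factor <- function(eq_square) {
  f <- function(s) 1 - 0.12 * exp(-s / 3.5)
  f(eq_square) / f(10)
}

# sigma of the source penumbra projected to the isocenter plane; the MLC
# sits (effectively) midway between the two layer planes.
.iso_sigma <- function(machine) {
  d_mlc <- (machine$layer_distance_proximal +
              machine$layer_distance_distal) / 2
  proj <- (machine$sad - d_mlc) / d_mlc
  c(x = machine$source_sigma_x * proj, y = machine$source_sigma_y * proj)
}

# separable Gaussian blur with truncated-kernel renormalization (uniform
# maps are preserved exactly, interior integrals conserved).
.blur_1d <- function(mat, sigma, h, margin = 4) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(margin * sigma / h))
  k <- stats::dnorm((-r:r) * h, sd = sigma)
  k <- k / sum(k)
  n <- nrow(mat)
  pad <- matrix(0, nrow = r, ncol = ncol(mat))
  padded <- rbind(pad, mat, pad)
  filt <- stats::filter(padded, k, sides = 2)
  ones <- stats::filter(rbind(pad, matrix(1, n, ncol(mat)), pad), k,
                        sides = 2)
  out <- as.matrix(filt[(r + 1):(r + n), , drop = FALSE]) /
    as.matrix(ones[(r + 1):(r + n), , drop = FALSE])
  dimnames(out) <- NULL
  out
}

#' Source-size blur of a fluence map
#'
#' Anisotropic Gaussian convolution modeling the finite primary source.
#' The source sigmas are scaled by the source-to-MLC / MLC-to-isocenter
#' projection (the MLC is taken at the midpoint of the two layer planes).
#'
#' @param f a `fluence_map`.
#' @param machine an [machine()] object.
#' @return A blurred `fluence_map`.
#' @export
source_blur <- function(f, machine) {
  sig <- .iso_sigma(machine)
  notes <- f$notes
  if (min(sig) < f$spacing)
    notes <- union(notes, sprintf(
      "blur sigma %.3g cm below grid spacing %.3g cm", min(sig), f$spacing))
  v <- .blur_1d(f$values, sig[["y"]], f$spacing)        # along y (rows)
  v <- t(.blur_1d(t(v), sig[["x"]], f$spacing))         # along x (cols)
  .new_fluence_map(list(x = f$x, y = f$y, spacing = f$spacing), v, notes)
}

#' Planar dose from a fluence map
#'
#' Relative dose at depth: the source-blurred fluence, magnified to the
#' measurement plane, times the depth-dose factor (and, optionally, a
#' relative output factor for the field's equivalent square).
#'
#' @param f a `fluence_map` at the isocenter plane.
#' @param geom a [beam_geometry()].
#' @param machine an [machine()] object.
#' @param equiv_square optional equivalent square, cm, for the output
#'   factor; `NULL` for none.
#' @return A `dose_map` (shares the `fluence_map` structure; coordinates
#'   are in the measurement plane).
#' @export
dose_plane <- function(f, geom, machine, equiv_square = NULL) {
  b <- source_blur(f, machine)
  m <- geom$magnification
  of <- if (is.null(equiv_square)) 1 else output_factor(equiv_square)
  out <- .new_fluence_map(
    list(x = b$x * m, y = b$y * m, spacing = b$spacing * m),
    pdd(geom$depth, machine) * of * b$values, b$notes)
  class(out) <- c("dose_map", class(out))
  out
}

# bilinear interpolation on a map; points outside the grid are an error
.interp_map <- function(map, xq, yq) {
  x <- map$x; y <- map$y
  if (any(xq < x[1] - 1e-9) || any(xq > x[length(x)] + 1e-9) ||
      any(yq < y[1] - 1e-9) || any(yq > y[length(y)] + 1e-9))
    stop("point outside the dose grid")
  h <- map$spacing
  ix <- pmin(pmax(1L, findInterval(xq, x)), length(x) - 1L)
  iy <- pmin(pmax(1L, findInterval(yq, y)), length(y) - 1L)
  fx <- pmin(pmax((xq - x[ix]) / (x[ix + 1] - x[ix]), 0), 1)
  fy <- pmin(pmax((yq - y[iy]) / (y[iy + 1] - y[iy]), 0), 1)
  v00 <- map$values[cbind(iy, ix)]
  v01 <- map$values[cbind(iy, ix + 1L)]
  v10 <- map$values[cbind(iy + 1L, ix)]
  v11 <- map$values[cbind(iy + 1L, ix + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Detector response kernels
#'
#' Named averaging kernels for the virtual detectors: the Edge diode is a
#' 0.08 cm Gaussian, the CC13 chamber a 0.6 cm Gaussian, and the Farmer
#' chamber a 2.3 cm line average along its (in-plane, Y) axis.
#'
#' @param name `"point"`, `"edge"`, `"cc13"` or `"farmer"`.
#' @return A list describing the kernel.
#' @export
detector_kernel <- function(name = c("point", "edge", "cc13", "farmer")) {
  name <- match.arg(name)
  switch(name,
         point = list(type = "point", name = name),
         edge = list(type = "gaussian", sigma = 0.08, name = name),
         cc13 = list(type = "gaussian", sigma = 0.6, name = name),
         farmer = list(type = "line", length = 2.3, axis = "y",
                       name = name))
}

#' Point dose with optional detector averaging
#'
#' Bilinear interpolation of a planar dose at a point. If `x` is a plan,
#' the dose plane is computed first via [accumulate_dynamic_fluence()]
#' and [dose_plane()]. A detector kernel averages the dose over the
#' detector's sensitive extent.
#'
#' @param x a `dose_map` (or `fluence_map`) or an [mlc_plan()].
#' @param point `c(x, y)` in the map's plane, cm.
#' @param geom a [beam_geometry()] (used when `x` is a plan).
#' @param machine an [machine()] object.
#' @param params an [mlc_parameters()] object (used when `x` is a plan).
#' @param detector a [detector_kernel()] or `NULL` for a point sample.
#' @param grid optional [fluence_grid()] when `x` is a plan.
#' @return Dose value at the point.
#' @export
point_dose <- function(x, point, geom = beam_geometry(), machine = NULL,
                       params = NULL, detector = NULL, grid = NULL) {
  map <- if (inherits(x, "mlc_plan")) {
    stopifnot(!is.null(machine), !is.null(params))
    g <- if (is.null(grid)) default_grid(x) else grid
    f <- accumulate_dynamic_fluence(x, params, machine, g)
    dose_plane(f, geom, machine)
  } else x
  if (is.null(detector) || detector$type == "point")
    return(.interp_map(map, point[1], point[2]))
  h <- map$spacing
  if (detector$type == "gaussian") {
    r <- ceiling(3 * detector$sigma / h)
    off <- (-r:r) * h
    w <- stats::dnorm(off, sd = detector$sigma)
    w2 <- outer(w, w); w2 <- w2 / sum(w2)
    xs <- outer(rep(point[1], length(off)), off, "+")
    ys <- outer(off, rep(point[2], length(off)), "+")
    return(sum(w2 * matrix(.interp_map(map, as.vector(xs), as.vector(ys)),
                           nrow = length(off))))
  }
  if (detector$type == "line") {
    n <- max(11L, 2L * ceiling(detector$length / (2 * h)) + 1L)
    off <- seq(-detector$length / 2, detector$length / 2, length.out = n)
    if (detector$axis == "y")
      return(mean(.interp_map(map, rep(point[1], n), point[2] + off)))
    return(mean(.interp_map(map, point[1] + off, rep(point[2], n))))
  }
  stop("unknown detector kernel type")
}

#' One-dimensional profile
#'
#' @param positions strictly increasing coordinates, cm.
#' @param values relative dose values.
#' @param axis `"x"`, `"y"` or `"diagonal"`.
#' @param meta named list of setup metadata (depth, ssd, ...).
#' @return An object of class `profile1d`.
#' @export
profile1d <- function(positions, values, axis = "x", meta = list()) {
  stopifnot(length(positions) == length(values),
            all(diff(positions) > 0))
  structure(list(positions = positions, values = values, axis = axis,
                 meta = meta), class = "profile1d")
}

#' Extract a profile from a map
#'
#' @param map a `fluence_map` or `dose_map`.
#' @param axis `"x"` (varying x at fixed y) or `"y"`.
#' @param at fixed coordinate of the other axis, cm.
#' @return A [profile1d()].
#' @export
extract_profile <- function(map, axis = c("x", "y"), at = 0) {
  axis <- match.arg(axis)
  if (axis == "x")
    profile1d(map$x, .interp_map(map, map$x, rep(at, length(map$x))),
              axis = "x")
  else
    profile1d(map$y, .interp_map(map, rep(at, length(map$y)), map$y),
              axis = "y")
}

#' Field edge by the inflection-point rule
#'
#' For an FFF beam the field edge is the inflection point of the penumbra:
#' the extremum of the first derivative of the profile. The derivative is
#' estimated by centered differences and the extremum refined by quadratic
#' interpolation of the three points around the peak. An error is raised
#' when no interior extremum exists or several grid points tie (e.g., a
#' linear ramp).
#'
#' @param p a [profile1d()].
#' @param window optional `c(lo, hi)` search window, cm.
#' @return Edge position, cm.
#' @export
field_edge_inflection <- function(p, window = NULL) {
  pos <- p$positions; val <- p$values
  if (!is.null(window)) {
    keep <- pos >= window[1] & pos <= window[2]
    if (sum(keep) < 5) stop("search window contains fewer than 5 samples")
    pos <- pos[keep]; val <- val[keep]
  }
  n <- length(pos)
  d <- (val[3:n] - val[1:(n - 2)]) / (pos[3:n] - pos[1:(n - 2)])
  dp <- pos[2:(n - 1)]
  ad <- abs(d)
  mx <- max(ad)
  if (mx == 0) stop("profile is flat: no penumbra in window")
  ties <- which(ad > mx * (1 - 1e-9))
  if (length(ties) > 1 && any(diff(ties) > 1))
    stop("ambiguous penumbra: multiple equal derivative extrema")
  if (length(ties) > 2)
    stop("ambiguous penumbra: derivative is constant over a region")
  k <- ties[1]
  if (k == 1 || k == length(d))
    stop("derivative extremum at the window boundary; widen the window")
  den <- d[k - 1] - 2 * d[k] + d[k + 1]
  if (abs(den) < mx * 1e-12)
    stop("ambiguous penumbra: derivative extremum is degenerate")
  delta <- (d[k - 1] - d[k + 1]) / (2 * den)
  dp[k] + delta * (dp[k + 1] - dp[k])
}

#' Write or read a profile CSV
#'
#' Comma-separated `position,value` rows with a '#' metadata header
#' (axis, depth, ssd).
#'
#' @param p a [profile1d()].
#' @param path file path.
#' @return `read_profile_csv()` returns a [profile1d()].
#' @export
write_profile_csv <- function(p, path) {
  con <- file(path, "w")
  on.exit(close(con))
  meta <- c(list(axis = p$axis), p$meta)
  writeLines(.meta_line("dualmlc-profile-v1", meta), con)
  utils::write.csv(data.frame(position = p$positions, value = p$values),
                   con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# dualmlc-profile-v1", hdr))
    stop("not a dualmlc profile file: ", path)
  meta <- .parse_meta(hdr)
  axis <- meta$axis
  meta$axis <- NULL
  df <- utils::read.csv(path, skip = 1)
  profile1d(df$position, df$value, axis = axis, meta = meta)
}
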