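#' Fluence grid specification
#'
#' Regular pixel grid in the isocenter plane. `x` and `y` are pixel-center
#' coordinates; pixel values are area averages over the pixel, so sub-grid
#' leaf motion changes the map continuously.
#'
#' @param xlim,ylim extents, cm (pixel centers span these limits).
#' @param spacing pixel size, cm (default 0.1).
#' @return An object of class `fluence_grid`.
#' @export
fluence_grid <- function(xlim, ylim, spacing = 0.1) {
  stopifnot(spacing > 0, xlim[1] < xlim[2], ylim[1] < ylim[2])
  structure(list(
    x = seq(xlim[1], xlim[2], by = spacing),
    y = seq(ylim[1], ylim[2], by = spacing),
    spacing = spacing
  ), class = "fluence_grid")
}

#' Default grid for a set of apertures
#'
#' Bounding box of all open leaf pairs in the control point(s) plus a
#' margin.
#'
#' @param x a `control_point`, `mlc_plan`, or aperture list.
#' @param spacing pixel size, cm.
#' @param margin margin beyond the aperture bounding box, cm (>= 2).
#' @return A [fluence_grid()].
#' @export
default_grid <- function(x, spacing = 0.1, margin = 2) {
  aps <- if (inherits(x, "mlc_plan"))
    lapply(x$control_points, function(cp) cp$apertures)
  else if (inherits(x, "control_point")) list(x$apertures)
  else list(x)
  xs <- ys <- c()
  for (ap in aps) for (lay in c("proximal", "distal")) {
    a <- ap[[lay]]
    if (nrow(a)) {
      xs <- c(xs, a$x_left, a$x_right)
      ys <- c(ys, a$y_lo, a$y_hi)
    }
  }
  if (!length(xs)) stop("no open apertures to derive a grid from")
  fluence_grid(c(min(xs) - margin, max(xs) + margin),
               c(min(ys) - margin, max(ys) + margin), spacing)
}

.new_fluence_map <- function(grid, values, notes = character()) {
  structure(list(x = grid$x, y = grid$y, spacing = grid$spacing,
                 values = values, notes = notes),
            class = "fluence_map")
}

#' @export
print.fluence_map <- function(x, ...) {
  cat(sprintf("fluence map %d x %d pixels, %.3g cm spacing, range [%.4g, %.4g]\n",
              length(x$x), length(x$y), x$spacing,
              min(x$values), max(x$values)))
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

# ---------------------------------------------------------------------------
# Piecewise-constant x-profiles.  A profile is list(brk, fun): `fun`
# evaluates the transmission at arbitrary x, `brk` lists its (sorted)
# discontinuities.  Pixel averages are exact integrals, so the map is an
# anti-aliased rasterization of the exact leaf geometry, and products of
# layers are taken at the function level (averaging after multiplying),
# which keeps coincident edges of the two layers exact.

# cumulative integral of a piecewise-constant function over [brk, val]
.pw_cumint <- function(t, brk, val) {
  cum <- c(0, cumsum(val * diff(brk)))
  i <- findInterval(t, brk, all.inside = TRUE)
  cum[i] + val[i] * (t - brk[i])
}

# pixel means over centers x_centers (pixel width h) of the piecewise
# function given by profile p = list(brk, fun); p$brk is sorted.
.pixel_avg_fun <- function(x_centers, h, p) {
  n <- length(x_centers)
  lo <- x_centers[1] - h
  hi <- x_centers[n] + h
  inner <- p$brk[p$brk > lo & p$brk < hi]
  brk <- c(lo - 1, lo, inner, hi, hi + 1)
  mids <- (brk[-1] + brk[-length(brk)]) / 2
  val <- p$fun(mids)
  upper <- .pw_cumint(x_centers + h / 2, brk, val)
  lower <- .pw_cumint(x_centers - h / 2, brk, val)
  (upper - lower) / h
}

# transmission profile of one leaf row: product of bank factors, each
# with a half-attenuation tip zone of width `tip` on the leaf side of the
# modeled tip position.  open=FALSE gives the fully blocked row.
.row_profile <- function(open, lt, rt, tip, tr) {
  if (!open) {
    f <- function(x) rep.int(tr, length(x))
    return(list(brk = numeric(0), fun = f))
  }
  st <- sqrt(tr)
  force(lt); force(rt); force(tip)
  f <- function(x)
    (tr + (st - tr) * (x >= lt - tip) + (1 - st) * (x > lt)) *
    (tr + (st - tr) * (x <= rt + tip) + (1 - st) * (x < rt))
  list(brk = sort.int(c(lt - tip, lt, rt, rt + tip)), fun = f)
}

# clamp profile p to at most `cap` inside intervals (list of c(a, b))
.pw_clamp <- function(p, intervals, cap) {
  if (!length(intervals)) return(p)
  force(p); force(intervals); force(cap)
  f <- function(x) {
    v <- p$fun(x)
    inside <- rep(FALSE, length(x))
    for (iv in intervals) inside <- inside | (x > iv[1] & x < iv[2])
    ifelse(inside, pmin(v, cap), v)
  }
  list(brk = sort(unique(c(p$brk, unlist(intervals)))), fun = f)
}

# product of two profiles
.pw_prod <- function(p1, p2) {
  force(p1); force(p2)
  list(brk = sort.int(c(p1$brk, p2$brk), method = "quick"),
       fun = function(x) p1$fun(x) * p2$fun(x))
}

# set difference of single open intervals a \ b -> list of intervals
.int_diff <- function(a, b) {
  if (is.null(a)) return(list())
  if (is.null(b)) return(list(a))
  out <- list()
  if (b[1] > a[1]) out <- c(out, list(c(a[1], min(a[2], b[1]))))
  if (b[2] < a[2]) out <- c(out, list(c(max(a[1], b[2]), a[2])))
  Filter(function(iv) iv[2] > iv[1] + 1e-12, out)
}

# One layer as horizontal bands: list of list(y0, y1, profile).
# Bands are leaf rows cut by tongue-and-groove strips; inside a strip
# band the profile is clamped to sqrt(T) over the strip x-intervals.
.layer_bands <- function(aperture, params, machine, y_range, layer) {
  tr <- params$layer_transmission[[layer]]
  st <- sqrt(tr)
  tip <- params$tip_width
  tng <- params$tng_width
  rows <- layer_rows(machine, layer, y_range)
  key <- round(rows$y_lo, 6)
  akey <- round(aperture$y_lo, 6)
  idx <- match(key, akey)
  open <- !is.na(idx)
  lt <- rt <- rep(NA_real_, nrow(rows))
  if (any(open)) {
    lt[open] <- leaf_tip_position(aperture$x_left[idx[open]], "left", params)
    rt[open] <- leaf_tip_position(aperture$x_right[idx[open]], "right",
                                  params)
  }
  profs <- lapply(seq_len(nrow(rows)), function(i)
    .row_profile(open[i] && rt[i] > lt[i], lt[i], rt[i], tip, tr))
  open_iv <- lapply(seq_len(nrow(rows)), function(i)
    if (open[i] && rt[i] > lt[i]) c(lt[i], rt[i]) else NULL)

  # strips: (y0, y1, x-intervals) on the open side of each row boundary
  strips <- list()
  if (tng > 0 && nrow(rows) > 1) {
    for (i in seq_len(nrow(rows) - 1)) {
      if (abs(rows$y_hi[i] - rows$y_lo[i + 1]) > 1e-9) next
      yb <- rows$y_hi[i]
      below <- .int_diff(open_iv[[i]], open_iv[[i + 1]])
      above <- .int_diff(open_iv[[i + 1]], open_iv[[i]])
      if (length(below))
        strips[[length(strips) + 1]] <- list(y0 = yb - tng, y1 = yb,
                                             x = below)
      if (length(above))
        strips[[length(strips) + 1]] <- list(y0 = yb, y1 = yb + tng,
                                             x = above)
    }
  }

  edges <- sort(unique(round(c(rows$y_lo, rows$y_hi,
                               unlist(lapply(strips, function(s)
                                 c(s$y0, s$y1)))), 9)))
  bands <- list()
  for (b in seq_len(length(edges) - 1)) {
    y0 <- edges[b]; y1 <- edges[b + 1]
    yc <- (y0 + y1) / 2
    i <- which(rows$y_lo <= yc & rows$y_hi >= yc)[1]
    if (is.na(i)) next
    p <- profs[[i]]
    for (s in strips)
      if (s$y0 <= yc && s$y1 >= yc) p <- .pw_clamp(p, s$x, st)
    bands[[length(bands) + 1]] <- list(y0 = y0, y1 = y1, profile = p)
  }
  bands
}

# rasterize bands onto a grid
.rasterize_bands <- function(bands, grid, v_out) {
  nx <- length(grid$x); ny <- length(grid$y)
  h <- grid$spacing
  values <- matrix(v_out, nrow = ny, ncol = nx)
  ylo_px <- grid$y - h / 2
  yhi_px <- grid$y + h / 2
  covered <- rep(0, ny)
  acc <- matrix(0, nrow = ny, ncol = nx)
  for (band in bands) {
    cov <- pmax(0, pmin(yhi_px, band$y1) - pmax(ylo_px, band$y0)) / h
    nz <- which(cov > 0)
    if (!length(nz)) next
    prof <- .pixel_avg_fun(grid$x, h, band$profile)
    acc[nz, ] <- acc[nz, ] + cov[nz] %o% prof
    covered[nz] <- covered[nz] + cov[nz]
  }
  # y not covered by any leaf row (outside the bank) keeps v_out
  rem <- pmax(0, 1 - covered)
  values <- acc + rem %o% rep(v_out, nx)
  values
}

.coarse_note <- function(grid, params) {
  if (grid$spacing > 0.1 && (params$tip_width > 0 || params$tng_width > 0))
    sprintf("grid spacing %.3g cm may be too coarse to resolve tip/T&G strips",
            grid$spacing)
  else character()
}

#' Transmission map of one MLC layer
#'
#' Computes the 2D transmission/fluence map of a single layer: open pixels
#' are 1, fully blocked pixels equal the layer transmission `T`, the tip
#' zone of width `tip_width` on the leaf side of each modeled tip
#' transmits `sqrt(T)` (the leaf acts as if half its height there), and
#' tongue-and-groove strips of width `tng_width` along leaf long sides
#' bordering open neighbor rows also transmit `sqrt(T)`. Pixel values are
#' exact area averages of the piecewise-constant leaf geometry, so partial
#' coverage is represented continuously; where a tip zone and a T&G strip
#' overlap, the smaller transmission wins.
#'
#' Rows not listed in `aperture` are treated as fully blocked. Modeled tip
#' positions come from [leaf_tip_position()] applied to the nominal
#' `x_left`/`x_right` of each row.
#'
#' @param aperture one layer's aperture frame (columns `y_lo`, `y_hi`,
#'   `x_left`, `x_right`).
#' @param params an [mlc_parameters()] object.
#' @param machine an [machine()] object.
#' @param grid a [fluence_grid()].
#' @param layer `"proximal"` or `"distal"` (selects the transmission and
#'   the row stagger).
#' @return A `fluence_map`.
#' @export
layer_transmission_map <- function(aperture, params, machine, grid,
                                   layer = c("proximal", "distal")) {
  layer <- match.arg(layer)
  tr <- params$layer_transmission[[layer]]
  h <- grid$spacing
  bands <- .layer_bands(aperture, params, machine,
                        c(min(grid$y) - h, max(grid$y) + h), layer)
  values <- .rasterize_bands(bands, grid, v_out = tr)
  .new_fluence_map(grid, values, .coarse_note(grid, params))
}

#' Combine the two layer maps
#'
#' Pointwise product of the proximal and distal transmission maps; the
#' fully stacked (both blocked) region transmits the product of the layer
#' transmissions. Note that for apertures whose layer edges coincide,
#' multiplying two already rasterized maps degrades the shared edge
#' (the product of pixel averages is not the average of the product);
#' [dual_layer_fluence()] avoids this by multiplying the exact profiles
#' before rasterizing and is what the dynamic accumulator uses.
#'
#' @param proximal,distal `fluence_map`s on identical grids.
#' @return A `fluence_map`.
#' @export
combined_fluence <- function(proximal, distal) {
  if (length(proximal$x) != length(distal$x) ||
      length(proximal$y) != length(distal$y) ||
      max(abs(proximal$x - distal$x)) > 1e-9 ||
      max(abs(proximal$y - distal$y)) > 1e-9)
    stop("fluence grids do not match")
  .new_fluence_map(
    list(x = proximal$x, y = proximal$y, spacing = proximal$spacing),
    proximal$values * distal$values,
    notes = union(proximal$notes, distal$notes))
}

#' Exact dual-layer fluence of a control point's apertures
#'
#' Computes the combined transmission of both layers by multiplying the
#' exact piecewise leaf profiles within each horizontal band (the bands
#' are the half-leaf-width partition induced by the staggered rows, cut
#' further by T&G strips) and rasterizing the product once. Edges shared
#' between the two layers stay exact to the pixel-average level.
#'
#' @param apertures list with `proximal` and `distal` aperture frames.
#' @param params an [mlc_parameters()] object.
#' @param machine an [machine()] object.
#' @param grid a [fluence_grid()].
#' @return A `fluence_map`.
#' @export
dual_layer_fluence <- function(apertures, params, machine, grid) {
  h <- grid$spacing
  yr <- c(min(grid$y) - h, max(grid$y) + h)
  bp <- .layer_bands(apertures$proximal, params, machine, yr, "proximal")
  bd <- .layer_bands(apertures$distal, params, machine, yr, "distal")
  trp <- params$layer_transmission[["proximal"]]
  trd <- params$layer_transmission[["distal"]]
  const_p <- list(brk = numeric(0), fun = function(x) rep(trp, length(x)))
  const_d <- list(brk = numeric(0), fun = function(x) rep(trd, length(x)))

  edges <- sort(unique(round(unlist(c(
    lapply(bp, function(b) c(b$y0, b$y1)),
    lapply(bd, function(b) c(b$y0, b$y1)))), 9)))
  find_band <- function(bands, yc, fallback) {
    for (b in bands) if (b$y0 <= yc && b$y1 >= yc) return(b$profile)
    fallback
  }
  bands <- list()
  for (b in seq_len(length(edges) - 1)) {
    y0 <- edges[b]; y1 <- edges[b + 1]
    yc <- (y0 + y1) / 2
    pp <- find_band(bp, yc, const_p)
    pd <- find_band(bd, yc, const_d)
    bands[[length(bands) + 1]] <- list(y0 = y0, y1 = y1,
                                       profile = .pw_prod(pp, pd))
  }
  values <- .rasterize_bands(bands, grid, v_out = trp * trd)
  .new_fluence_map(grid, values, .coarse_note(grid, params))
}

# linear interpolation of apertures between two control points at
# fraction f in [0, 1]; rows are matched on (layer, y_lo), rows present
# on one side only are held static.
.interp_apertures <- function(ap1, ap2, f) {
  out <- list()
  for (lay in c("proximal", "distal")) {
    a <- ap1[[lay]]; b <- ap2[[lay]]
    ka <- round(a$y_lo, 6); kb <- round(b$y_lo, 6)
    common <- intersect(ka, kb)
    ia <- match(common, ka); ib <- match(common, kb)
    merged <- a[ia, , drop = FALSE]
    merged$x_left <- (1 - f) * a$x_left[ia] + f * b$x_left[ib]
    merged$x_right <- (1 - f) * a$x_right[ia] + f * b$x_right[ib]
    only_a <- a[!(ka %in% common), , drop = FALSE]
    only_b <- b[!(kb %in% common), , drop = FALSE]
    merged <- rbind(merged, only_a, only_b)
    out[[lay]] <- merged[order(merged$y_lo), , drop = FALSE]
  }
  out
}

#' Accumulate the fluence of a dynamic delivery
#'
#' MU-weight-normalized, time-averaged combined fluence of a plan. MU
#' weights are differential: each control point's weight is delivered
#' while the leaves move linearly from the previous control point to it
#' (the first weight is delivered statically). Segments are subdivided so
#' no leaf travels more than `max_substep` between samples, and each
#' sub-segment is sampled at its midpoint.
#'
#' @param plan an [mlc_plan()].
#' @param params an [mlc_parameters()] object.
#' @param machine an [machine()] object.
#' @param grid a [fluence_grid()]; defaults to [default_grid()] of the plan.
#' @param max_substep maximum leaf travel per sub-sample, cm (default 0.1).
#' @return A `fluence_map` whose values are the time-averaged relative
#'   fluence (weights sum to 1).
#' @export
accumulate_dynamic_fluence <- function(plan, params, machine,
                                       grid = default_grid(plan),
                                       max_substep = 0.1) {
  stopifnot(inherits(plan, "mlc_plan"))
  cps <- plan$control_points
  acc <- matrix(0, nrow = length(grid$y), ncol = length(grid$x))
  w1 <- cps[[1]]$mu_weight
  if (w1 > 0) {
    f <- dual_layer_fluence(cps[[1]]$apertures, params, machine, grid)
    acc <- acc + w1 * f$values
  }
  if (length(cps) > 1) {
    for (j in 2:length(cps)) {
      w <- cps[[j]]$mu_weight
      if (w <= 0) next
      travel <- .max_leaf_travel(cps[[j - 1]], cps[[j]])
      n_sub <- max(1L, ceiling(travel / max_substep))
      fr <- (seq_len(n_sub) - 0.5) / n_sub
      for (f_sub in fr) {
        ap <- .interp_apertures(cps[[j - 1]]$apertures, cps[[j]]$apertures,
                                f_sub)
        fm <- dual_layer_fluence(ap, params, machine, grid)
        acc <- acc + (w / n_sub) * fm$values
      }
    }
  }
  .new_fluence_map(grid, acc, .coarse_note(grid, params))
}

#' Write or read a fluence/dose map
#'
#' `write_map_grid()` uses a compact text grid format: two '#' header
#' lines (format tag; x0, y0, spacing, nx, ny) followed by `ny` rows of
#' `nx` values. `write_map_csv()` writes long-format `x,y,value` rows.
#' Round-trips are lossless to the stated precision.
#'
#' @param map a `fluence_map` (or dose map on the same structure).
#' @param path file path.
#' @return Readers return a `fluence_map`.
#' @export
write_map_grid <- function(map, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dualmlc-map-v1", con)
  writeLines(sprintf("# x0=%.10g y0=%.10g spacing=%.10g nx=%d ny=%d",
                     map$x[1], map$y[1], map$spacing,
                     length(map$x), length(map$y)), con)
  utils::write.table(format(map$values, digits = 12, scientific = TRUE,
                            trim = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_map_grid
#' @export
read_map_grid <- function(path) {
  hdr <- readLines(path, n = 2)
  if (!identical(hdr[1], "# dualmlc-map-v1"))
    stop("not a dualmlc map file: ", path)
  kv <- regmatches(hdr[2], gregexpr("[a-z0-9]+=[-0-9.e+]+", hdr[2]))[[1]]
  vals <- stats::setNames(
    as.numeric(sub(".*=", "", kv)), sub("=.*", "", kv))
  m <- as.matrix(utils::read.table(path, skip = 2))
  dimnames(m) <- NULL
  if (nrow(m) != vals["ny"] || ncol(m) != vals["nx"])
    stop("map dimensions disagree with header in ", path)
  grid <- list(x = vals[["x0"]] + (seq_len(vals[["nx"]]) - 1) * vals[["spacing"]],
               y = vals[["y0"]] + (seq_len(vals[["ny"]]) - 1) * vals[["spacing"]],
               spacing = vals[["spacing"]])
  .new_fluence_map(grid, m)
}

#' @rdname write_map_grid
#' @export
write_map_csv <- function(map, path) {
  df <- data.frame(x = rep(map$x, each = length(map$y)),
                   y = rep(map$y, times = length(map$x)),
                   value = as.vector(map$values))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# dualmlc-map-csv-v1 units=cm", con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_grid
#' @export
read_map_csv <- function(path) {
  hdr <- readLines(path, n = 1)
  if (!grepl("^# dualmlc-map-csv-v1", hdr))
    stop("not a dualmlc map csv file: ", path)
  df <- utils::read.csv(path, skip = 1)
  xs <- sort(unique(df$x)); ys <- sort(unique(df$y))
  values <- matrix(NA_real_, nrow = length(ys), ncol = length(xs))
  values[cbind(match(df$y, ys), match(df$x, xs))] <- df$value
  .new_fluence_map(list(x = xs, y = ys, spacing = diff(xs[1:2])), values)
}
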