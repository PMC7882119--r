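#' Leaf-row geometry of an MLC layer
#'
#' Row edges in the in-plane (Y) direction at isocenter. Proximal rows are
#' aligned on integer multiples of the physical leaf width; distal rows are
#' staggered by half a physical width, which yields the effective
#' resolution of half a leaf width.
#'
#' @param machine an [machine()] object.
#' @param layer `"proximal"` or `"distal"`.
#' @param y_range in-plane extent to cover, cm (length-2).
#' @return A data frame with columns `y_lo`, `y_hi`, one row per leaf pair.
#' @export
layer_rows <- function(machine, layer = c("proximal", "distal"),
                       y_range = c(-machine$max_field / 2,
                                   machine$max_field / 2)) {
  layer <- match.arg(layer)
  w <- machine$physical_leaf_width
  shift <- if (layer == "distal") w / 2 else 0
  lo <- floor((y_range[1] - shift) / w) * w + shift
  edges <- seq(lo, y_range[2] + w, by = w)
  data.frame(y_lo = edges[-length(edges)], y_hi = edges[-1])
}

#' Build a layer aperture
#'
#' An aperture for one layer is a data frame with one row per leaf pair:
#' columns `y_lo`, `y_hi` (row extent, cm), `x_left`, `x_right` (nominal
#' tip positions, cm). Rows not listed are treated as fully blocked.
#'
#' `rect_field_aperture()` opens a rectangle on both layers;
#' rows whose center falls inside `[y1, y2]` open to `[x1, x2]`.
#'
#' @param machine an [machine()] object.
#' @param x1,x2,y1,y2 rectangle bounds at isocenter, cm.
#' @return A list with elements `proximal` and `distal` aperture frames.
#' @export
#' @examples
#' ap <- rect_field_aperture(machine(), -5, 5, -5, 5)
rect_field_aperture <- function(machine, x1, x2, y1, y2) {
  stopifnot(x1 <= x2, y1 <= y2)
  one <- function(layer) {
    rows <- layer_rows(machine, layer, c(y1 - 1, y2 + 1))
    ctr <- (rows$y_lo + rows$y_hi) / 2
    open <- ctr > y1 & ctr < y2
    rows <- rows[open, , drop = FALSE]
    rows$x_left <- rep(x1, nrow(rows))
    rows$x_right <- rep(x2, nrow(rows))
    rownames(rows) <- NULL
    rows
  }
  list(proximal = one("proximal"), distal = one("distal"))
}

#' Construct a control point
#'
#' @param apertures list with `proximal` and `distal` aperture frames (see
#'   [rect_field_aperture()]).
#' @param mu_weight fraction of the plan MU delivered in this segment.
#' @param gantry_angle gantry angle, degrees.
#' @return An object of class `control_point`.
#' @export
control_point <- function(apertures, mu_weight = 1, gantry_angle = 0) {
  stopifnot(is.list(apertures),
            all(c("proximal", "distal") %in% names(apertures)),
            mu_weight >= 0)
  for (lay in c("proximal", "distal")) {
    a <- apertures[[lay]]
    stopifnot(all(c("y_lo", "y_hi", "x_left", "x_right") %in% names(a)))
    if (nrow(a) && any(a$x_left > a$x_right + 1e-12))
      stop("aperture has x_left > x_right in ", lay, " layer")
  }
  structure(list(apertures = apertures, mu_weight = mu_weight,
                 gantry_angle = gantry_angle),
            class = "control_point")
}

#' Construct a plan
#'
#' A plan is an ordered sequence of control points with MU weights summing
#' to one, plus the total MU and a label. Leaf motion is interpolated
#' linearly between consecutive control points of the same beam.
#'
#' @param control_points list of [control_point()] objects.
#' @param total_mu total monitor units.
#' @param label character label.
#' @param arc logical; `TRUE` for rotational (arc) delivery, which enables
#'   MU-per-degree checks.
#' @return An object of class `mlc_plan`.
#' @export
mlc_plan <- function(control_points, total_mu = 100, label = "plan",
                     arc = TRUE) {
  w <- vapply(control_points, function(cp) cp$mu_weight, numeric(1))
  if (sum(w) <= 0) stop("plan has zero total MU weight")
  for (i in seq_along(control_points))
    control_points[[i]]$mu_weight <- w[i] / sum(w)
  structure(list(control_points = control_points, total_mu = total_mu,
                 label = label, arc = arc),
            class = "mlc_plan")
}

#' @export
print.mlc_plan <- function(x, ...) {
  cat(sprintf("MLC plan '%s': %d control points, %.1f MU, %s\n",
              x$label, length(x$control_points), x$total_mu,
              if (x$arc) "arc" else "fixed gantry"))
  invisible(x)
}

# match apertures row-by-row between consecutive control points; rows are
# identified by (layer, y_lo). Returns max |leaf travel| in cm.
.max_leaf_travel <- function(cp1, cp2) {
  mx <- 0
  for (lay in c("proximal", "distal")) {
    a <- cp1$apertures[[lay]]; b <- cp2$apertures[[lay]]
    key_a <- round(a$y_lo, 6); key_b <- round(b$y_lo, 6)
    common <- intersect(key_a, key_b)
    if (length(common)) {
      ia <- match(common, key_a); ib <- match(common, key_b)
      mx <- max(mx, abs(a$x_left[ia] - b$x_left[ib]),
                abs(a$x_right[ia] - b$x_right[ib]))
    }
  }
  mx
}

#' Validate apertures and plan kinematics
#'
#' Checks a single control point (field bounds) or a whole plan (field
#' bounds, minimum dynamic gap for moving leaves, leaf speed against the
#' fastest deliverable segment time, and MU/deg for arc segments). The
#' segment time is `max(delta_MU / max_dose_rate,
#' delta_gantry / max_gantry_speed)`.
#'
#' @param x a `control_point` or an `mlc_plan`.
#' @param machine an [machine()] object.
#' @param params an [mlc_parameters()] object (supplies the minimum
#'   dynamic gap).
#' @return A list of class `aperture_validity` with `valid` (logical) and
#'   `violations` (data frame: control point index, type, detail).
#' @export
validate_aperture <- function(x, machine, params) {
  viol <- list()
  add <- function(i, type, detail)
    viol[[length(viol) + 1]] <<- data.frame(control_point = i, type = type,
                                            detail = detail)
  half <- machine$max_field / 2

  check_bounds <- function(cp, i) {
    for (lay in c("proximal", "distal")) {
      a <- cp$apertures[[lay]]
      if (nrow(a) == 0) next
      if (any(abs(c(a$x_left, a$x_right)) > half + 1e-9))
        add(i, "field_bounds",
            sprintf("%s leaf beyond +/-%g cm", lay, half))
      if (any(a$y_lo < -half - machine$physical_leaf_width - 1e-9) ||
          any(a$y_hi > half + machine$physical_leaf_width + 1e-9))
        add(i, "field_bounds", sprintf("%s rows beyond field in Y", lay))
    }
  }

  if (inherits(x, "control_point")) {
    check_bounds(x, 1L)
  } else if (inherits(x, "mlc_plan")) {
    cps <- x$control_points
    for (i in seq_along(cps)) check_bounds(cps[[i]], i)
    if (length(cps) > 1) {
      for (i in seq_len(length(cps) - 1)) {
        cp1 <- cps[[i]]; cp2 <- cps[[i + 1]]
        travel <- .max_leaf_travel(cp1, cp2)
        dmu <- x$total_mu * cp2$mu_weight
        dgan <- abs(cp2$gantry_angle - cp1$gantry_angle)
        t_seg <- max(dmu / machine$max_dose_rate,
                     dgan / machine$max_gantry_speed)
        if (travel > 0 && t_seg > 0 &&
            travel / t_seg > machine$max_leaf_speed + 1e-9)
          add(i + 1L, "leaf_speed",
              sprintf("requires %.2f cm/s > %.1f cm/s",
                      travel / t_seg, machine$max_leaf_speed))
        if (x$arc && dgan > 0 && dmu / dgan < machine$min_mu_per_deg - 1e-12)
          add(i + 1L, "mu_per_deg",
              sprintf("%.3f MU/deg < %.2f MU/deg",
                      dmu / dgan, machine$min_mu_per_deg))
        if (travel > 1e-9) {
          for (cp in list(cp1, cp2)) for (lay in c("proximal", "distal")) {
            a <- cp$apertures[[lay]]
            gap <- a$x_right - a$x_left
            if (nrow(a) && any(gap < params$dynamic_min_gap - 1e-9))
              add(i, "min_gap",
                  sprintf("moving %s gap %.3f cm < %.3f cm", lay,
                          min(gap), params$dynamic_min_gap))
          }
        }
      }
    }
  } else stop("x must be a control_point or an mlc_plan")

  violations <- if (length(viol)) do.call(rbind, viol) else
    data.frame(control_point = integer(), type = character(),
               detail = character())
  violations <- unique(violations)
  structure(list(valid = nrow(violations) == 0, violations = violations),
            class = "aperture_validity")
}

#' @export
print.aperture_validity <- function(x, ...) {
  if (x$valid) cat("aperture/plan valid: no violations\n")
  else {
    cat(sprintf("INVALID: %d violation(s)\n", nrow(x$violations)))
    print(x$violations)
  }
  invisible(x)
}

#' Write or read a plan as JSON
#'
#' @param plan an [mlc_plan()].
#' @param path file path.
#' @return `read_plan_json()` returns the plan.
#' @export
write_plan_json <- function(plan, path) {
  cps <- lapply(plan$control_points, function(cp) {
    list(mu_weight = cp$mu_weight, gantry_angle = cp$gantry_angle,
         proximal = as.list(cp$apertures$proximal),
         distal = as.list(cp$apertures$distal))
  })
  obj <- list(format = "dualmlc-plan-v1", label = plan$label,
              total_mu = plan$total_mu, arc = plan$arc,
              control_points = cps)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_json
#' @export
read_plan_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$format) || obj$format != "dualmlc-plan-v1")
    stop("not a dualmlc plan file: ", path)
  as_frame <- function(l) {
    cols <- c("y_lo", "y_hi", "x_left", "x_right")
    if (is.null(l) || length(l) == 0 || length(l[[1]]) == 0)
      return(stats::setNames(
        as.data.frame(replicate(4, numeric(0), simplify = FALSE)), cols))
    as.data.frame(lapply(l[cols], function(v) unlist(v)))
  }
  cps <- lapply(obj$control_points, function(row)
    control_point(
      apertures = list(proximal = as_frame(row$proximal),
                       distal = as_frame(row$distal)),
      mu_weight = row$mu_weight, gantry_angle = row$gantry_angle))
  mlc_plan(cps, total_mu = obj$total_mu, label = obj$label, arc = obj$arc)
}
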