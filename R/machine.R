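#' Machine geometry and beam constants
#'
#' Describes the fixed geometry of a ring-gantry linac with a
#' stacked-and-staggered dual-layer MLC. Defaults correspond to a 6 MV FFF
#' beam machine with a 28 x 28 cm^2 maximum field, 1 cm physical leaf
#' shadow per layer and 0.5 cm effective leaf width from the half-width
#' stagger between the two layers.
#'
#' @param sad source-axis distance, cm.
#' @param layer_distance_proximal source-to-bottom-of-leaf distance of the
#'   upper (proximal) MLC layer, cm.
#' @param layer_distance_distal the same for the lower (distal) layer, cm.
#' @param max_field maximum square field side at isocenter, cm.
#' @param effective_leaf_width effective leaf width at isocenter, cm
#'   (the staggered resolution, half the physical width).
#' @param physical_leaf_width physical leaf shadow at isocenter, cm.
#' @param d_max depth of maximum dose, cm.
#' @param source_sigma_x,source_sigma_y Gaussian primary-source sigmas in
#'   the cross-plane (leaf travel) and in-plane directions, cm.
#' @param max_leaf_speed maximum leaf speed, cm/s.
#' @param max_gantry_speed maximum gantry speed, deg/s.
#' @param min_mu_per_deg minimum deliverable MU per degree for arcs.
#' @param max_dose_rate maximum dose rate, MU/s (800 MU/min nominal).
#' @return An object of class `mlc_machine`.
#' @export
#' @examples
#' m <- machine()
#' m$max_field
machine <- function(sad = 100,
                    layer_distance_proximal = 38.9,
                    layer_distance_distal = 47.9,
                    max_field = 28,
                    effective_leaf_width = 0.5,
                    physical_leaf_width = 1.0,
                    d_max = 1.3,
                    source_sigma_x = 0.075,
                    source_sigma_y = 0.090,
                    max_leaf_speed = 5,
                    max_gantry_speed = 12,
                    min_mu_per_deg = 0.1,
                    max_dose_rate = 800 / 60) {
  m <- list(
    sad = sad,
    layer_distance_proximal = layer_distance_proximal,
    layer_distance_distal = layer_distance_distal,
    max_field = max_field,
    effective_leaf_width = effective_leaf_width,
    physical_leaf_width = physical_leaf_width,
    d_max = d_max,
    source_sigma_x = source_sigma_x,
    source_sigma_y = source_sigma_y,
    max_leaf_speed = max_leaf_speed,
    max_gantry_speed = max_gantry_speed,
    min_mu_per_deg = min_mu_per_deg,
    max_dose_rate = max_dose_rate
  )
  lens <- unlist(m)
  if (any(!is.finite(lens)) || any(lens <= 0))
    stop("all machine constants must be positive and finite")
  if (!(layer_distance_proximal < layer_distance_distal &&
        layer_distance_distal < sad))
    stop("layer distances must satisfy proximal < distal < sad")
  class(m) <- "mlc_machine"
  m
}

#' MLC leaf-end model parameters
#'
#' The parametric leaf-end/fluence model of the TPS: each leaf is an
#' infinitely thin attenuator with transmission `layer_transmission`; its
#' modeled tip position is the nominal position corrected by `offset`,
#' `gain` and `curvature` (see [leaf_tip_position()]); a strip of width
#' `tip_width` inboard of the tip, and tongue-and-groove strips of width
#' `tng_width` along leaf sides facing open neighbor rows, transmit as if
#' the leaf had half its height there (transmission `sqrt(T)`).
#'
#' @param offset leaf-end offset, cm. Positive values retract both modeled
#'   tips outward, widening every gap dosimetrically by `2 * offset`.
#' @param gain dimensionless multiplicative position error; shifts the
#'   leaf-pair midpoint by `gain * x_nom`.
#' @param curvature quadratic off-axis term, 1/cm; adds
#'   `curvature * x_nom^2` to the dosimetric offset away from the axis.
#' @param tip_width width of the half-attenuation tip zone, cm.
#' @param layer_transmission fraction in (0, 1) transmitted through a
#'   single fully blocking layer. One value shared by both layers or a
#'   named vector `c(proximal=, distal=)`.
#' @param tng_width tongue-and-groove strip width, cm.
#' @param dynamic_min_gap minimum allowed moving-leaf gap, cm.
#' @return An object of class `mlc_parameters`.
#' @export
#' @examples
#' p <- mlc_parameters(offset = 0.007)
#' leaf_tip_position(5, "right", p)
mlc_parameters <- function(offset = 0,
                           gain = 0,
                           curvature = 0,
                           tip_width = 0,
                           layer_transmission = 0.0047,
                           tng_width = 0.05,
                           dynamic_min_gap = 0.06) {
  if (length(layer_transmission) == 1)
    layer_transmission <- c(proximal = unname(layer_transmission),
                            distal = unname(layer_transmission))
  if (!all(c("proximal", "distal") %in% names(layer_transmission)))
    names(layer_transmission) <- c("proximal", "distal")
  stopifnot(
    is.finite(offset), is.finite(gain), is.finite(curvature),
    tip_width >= 0, tng_width >= 0, dynamic_min_gap >= 0,
    all(layer_transmission > 0), all(layer_transmission < 1)
  )
  p <- list(
    offset = offset, gain = gain, curvature = curvature,
    tip_width = tip_width,
    layer_transmission = layer_transmission,
    tng_width = tng_width,
    dynamic_min_gap = dynamic_min_gap
  )
  class(p) <- "mlc_parameters"
  p
}

#' @export
print.mlc_parameters <- function(x, ...) {
  cat("MLC leaf-end model parameters\n")
  cat(sprintf("  offset:       %+0.4f cm\n", x$offset))
  cat(sprintf("  gain:         %+0.5f\n", x$gain))
  cat(sprintf("  curvature:    %+0.2e 1/cm\n", x$curvature))
  cat(sprintf("  tip width:    %0.3f cm\n", x$tip_width))
  cat(sprintf("  transmission: %0.4f (proximal) / %0.4f (distal)\n",
              x$layer_transmission[["proximal"]],
              x$layer_transmission[["distal"]]))
  cat(sprintf("  T&G width:    %0.3f cm\n", x$tng_width))
  cat(sprintf("  min dyn gap:  %0.3f cm\n", x$dynamic_min_gap))
  invisible(x)
}

#' @export
print.mlc_machine <- function(x, ...) {
  cat("Ring-gantry dual-layer MLC machine\n")
  cat(sprintf("  SAD %g cm, max field %g x %g cm^2\n",
              x$sad, x$max_field, x$max_field))
  cat(sprintf("  MLC layers at %g / %g cm, leaf width %g cm physical (%g cm effective)\n",
              x$layer_distance_proximal, x$layer_distance_distal,
              x$physical_leaf_width, x$effective_leaf_width))
  cat(sprintf("  source sigma %g (X) / %g (Y) cm, d_max %g cm\n",
              x$source_sigma_x, x$source_sigma_y, x$d_max))
  invisible(x)
}

#' Write or read a machine description as JSON
#'
#' Serializes a machine plus an MLC parameter set to a single JSON machine
#' file and reads it back.
#'
#' @param machine an `mlc_machine`.
#' @param params an `mlc_parameters`.
#' @param path file path.
#' @return `read_machine_json()` returns `list(machine, params)`.
#' @export
write_machine_json <- function(machine, params, path) {
  obj <- list(
    format = "dualmlc-machine-v1",
    machine = unclass(machine),
    mlc_parameters = list(
      offset = params$offset, gain = params$gain,
      curvature = params$curvature, tip_width = params$tip_width,
      layer_transmission = as.list(params$layer_transmission),
      tng_width = params$tng_width,
      dynamic_min_gap = params$dynamic_min_gap
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_machine_json
#' @export
read_machine_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "dualmlc-machine-v1")
    stop("not a dualmlc machine file: ", path)
  m <- do.call(machine, obj$machine)
  pp <- obj$mlc_parameters
  p <- mlc_parameters(
    offset = pp$offset, gain = pp$gain, curvature = pp$curvature,
    tip_width = pp$tip_width,
    layer_transmission = c(proximal = pp$layer_transmission$proximal,
                           distal = pp$layer_transmission$distal),
    tng_width = pp$tng_width, dynamic_min_gap = pp$dynamic_min_gap
  )
  list(machine = m, params = p)
}
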