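#' Modeled leaf-tip position
#'
#' Maps a nominal leaf position to the tip position used by the fluence
#' model. For the left and right banks
#' \deqn{X_{Lt} = X_{nom} - Offset + Gain\,X_{nom} - Curvature\,X_{nom}^2}
#' \deqn{X_{Rt} = X_{nom} + Offset + Gain\,X_{nom} + Curvature\,X_{nom}^2}
#' with the X coordinate positive to the right of the central axis for both
#' banks (beam's eye view, IEC 61217). The signed nominal position itself
#' plays the role of the off-axis term, so that Offset and Curvature move
#' the dosimetric edge while Gain moves the pair midpoint.
#'
#' @param x_nom nominal leaf position(s), cm at isocenter; must satisfy
#'   `abs(x_nom) <= 14`.
#' @param bank `"left"` or `"right"`.
#' @param params an [mlc_parameters()] object.
#' @return Modeled tip position(s), cm.
#' @export
#' @examples
#' leaf_tip_position(3, "right", mlc_parameters())        # identity
#' leaf_tip_position(5, "right", mlc_parameters(offset = 0.007))
leaf_tip_position <- function(x_nom, bank = c("left", "right"), params) {
  bank <- match.arg(bank)
  stopifnot(inherits(params, "mlc_parameters"))
  if (any(!is.finite(x_nom)) || any(abs(x_nom) > 14))
    stop("x_nom out of range: |x_nom| must be <= 14 cm")
  s <- if (bank == "left") -1 else 1
  x_nom + s * params$offset + params$gain * x_nom +
    s * params$curvature * x_nom^2
}

#' Dosimetric offset of a closed leaf pair
#'
#' Half the modeled tip separation of an opposed pair planned at the same
#' nominal position: `(X_Rt - X_Lt) / 2 = offset + curvature * x_nom^2`.
#' Independent of `gain`.
#'
#' @inheritParams leaf_tip_position
#' @return Dosimetric offset(s), cm.
#' @export
dosimetric_offset <- function(x_nom, params) {
  stopifnot(inherits(params, "mlc_parameters"))
  if (any(!is.finite(x_nom)) || any(abs(x_nom) > 14))
    stop("x_nom out of range: |x_nom| must be <= 14 cm")
  params$offset + params$curvature * x_nom^2
}

#' Midpoint shift of a closed leaf pair
#'
#' Displacement of the modeled pair midpoint from the nominal position:
#' `(X_Lt + X_Rt) / 2 - x_nom = gain * x_nom`. Independent of `offset`
#' and `curvature`.
#'
#' @inheritParams leaf_tip_position
#' @return Midpoint shift(s), cm.
#' @export
midpoint_shift <- function(x_nom, params) {
  stopifnot(inherits(params, "mlc_parameters"))
  if (any(!is.finite(x_nom)) || any(abs(x_nom) > 14))
    stop("x_nom out of range: |x_nom| must be <= 14 cm")
  params$gain * x_nom
}

#' Equivalent square of a rectangular field
#'
#' Side of the square field with the same area-to-perimeter ratio,
#' `2ab/(a+b)`.
#'
#' @param a,b rectangle sides, cm; must be positive.
#' @return Equivalent square side, cm.
#' @export
#' @examples
#' equivalent_square(0.333, 1)  # ~0.5
equivalent_square <- function(a, b) {
  if (any(!is.finite(c(a, b))) || any(c(a, b) <= 0))
    stop("field sides must be positive")
  2 * a * b / (a + b)
}
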