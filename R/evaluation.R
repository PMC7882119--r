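# Dose-comparison and QA statistics: gamma analysis with global/local
# normalization, per-detector local dose errors, TG-119-style confidence
# limits.

#' Gamma criteria
#'
#' @param dose_tolerance dose-difference tolerance, percent.
#' @param dta distance-to-agreement, mm.
#' @param normalization `"global"` (tolerance scales with the reference
#'   maximum) or `"local"` (with the local reference dose).
#' @param threshold low-dose exclusion threshold, percent of the
#'   reference maximum (default 10).
#' @return An object of class `gamma_criteria`.
#' @export
#' @examples
#' gamma_criteria(3, 2, "global")  # the standard 3%G/2mm
gamma_criteria <- function(dose_tolerance = 3, dta = 2,
                           normalization = c("global", "local"),
                           threshold = 10) {
  normalization <- match.arg(normalization)
  stopifnot(dose_tolerance > 0, dta > 0, threshold > 0, threshold < 100)
  structure(list(dose_tolerance = dose_tolerance, dta = dta,
                 normalization = normalization, threshold = threshold),
            class = "gamma_criteria")
}

#' @export
print.gamma_criteria <- function(x, ...) {
  cat(sprintf("%g%%%s/%gmm, %g%% threshold\n", x$dose_tolerance,
              if (x$normalization == "global") "G" else "L", x$dta,
              x$threshold))
  invisible(x)
}

#' Parse a compact criteria string
#'
#' `"3G2"` means 3% global / 2 mm, `"2L2"` 2% local / 2 mm.
#'
#' @param s criteria string.
#' @param threshold threshold percent.
#' @return A [gamma_criteria()].
#' @export
parse_criteria <- function(s, threshold = 10) {
  m <- regmatches(s, regexec("^([0-9.]+)([GgLl])([0-9.]+)$", s))[[1]]
  if (length(m) != 4) stop("cannot parse criteria string: ", s)
  gamma_criteria(as.numeric(m[2]), as.numeric(m[4]),
                 if (toupper(m[3]) == "G") "global" else "local",
                 threshold)
}

# fine resampling of a reference map by bilinear interpolation
.resample_ref <- function(ref, step) {
  xf <- seq(ref$x[1], ref$x[length(ref$x)], by = step)
  yf <- seq(ref$y[1], ref$y[length(ref$y)], by = step)
  vals <- .interp_map(ref, rep(xf, each = length(yf)),
                      rep(yf, times = length(xf)))
  list(x = xf, y = yf, values = matrix(vals, nrow = length(yf)),
       step = step)
}

#' Gamma analysis
#'
#' Computes the gamma index of an evaluated dose against a reference
#' map:
#' \deqn{\gamma(p) = \min_{|r - p| \le 3\,dta}
#'   \sqrt{(\Delta D(p,r)/\Delta D_{tol})^2 + (|p-r|/dta)^2}}
#' The reference is resampled by bilinear interpolation at `dta/10`
#' steps (never coarser than 0.02 cm, so loosening the DTA never
#' degrades the search grid); the dose tolerance is `dose_tolerance * max(ref)` for global
#' normalization and `dose_tolerance * ref(r)` (per reference point) for
#' local. Evaluated points receiving less than `threshold` percent of
#' the reference maximum are excluded.
#'
#' @param eval_dose a `dose_map`/`fluence_map` on the same coordinate
#'   units as `ref`, or a data frame with columns `x`, `y`, `dose`
#'   (detector point set).
#' @param ref a reference `dose_map`.
#' @param crit a [gamma_criteria()].
#' @return A `gamma_result`: data frame `points` (x, y, eval, ref_here,
#'   gamma, local_err_pct), `passing_rate` (percent of gamma <= 1), `n`,
#'   `criteria`.
#' @export
gamma_index <- function(eval_dose, ref, crit = gamma_criteria()) {
  dta_cm <- crit$dta / 10
  if (inherits(eval_dose, "fluence_map")) {
    pts <- data.frame(x = rep(eval_dose$x, each = length(eval_dose$y)),
                      y = rep(eval_dose$y, times = length(eval_dose$x)),
                      dose = as.vector(eval_dose$values))
  } else {
    pts <- as.data.frame(eval_dose)
    stopifnot(all(c("x", "y", "dose") %in% names(pts)))
  }
  ref_max <- max(ref$values)
  cut <- crit$threshold / 100 * ref_max
  keep <- pts$dose >= cut
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts))
    stop("no evaluated points above the dose threshold")

  # dta/10 resampling, but never coarser than 0.02 cm so that loosening
  # the DTA cannot degrade the search grid
  fine <- .resample_ref(ref, min(dta_cm / 10, 0.02))
  radius <- 3 * dta_cm
  tol_global <- crit$dose_tolerance / 100 * ref_max
  # squared inverse tolerance per fine reference node
  inv_tol2 <- if (crit$normalization == "global")
    matrix(1 / tol_global^2, nrow(fine$values), ncol(fine$values))
  else (100 / (crit$dose_tolerance * fine$values))^2
  inv_dta2 <- 1 / dta_cm^2

  gam <- numeric(nrow(pts))
  ref_here <- .interp_map(ref, pmin(pmax(pts$x, ref$x[1]),
                                    ref$x[length(ref$x)]),
                          pmin(pmax(pts$y, ref$y[1]),
                               ref$y[length(ref$y)]))
  step <- fine$step
  for (i in seq_len(nrow(pts))) {
    ix0 <- max(1L, ceiling((pts$x[i] - radius - fine$x[1]) / step) + 1L)
    ix1 <- min(length(fine$x),
               floor((pts$x[i] + radius - fine$x[1]) / step) + 1L)
    iy0 <- max(1L, ceiling((pts$y[i] - radius - fine$y[1]) / step) + 1L)
    iy1 <- min(length(fine$y),
               floor((pts$y[i] + radius - fine$y[1]) / step) + 1L)
    ix <- ix0:ix1; iy <- iy0:iy1
    sub <- fine$values[iy, ix, drop = FALSE]
    dd2 <- (pts$dose[i] - sub)^2
    dist2 <- outer((fine$y[iy] - pts$y[i])^2, (fine$x[ix] - pts$x[i])^2,
                   "+")
    g2 <- dd2 * inv_tol2[iy, ix, drop = FALSE] + dist2 * inv_dta2
    g2[dist2 > radius^2 + 1e-12] <- Inf
    gam[i] <- sqrt(min(g2))
  }
  res <- data.frame(x = pts$x, y = pts$y, eval = pts$dose,
                    ref_here = ref_here, gamma = gam,
                    local_err_pct = 100 * (pts$dose - ref_here) / ref_here)
  structure(list(points = res,
                 passing_rate = 100 * mean(gam <= 1 + 1e-9),
                 n = nrow(res), criteria = crit),
            class = "gamma_result")
}

#' @export
print.gamma_result <- function(x, ...) {
  cat(sprintf("gamma %s: passing rate %.1f%% (n = %d), mean gamma %.3f\n",
              paste0(x$criteria$dose_tolerance, "%",
                     if (x$criteria$normalization == "global") "G" else "L",
                     "/", x$criteria$dta, "mm"),
              x$passing_rate, x$n, mean(x$points$gamma)))
  invisible(x)
}

#' Local dose-error statistics
#'
#' Per-point locally normalized percent errors `100 (eval - ref) / ref`
#' over points receiving at least `threshold` percent of the maximum
#' reference dose, with mean, median, sd and a 1%-bin histogram.
#'
#' @param eval_dose,ref_dose numeric vectors of paired doses.
#' @param threshold exclusion threshold, percent of `max(ref_dose)`.
#' @return A list of class `local_error_stats`.
#' @export
local_error_stats <- function(eval_dose, ref_dose, threshold = 10) {
  stopifnot(length(eval_dose) == length(ref_dose))
  keep <- ref_dose >= threshold / 100 * max(ref_dose)
  err <- 100 * (eval_dose[keep] - ref_dose[keep]) / ref_dose[keep]
  if (!length(err)) stop("no points above the dose threshold")
  breaks <- seq(floor(min(err)) - 0.5, ceiling(max(err)) + 0.5, by = 1)
  h <- graphics::hist(err, breaks = breaks, plot = FALSE)
  structure(list(mean = mean(err), median = stats::median(err),
                 sd = stats::sd(err), n = length(err),
                 errors = err,
                 histogram = data.frame(mid = h$mids, count = h$counts)),
            class = "local_error_stats")
}

#' @export
print.local_error_stats <- function(x, ...) {
  cat(sprintf("local dose errors: mean %.2f%%, median %.2f%%, sd %.2f%% (n = %d)\n",
              x$mean, x$median, x$sd, x$n))
  invisible(x)
}

# round a limit toward zero at one decimal (the reporting convention
# used with commissioning confidence limits: 0.0 +/- 1.1 -> +/- 2.1)
.round_toward_zero <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 1e-9) / f
}

#' TG-119-style confidence limit
#'
#' For error distributions, the two-sided 95% limit `mean +/- 1.96 sd`;
#' for passing rates, the lower limit `mean - 1.96 sd` (upper end 100).
#' `sd` is the sample standard deviation. Both the raw limits and the
#' reporting-style values (rounded toward zero at one decimal) are
#' returned.
#'
#' @param values percent values (errors or passing rates).
#' @param direction `"two_sided_error"` or `"lower_passing"`.
#' @return A list of class `confidence_limit`: `mean`, `sd`, `n`,
#'   `raw` (limit vector), `reported` (rounded).
#' @export
#' @examples
#' confidence_limit(c(-1, 0, 1), "two_sided_error")
confidence_limit <- function(values,
                             direction = c("two_sided_error",
                                           "lower_passing")) {
  direction <- match.arg(direction)
  stopifnot(length(values) >= 2)
  m <- mean(values)
  s <- stats::sd(values)
  raw <- if (direction == "two_sided_error")
    c(lower = m - 1.96 * s, upper = m + 1.96 * s)
  else c(lower = min(m - 1.96 * s, 100), upper = 100)
  reported <- .round_toward_zero(raw)
  if (direction == "lower_passing") reported["upper"] <- 100
  structure(list(mean = m, sd = s, n = length(values),
                 direction = direction, raw = raw, reported = reported),
            class = "confidence_limit")
}

#' @export
print.confidence_limit <- function(x, ...) {
  cat(sprintf("95%% confidence limit (%s): [%.2f, %.2f] (reported %.1f to %.1f); mean %.2f, sd %.2f, n %d\n",
              x$direction, x$raw[1], x$raw[2], x$reported[1],
              x$reported[2], x$mean, x$sd, x$n))
  invisible(x)
}
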