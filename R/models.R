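# Closed-form areal density / magnification models of eccentricity.

#' Power-law density model
#'
#' A three-parameter power law of eccentricity, `scale * (offset + E)^-exponent`.
#' With the default coefficients of [cortical_magnification()] it gives the V1
#' areal magnification factor in mm^2/deg^2; with those of [lgn_parvo_density()]
#' it gives the parvocellular LGN cell density in cells/deg^2. A positive
#' `offset` keeps the value finite at the fovea (E = 0).
#'
#' @param scale Positive multiplicative coefficient.
#' @param offset Positive horizontal offset in degrees.
#' @param exponent Positive exponent applied with a negative sign.
#' @return An object of class `power_law_model`.
#' @examples
#' m <- power_law_model(103, 0.82, 2.28)
#' predict(m, E = 3)
#' @export
power_law_model <- function(scale, offset, exponent) {
  check_positive_scalar(scale, "scale")
  check_positive_scalar(offset, "offset")
  check_positive_scalar(exponent, "exponent")
  structure(list(scale = scale, offset = offset, exponent = exponent),
            class = "power_law_model")
}

#' Shifted-parabola density model
#'
#' A four-parameter model `scale * (floor + (E - center)^2)^-exponent`: a power
#' law of a parabola in eccentricity, peaking at `E = center`. With the default
#' coefficients of [lgn_magno_density()] it gives the magnocellular LGN cell
#' density, which is maximal parafoveally rather than at fixation.
#'
#' @param scale Positive multiplicative coefficient.
#' @param floor Positive parabola floor in deg^2 (keeps the base positive).
#' @param center Eccentricity of the peak, in degrees.
#' @param exponent Positive exponent applied with a negative sign.
#' @return An object of class `shifted_parabola_model`.
#' @examples
#' m <- shifted_parabola_model(2620.2, 5.5638, 1.8322, 0.8012)
#' predict(m, E = m$center)  # the maximum
#' @export
shifted_parabola_model <- function(scale, floor, center, exponent) {
  check_positive_scalar(scale, "scale")
  check_positive_scalar(floor, "floor")
  check_positive_scalar(exponent, "exponent")
  if (!is.numeric(center) || length(center) != 1L || !is.finite(center))
    stop("'center' must be a finite numeric scalar", call. = FALSE)
  structure(list(scale = scale, floor = floor, center = center,
                 exponent = exponent),
            class = "shifted_parabola_model")
}

#' Density anchor table
#'
#' An ordered table of (eccentricity, density) anchors for piecewise-linear
#' interpolation, used for retinal ganglion cell densities where only tabulated
#' values (not a fitted closed form) are available.
#'
#' @param eccentricity Strictly increasing eccentricities in degrees
#'   (at least two).
#' @param density Positive densities in cells/deg^2, one per eccentricity.
#' @return An object of class `density_anchor_table`.
#' @examples
#' density_anchor_table(c(2, 5), c(8500, 3000))
#' @export
density_anchor_table <- function(eccentricity, density) {
  if (length(eccentricity) < 2L)
    stop("anchor table needs at least 2 anchors", call. = FALSE)
  if (length(density) != length(eccentricity))
    stop("'eccentricity' and 'density' must have equal length", call. = FALSE)
  if (!all(is.finite(eccentricity)) || !all(is.finite(density)))
    stop("anchors must be finite", call. = FALSE)
  if (any(diff(eccentricity) <= 0))
    stop("anchor eccentricities must be strictly increasing", call. = FALSE)
  if (any(density <= 0))
    stop("anchor densities must be positive", call. = FALSE)
  structure(list(eccentricity = as.numeric(eccentricity),
                 density = as.numeric(density)),
            class = "density_anchor_table")
}

#' @export
predict.power_law_model <- function(object, E, ...) {
  check_eccentricity(E)
  object$scale * (object$offset + E)^(-object$exponent)
}

#' @export
predict.shifted_parabola_model <- function(object, E, ...) {
  check_eccentricity(E)
  object$scale * (object$floor + (E - object$center)^2)^(-object$exponent)
}

#' @export
print.power_law_model <- function(x, ...) {
  cat(sprintf("Power-law model: %.6g * (%.6g + E)^-%.6g\n",
              x$scale, x$offset, x$exponent))
  invisible(x)
}

#' @export
print.shifted_parabola_model <- function(x, ...) {
  cat(sprintf("Shifted-parabola model: %.6g * (%.6g + (E - %.6g)^2)^-%.6g\n",
              x$scale, x$floor, x$center, x$exponent))
  invisible(x)
}

#' @export
print.density_anchor_table <- function(x, ...) {
  cat("Density anchor table (cells/deg^2):\n")
  print(data.frame(eccentricity = x$eccentricity, density = x$density),
        row.names = FALSE)
  invisible(x)
}

#' Areal cortical magnification
#'
#' Evaluates the V1 areal cortical magnification factor M(E): the cortical
#' surface in mm^2 devoted to one deg^2 of visual field at eccentricity E. The
#' default model is `103 * (0.82 + E)^-2.28`, a fit to macaque V1; M is
#' strictly decreasing in E.
#'
#' @param E Eccentricity in degrees (vectorised, must be >= 0). Values beyond
#'   20 deg are accepted with a warning, since the fit derives from
#'   parafoveal/peripheral data of unstated extent.
#' @param model A [power_law_model()]; defaults to the macaque V1 fit.
#' @return Areal magnification in mm^2/deg^2.
#' @examples
#' cortical_magnification(3)   # ~4.85 mm^2/deg^2
#' @export
cortical_magnification <- function(E, model = default_models()$v1_magnification) {
  warn_far_periphery(E)
  predict(model, E)
}

#' Parvocellular LGN cell density
#'
#' Evaluates the parvocellular LGN cell magnification N_P(E) in cells/deg^2,
#' by default `1,011,688 * (2.9144 + E)^-2.6798` (macaque); strictly
#' decreasing in E.
#'
#' @inheritParams cortical_magnification
#' @param model A [power_law_model()]; defaults to the macaque parvo fit.
#' @return Cell density in cells/deg^2.
#' @examples
#' lgn_parvo_density(3)
#' @export
lgn_parvo_density <- function(E, model = default_models()$lgn_parvo) {
  warn_far_periphery(E)
  predict(model, E)
}

#' Magnocellular LGN cell density
#'
#' Evaluates the magnocellular LGN cell magnification N_M(E) in cells/deg^2,
#' by default `2,620.2 * (5.5638 + (E - 1.8322)^2)^-0.8012` (macaque). The
#' density is unimodal with its peak at `model$center` (1.8322 deg by default).
#'
#' @inheritParams cortical_magnification
#' @param model A [shifted_parabola_model()]; defaults to the macaque magno fit.
#' @return Cell density in cells/deg^2.
#' @examples
#' lgn_magno_density(3)
#' @export
lgn_magno_density <- function(E, model = default_models()$lgn_magno) {
  warn_far_periphery(E)
  predict(model, E)
}

#' Retinal ganglion cell density
#'
#' Piecewise-linear interpolation of retinal ganglion cell (RGC) density
#' between tabulated anchors; the default anchors are 8,500 cells/deg^2 at
#' 2 deg and 3,000 cells/deg^2 at 5 deg eccentricity (macaque, binocular
#' viewing, 90% of RGCs projecting to LGN). Anchor densities are reproduced
#' exactly. Eccentricities outside the anchor range are refused by default:
#' the two-point table carries no information there.
#'
#' @param E Eccentricity in degrees (vectorised, must be >= 0).
#' @param table A [density_anchor_table()]; defaults to the macaque anchors.
#' @param extrapolate If `TRUE`, extend the boundary segments linearly beyond
#'   the anchor range (with a warning) instead of erroring.
#' @return RGC density in cells/deg^2.
#' @examples
#' rgc_density(3)  # 6666.67 cells/deg^2
#' @export
rgc_density <- function(E, table = default_models()$rgc_anchors,
                        extrapolate = FALSE) {
  check_eccentricity(E)
  lo <- min(table$eccentricity)
  hi <- max(table$eccentricity)
  outside <- E < lo | E > hi
  if (any(outside)) {
    if (!extrapolate)
      stop(sprintf(paste0("eccentricity %s outside the RGC anchor range ",
                          "[%g, %g] deg; set extrapolate = TRUE to extend ",
                          "the boundary segments linearly"),
                   paste(format(E[outside]), collapse = ", "), lo, hi),
           call. = FALSE)
    warning(sprintf("extrapolating RGC density outside the anchor range [%g, %g] deg",
                    lo, hi), call. = FALSE)
  }
  f <- stats::approxfun(table$eccentricity, table$density, rule = 2)
  out <- f(E)
  # rule = 2 clamps; replace clamped values by linear extension of the end segments
  if (any(outside)) {
    n <- length(table$eccentricity)
    below <- E < lo
    above <- E > hi
    slope_lo <- (table$density[2L] - table$density[1L]) /
      (table$eccentricity[2L] - table$eccentricity[1L])
    slope_hi <- (table$density[n] - table$density[n - 1L]) /
      (table$eccentricity[n] - table$eccentricity[n - 1L])
    out[below] <- table$density[1L] + slope_lo * (E[below] - lo)
    out[above] <- table$density[n] + slope_hi * (E[above] - hi)
  }
  out
}

# ---- internal validation helpers ----

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop(sprintf("'%s' must be a positive finite scalar (got %s)",
                 name, paste(format(x), collapse = ", ")), call. = FALSE)
  invisible(x)
}

check_eccentricity <- function(E) {
  if (!is.numeric(E) || length(E) == 0L || any(!is.finite(E)))
    stop("eccentricity must be finite numeric", call. = FALSE)
  if (any(E < 0))
    stop(sprintf("eccentricity must be >= 0 deg (got %s)",
                 paste(format(E[E < 0]), collapse = ", ")), call. = FALSE)
  invisible(E)
}

warn_far_periphery <- function(E, limit = 20) {
  if (is.numeric(E) && any(is.finite(E) & E > limit))
    warning(sprintf("eccentricity beyond %g deg: the density fits come from data of unstated peripheral extent",
                    limit), call. = FALSE)
  invisible(E)
}
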