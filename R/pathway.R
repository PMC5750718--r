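# Per-stage neuron counts, V1 bounds, paper-style rounding and expansion ratios.

#' Stimulus specification
#'
#' @param area Stimulus area in deg^2 (>= 0).
#' @param eccentricity Eccentricity of the stimulus center in degrees.
#' @param width,height Optional extent in degrees for integrated mode; their
#'   product must equal `area` to within 1e-9.
#' @return An object of class `stimulus_spec`.
#' @examples
#' stimulus_spec(1, 3)
#' @export
stimulus_spec <- function(area, eccentricity, width = NULL, height = NULL) {
  if (!is.numeric(area) || length(area) != 1L || !is.finite(area) || area < 0)
    stop("'area' must be a finite scalar >= 0", call. = FALSE)
  check_eccentricity(eccentricity)
  if (length(eccentricity) != 1L)
    stop("'eccentricity' must be a scalar", call. = FALSE)
  if (xor(is.null(width), is.null(height)))
    stop("give both 'width' and 'height' or neither", call. = FALSE)
  if (!is.null(width)) {
    if (width <= 0 || height <= 0)
      stop("'width' and 'height' must be positive", call. = FALSE)
    if (abs(width * height - area) > 1e-9)
      stop(sprintf("width * height (%g) must equal area (%g)",
                   width * height, area), call. = FALSE)
  }
  structure(list(area = area, eccentricity = eccentricity,
                 width = width, height = height),
            class = "stimulus_spec")
}

#' Anatomical parameters of the V1 counting chain
#'
#' All anatomical assumptions entering the V1 neuron count, exposed as
#' parameters. Defaults are for macaque V1: layers 2/3/4B span about 0.75 mm
#' of depth, about 80% of V1 neurons are excitatory (pyramidal, projecting to
#' higher cortex), cortical density is about 120,000 neurons/mm^3, about 75%
#' of neurons across layers 2/3/4B have orientation bandwidth below 30 deg,
#' and calcium imaging suggests 55% of neurons in a small volume respond to at
#' least one visual stimulus (the rest being potentially silent).
#'
#' @param laminar_depth Depth of the output layers (2/3/4B), mm.
#' @param excitatory_fraction Excitatory share of V1 neurons, in [0, 1].
#' @param v1_density Cortical neuron density, neurons/mm^3.
#' @param tuned_fraction Share of neurons orientation-tuned (bandwidth < 30
#'   deg), in [0, 1].
#' @param responsive_fraction Share of neurons visually responsive (non-silent),
#'   in [0, 1].
#' @return An object of class `anatomy_params`.
#' @export
anatomy_params <- function(laminar_depth = 0.75, excitatory_fraction = 0.8,
                           v1_density = 120000, tuned_fraction = 0.75,
                           responsive_fraction = 0.55) {
  check_positive_scalar(laminar_depth, "laminar_depth")
  check_positive_scalar(v1_density, "v1_density")
  for (nm in c("excitatory_fraction", "tuned_fraction", "responsive_fraction")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must be a fraction in [0, 1]", nm), call. = FALSE)
  }
  structure(list(laminar_depth = laminar_depth,
                 excitatory_fraction = excitatory_fraction,
                 v1_density = v1_density,
                 tuned_fraction = tuned_fraction,
                 responsive_fraction = responsive_fraction),
            class = "anatomy_params")
}

#' Activated cortical surface
#'
#' Cortical surface in mm^2 activated by a stimulus. In `point` mode (the
#' default) the areal magnification is evaluated at the stimulus-center
#' eccentricity and multiplied by the stimulus area. In `integrated` mode the
#' stimulus footprint is approximated as an eccentricity band of the stimulus
#' height centered on the stimulus eccentricity, and the magnification is
#' integrated across the band and multiplied by the stimulus width; as the
#' extent shrinks to zero the two modes agree.
#'
#' @param stim A [stimulus_spec()]. Integrated mode requires an extent
#'   (width/height), or a square extent is inferred from the area.
#' @param model A [power_law_model()] for the areal magnification.
#' @param mode `"point"` or `"integrated"`.
#' @return Surface in mm^2.
#' @examples
#' cortical_surface(stimulus_spec(1, 3))  # ~4.85 mm^2
#' @export
cortical_surface <- function(stim, model = default_models()$v1_magnification,
                             mode = c("point", "integrated")) {
  if (!is.character(mode) || !all(mode %in% c("point", "integrated")))
    stop(sprintf("unknown surface mode '%s': use 'point' or 'integrated'",
                 paste(mode, collapse = ", ")), call. = FALSE)
  mode <- match.arg(mode)
  if (stim$area == 0) return(0)
  if (mode == "point")
    return(stim$area * cortical_magnification(stim$eccentricity, model))
  w <- stim$width
  h <- stim$height
  if (is.null(w)) {
    w <- sqrt(stim$area)
    h <- w
  }
  lower <- stim$eccentricity - h / 2
  upper <- stim$eccentricity + h / 2
  if (lower < 0)
    stop(sprintf("integration band [%g, %g] extends below 0 deg eccentricity",
                 lower, upper), call. = FALSE)
  warn_far_periphery(upper)
  band <- stats::integrate(function(e) predict(model, e), lower, upper,
                           rel.tol = 1e-10)
  w * band$value
}

#' Effective cortical depth
#'
#' Depth of the excitatory (pyramidal) population of the output layers:
#' `laminar_depth * excitatory_fraction`. With the defaults,
#' 0.75 mm x 0.8 = 0.6 mm.
#'
#' @param params An [anatomy_params()].
#' @return Effective depth in mm.
#' @export
effective_depth <- function(params = anatomy_params()) {
  params$laminar_depth * params$excitatory_fraction
}

#' Upper bound on the activated V1 neuron count
#'
#' Surface x effective depth x cortical density: the count assuming every
#' neuron in the activated volume contributes to the task regardless of its
#' tuning. `rounded = TRUE` applies the rounded-intermediate reporting
#' convention (surface rounded to the mm^2, volume to the mm^3, count to the
#' nearest 10,000), which reproduces the figures as conventionally quoted;
#' `rounded = FALSE` carries the chain at full precision.
#'
#' @inheritParams cortical_surface
#' @param params An [anatomy_params()].
#' @param rounded Apply the rounded-intermediate reporting convention.
#' @param grains Named grains as in `default_config()$rounding`.
#' @return Neuron count (a real number; see Details on rounding).
#' @examples
#' v1_upper(stimulus_spec(1, 3))                  # 349,193 (full precision)
#' v1_upper(stimulus_spec(1, 3), rounded = TRUE)  # 360,000
#' @export
v1_upper <- function(stim, model = default_models()$v1_magnification,
                     params = anatomy_params(), mode = "point",
                     rounded = FALSE, grains = default_config()$rounding) {
  surface <- cortical_surface(stim, model, mode)
  depth <- effective_depth(params)
  if (!rounded)
    return(surface * depth * params$v1_density)
  surface_r <- round_paper_style(surface, grains$surface)
  volume_r <- round_paper_style(surface_r * depth, grains$volume)
  round_paper_style(volume_r * params$v1_density, grains$v1)
}

#' Lower bound on the task-relevant V1 neuron count (tuned neurons)
#'
#' `tuned_fraction` x [v1_upper()]: only neurons selective for orientation
#' (bandwidth < 30 deg) are counted. In rounded mode the fraction is applied
#' to the rounded upper bound and the product re-rounded at the V1 grain.
#'
#' @inheritParams v1_upper
#' @return Neuron count.
#' @export
v1_lower_tuned <- function(stim, model = default_models()$v1_magnification,
                           params = anatomy_params(), mode = "point",
                           rounded = FALSE, grains = default_config()$rounding) {
  upper <- v1_upper(stim, model, params, mode, rounded, grains)
  out <- params$tuned_fraction * upper
  if (rounded) round_paper_style(out, grains$v1) else out
}

#' Loose lower bound on the task-relevant V1 neuron count
#'
#' `tuned_fraction` x `responsive_fraction` x [v1_upper()]: additionally
#' discounts neurons that may be entirely silent (undetected by extracellular
#' recording), assuming silent neurons do not contribute to the task.
#'
#' @inheritParams v1_upper
#' @return Neuron count.
#' @export
v1_lower_loose <- function(stim, model = default_models()$v1_magnification,
                           params = anatomy_params(), mode = "point",
                           rounded = FALSE, grains = default_config()$rounding) {
  upper <- v1_upper(stim, model, params, mode, rounded, grains)
  out <- params$tuned_fraction * params$responsive_fraction * upper
  if (rounded) round_paper_style(out, grains$v1) else out
}

#' LGN neuron count
#'
#' Parvocellular and magnocellular LGN counts for a stimulus: stimulus area
#' times the respective cell density at the stimulus-center eccentricity, plus
#' their total.
#'
#' @param stim A [stimulus_spec()].
#' @param parvo_model A [power_law_model()] for the parvocellular density.
#' @param magno_model A [shifted_parabola_model()] for the magnocellular
#'   density.
#' @return Named numeric vector with elements `parvo`, `magno`, `total`.
#' @examples
#' lgn_count(stimulus_spec(1, 3))  # total ~9,195
#' @export
lgn_count <- function(stim, parvo_model = default_models()$lgn_parvo,
                      magno_model = default_models()$lgn_magno) {
  if (stim$area == 0) return(c(parvo = 0, magno = 0, total = 0))
  p <- stim$area * lgn_parvo_density(stim$eccentricity, parvo_model)
  m <- stim$area * lgn_magno_density(stim$eccentricity, magno_model)
  c(parvo = p, magno = m, total = p + m)
}

#' Retinal ganglion cell count
#'
#' Stimulus area times the interpolated RGC density at the stimulus-center
#' eccentricity.
#'
#' @param stim A [stimulus_spec()].
#' @param table A [density_anchor_table()].
#' @param extrapolate Passed to [rgc_density()].
#' @return RGC count.
#' @examples
#' rgc_count(stimulus_spec(1, 3))  # 6,666.67
#' @export
rgc_count <- function(stim, table = default_models()$rgc_anchors,
                      extrapolate = FALSE) {
  if (stim$area == 0) return(0)
  stim$area * rgc_density(stim$eccentricity, table, extrapolate)
}

#' Round a value half-up to a reporting grain
#'
#' Half-up rounding to a stage-specific grain, the convention under which the
#' conventionally quoted "approximately" figures reproduce exactly (e.g.
#' 148,500 at grain 10,000 rounds up to 150,000, where banker's rounding
#' would not). Idempotent on already-rounded values.
#'
#' @param value Nonnegative numeric (vectorised).
#' @param grain Positive rounding grain (e.g. 10,000 for V1 counts, 1,000 for
#'   LGN, 500 for RGC, 1 for mm^2, mm^3 and ratios).
#' @return `value` rounded to the nearest multiple of `grain`, ties away from
#'   zero.
#' @examples
#' round_paper_style(148500, 10000)  # 150000
#' round_paper_style(9195, 1000)     # 9000
#' @export
round_paper_style <- function(value, grain) {
  if (!is.numeric(grain) || length(grain) != 1L || !is.finite(grain) || grain <= 0)
    stop(sprintf("unknown rounding grain '%s': must be a positive number",
                 paste(format(grain), collapse = ", ")), call. = FALSE)
  if (any(value < 0, na.rm = TRUE))
    stop("round_paper_style expects nonnegative values", call. = FALSE)
  floor(value / grain + 0.5) * grain
}

#' Expansion ratios between pathway stages
#'
#' LGN:V1 and RGC:V1 expansion ratios at both V1 bounds, computed from the
#' paper-rounded stage counts: the high ratio divides the rounded V1 upper
#' bound, and the low ratio the rounded loose lower bound, by the rounded
#' upstream count, each reported to the nearest integer (half-up). With the
#' default configuration these are 17-40 (LGN) and 23-55 (RGC).
#'
#' @param est A `pathway_estimate` from [estimate_pathway()].
#' @return An object of class `ratio_report`: a named numeric vector with
#'   elements `lgn_v1_low`, `lgn_v1_high`, `rgc_v1_low`, `rgc_v1_high`.
#' @export
expansion_ratios <- function(est) {
  r <- est$rounded
  if (!is.finite(r[["lgn_total"]]) || r[["lgn_total"]] <= 0 ||
      !is.finite(r[["rgc"]]) || r[["rgc"]] <= 0)
    stop("expansion ratios undefined: an upstream stage count is zero or unavailable",
         call. = FALSE)
  compute_ratios(r, est$config$rounding$ratio)
}

# Ratios from the rounded counts; an invalid (zero/NA) upstream stage yields NA.
compute_ratios <- function(rounded, grain) {
  ratio <- function(num, den) {
    if (is.finite(den) && den > 0) round_paper_style(num / den, grain)
    else NA_real_
  }
  structure(c(
    lgn_v1_low  = ratio(rounded[["v1_lower_loose"]], rounded[["lgn_total"]]),
    lgn_v1_high = ratio(rounded[["v1_upper"]], rounded[["lgn_total"]]),
    rgc_v1_low  = ratio(rounded[["v1_lower_loose"]], rounded[["rgc"]]),
    rgc_v1_high = ratio(rounded[["v1_upper"]], rounded[["rgc"]])
  ), class = "ratio_report")
}

#' Estimate the neuron counts of the whole pathway
#'
#' Orchestrates the full chain for one configuration: activated cortical
#' surface, effective depth and volume, V1 upper bound and tuned/loose lower
#' bounds, parvo/magno/total LGN counts and the RGC count — each carried both
#' at full precision (`raw`) and under the rounded-intermediate reporting
#' convention (`rounded`) — plus the expansion ratios. Deterministic: two runs
#' with the same configuration give identical results.
#'
#' @param config An `nc_config` list ([default_config()] reproduces the
#'   standard worked example: a 1 deg^2 stimulus at 3 deg eccentricity).
#' @param partial If `TRUE`, a failing stage (the RGC count when the
#'   eccentricity lies outside the anchor range) is reported as `NA` with a
#'   warning while the remaining stages are still computed; if `FALSE` (the
#'   default) such errors propagate.
#' @return An object of class `pathway_estimate` with components `raw` and
#'   `rounded` (named numeric vectors over `v1_surface`,
#'   `v1_effective_depth`, `v1_volume`, `v1_upper`, `v1_lower_tuned`,
#'   `v1_lower_loose`, `lgn_parvo`, `lgn_magno`, `lgn_total`, `rgc`),
#'   `ratios` (a `ratio_report`, or `NULL` with a warning when the stimulus
#'   area is zero) and `config` (the configuration used).
#' @examples
#' est <- estimate_pathway()
#' est$rounded[["v1_upper"]]  # 360000
#' @export
estimate_pathway <- function(config = default_config(), partial = FALSE) {
  config <- validate_config(config)
  models <- config_models(config)
  s <- config$stimulus
  stim <- stimulus_spec(s$area, s$eccentricity, s$width, s$height)
  params <- anatomy_params(config$v1$laminar_depth, config$v1$excitatory_fraction,
                           config$v1$density, config$v1$tuned_fraction,
                           config$v1$responsive_fraction)
  grains <- config$rounding
  mode <- s$mode

  surface <- cortical_surface(stim, models$v1_magnification, mode)
  depth <- effective_depth(params)
  lgn <- lgn_count(stim, models$lgn_parvo, models$lgn_magno)
  rgc <- if (partial) {
    tryCatch(rgc_count(stim, models$rgc_anchors, config$rgc$extrapolate),
             error = function(e) {
               warning(sprintf("RGC stage unavailable: %s", conditionMessage(e)),
                       call. = FALSE)
               NA_real_
             })
  } else {
    rgc_count(stim, models$rgc_anchors, config$rgc$extrapolate)
  }

  raw <- c(
    v1_surface = surface,
    v1_effective_depth = depth,
    v1_volume = surface * depth,
    v1_upper = surface * depth * params$v1_density,
    v1_lower_tuned = params$tuned_fraction * surface * depth * params$v1_density,
    v1_lower_loose = params$tuned_fraction * params$responsive_fraction *
      surface * depth * params$v1_density,
    lgn_parvo = lgn[["parvo"]],
    lgn_magno = lgn[["magno"]],
    lgn_total = lgn[["total"]],
    rgc = rgc
  )

  surface_r <- round_paper_style(surface, grains$surface)
  volume_r <- round_paper_style(surface_r * depth, grains$volume)
  upper_r <- round_paper_style(volume_r * params$v1_density, grains$v1)
  rounded <- c(
    v1_surface = surface_r,
    v1_effective_depth = depth,
    v1_volume = volume_r,
    v1_upper = upper_r,
    v1_lower_tuned = round_paper_style(params$tuned_fraction * upper_r, grains$v1),
    v1_lower_loose = round_paper_style(
      params$tuned_fraction * params$responsive_fraction * upper_r, grains$v1),
    lgn_parvo = round_paper_style(lgn[["parvo"]], grains$lgn),
    lgn_magno = round_paper_style(lgn[["magno"]], grains$lgn),
    lgn_total = round_paper_style(lgn[["total"]], grains$lgn),
    rgc = round_paper_style(rgc, grains$rgc)
  )

  est <- structure(list(raw = raw, rounded = rounded, ratios = NULL,
                        config = config),
                   class = "pathway_estimate")
  ok_lgn <- is.finite(rounded[["lgn_total"]]) && rounded[["lgn_total"]] > 0
  ok_rgc <- is.finite(rounded[["rgc"]]) && rounded[["rgc"]] > 0
  if (ok_lgn || ok_rgc) {
    est$ratios <- compute_ratios(rounded, grains$ratio)
    if (!ok_lgn || !ok_rgc)
      warning("some expansion ratios are undefined (zero or unavailable stage count)",
              call. = FALSE)
  } else {
    warning("expansion ratios are undefined for a zero stage count",
            call. = FALSE)
  }
  est
}

#' @export
print.pathway_estimate <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

#' @export
print.ratio_report <- function(x, ...) {
  cat(sprintf("Expansion ratios (rounded counts): LGN:V1 %d:1 to %d:1, RGC:V1 %d:1 to %d:1\n",
              as.integer(x[["lgn_v1_low"]]), as.integer(x[["lgn_v1_high"]]),
              as.integer(x[["rgc_v1_low"]]), as.integer(x[["rgc_v1_high"]])))
  invisible(x)
}

#' Flatten a pathway estimate to a one-row data frame
#'
#' One column per raw and rounded field (suffixed `_raw` / `_rounded`) plus
#' the four expansion ratios (NA when undefined); suitable for CSV output and
#' for stacking sweep results.
#'
#' @param x A `pathway_estimate`.
#' @param row.names,optional,... Ignored; present for method compatibility.
#' @return A one-row `data.frame`.
#' @export
as.data.frame.pathway_estimate <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  vals <- c(stats::setNames(as.list(x$raw), paste0(names(x$raw), "_raw")),
            stats::setNames(as.list(x$rounded), paste0(names(x$rounded), "_rounded")))
  ratio_names <- c("lgn_v1_low", "lgn_v1_high", "rgc_v1_low", "rgc_v1_high")
  if (is.null(x$ratios)) {
    vals[ratio_names] <- NA_real_
  } else {
    vals[ratio_names] <- as.list(unclass(x$ratios)[ratio_names])
  }
  as.data.frame(vals)
}
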