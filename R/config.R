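# Configuration: default constants, user overrides, validation.

.nc_cache <- new.env(parent = emptyenv())

#' Default run configuration
#'
#' Returns the built-in configuration: the default stimulus (1 deg^2 at 3 deg
#' eccentricity), the coefficients of the V1 magnification and LGN parvo/magno
#' density models, the RGC anchor table, the anatomical parameters of the V1
#' chain, and the half-up reporting grains. The defaults ship as a YAML
#' constants file (`system.file("extdata", "default_config.yaml",
#' package = "neurocensus")`) so that coefficients for other species can be
#' substituted wholesale; the file is read once per session and cached.
#'
#' @return A nested named list of class `nc_config` with sections `stimulus`,
#'   `v1`, `lgn`, `rgc` and `rounding`.
#' @examples
#' cfg <- default_config()
#' cfg$v1$density
#' @export
default_config <- function() {
  if (is.null(.nc_cache$default_config)) {
    path <- system.file("extdata", "default_config.yaml",
                        package = "neurocensus", mustWork = TRUE)
    .nc_cache$default_config <- as_nc_config(yaml::read_yaml(path))
  }
  .nc_cache$default_config
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML file of (possibly partial) overrides and merges it onto the
#' built-in defaults: any key present in the file replaces the default, keys
#' absent from the file keep their default, and unknown keys are rejected with
#' an error naming them.
#'
#' @param path Path to a YAML file structured like the default constants file.
#' @return A validated `nc_config` list.
#' @seealso [default_config()], [write_config()]
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop(sprintf("config file '%s' does not exist", path), call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) user <- list()
  as_nc_config(merge_config(default_config(), user, prefix = character()))
}

#' Write a run configuration to a YAML file
#'
#' Dumps the effective configuration so a run can be reproduced exactly from
#' the dump (`load_config()` of the written file round-trips).
#'
#' @param config An `nc_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' Checks structure (the five sections, no unknown keys) and every domain
#' constraint: positive model coefficients, fractions in (0, 1], positive
#' depths, densities and grains, a well-formed RGC anchor table, and a
#' consistent stimulus (area >= 0; if width/height are given their product
#' must equal the area).
#'
#' @param config A nested list as returned by [default_config()].
#' @return The validated config (classed `nc_config`), invisibly usable in all
#'   estimation functions. Errors name the offending key and constraint.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  config <- merge_config(default_config(), unclass(config), prefix = character())

  s <- config$stimulus
  if (!is.numeric(s$area) || length(s$area) != 1L || !is.finite(s$area) || s$area < 0)
    stop("stimulus.area: must be a finite scalar >= 0", call. = FALSE)
  if (!is.numeric(s$eccentricity) || length(s$eccentricity) != 1L ||
      !is.finite(s$eccentricity) || s$eccentricity < 0)
    stop("stimulus.eccentricity: must be a finite scalar >= 0", call. = FALSE)
  if (!s$mode %in% c("point", "integrated"))
    stop("stimulus.mode: must be 'point' or 'integrated'", call. = FALSE)
  if (xor(is.null(s$width), is.null(s$height)))
    stop("stimulus.width/height: give both or neither", call. = FALSE)
  if (!is.null(s$width)) {
    if (s$width <= 0 || s$height <= 0)
      stop("stimulus.width/height: must be positive", call. = FALSE)
    if (abs(s$width * s$height - s$area) > 1e-9)
      stop(sprintf("stimulus.width*height (%g) must equal stimulus.area (%g)",
                   s$width * s$height, s$area), call. = FALSE)
  }

  for (key in c("laminar_depth", "density")) {
    v <- config$v1[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("v1.%s: must be a positive finite scalar", key), call. = FALSE)
  }
  for (key in c("excitatory_fraction", "tuned_fraction", "responsive_fraction")) {
    v <- config$v1[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0 || v > 1)
      stop(sprintf("v1.%s: must be a fraction in [0, 1]", key), call. = FALSE)
  }

  # constructors enforce the per-model invariants
  config_models(config)

  if (!is.logical(config$rgc$extrapolate) || length(config$rgc$extrapolate) != 1L)
    stop("rgc.extrapolate: must be TRUE or FALSE", call. = FALSE)

  for (key in names(config$rounding)) {
    v <- config$rounding[[key]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop(sprintf("rounding.%s: must be a positive grain", key), call. = FALSE)
  }

  as_nc_config(config)
}

#' Build the density models declared in a configuration
#'
#' @param config An `nc_config` list.
#' @return A list with elements `v1_magnification` and `lgn_parvo`
#'   ([power_law_model()]), `lgn_magno` ([shifted_parabola_model()]) and
#'   `rgc_anchors` ([density_anchor_table()]).
#' @examples
#' m <- config_models(default_config())
#' predict(m$v1_magnification, 3)
#' @export
config_models <- function(config) {
  v <- config$v1$magnification
  p <- config$lgn$parvo
  m <- config$lgn$magno
  a <- config$rgc$anchors
  list(
    v1_magnification = power_law_model(v$scale, v$offset, v$exponent),
    lgn_parvo = power_law_model(p$scale, p$offset, p$exponent),
    lgn_magno = shifted_parabola_model(m$scale, m$floor, m$center, m$exponent),
    rgc_anchors = density_anchor_table(
      vapply(a, `[[`, numeric(1), "eccentricity"),
      vapply(a, `[[`, numeric(1), "density"))
  )
}

#' Default density models
#'
#' Convenience accessor for [config_models()] of [default_config()].
#'
#' @return See [config_models()].
#' @export
default_models <- function() {
  if (is.null(.nc_cache$default_models))
    .nc_cache$default_models <- config_models(default_config())
  .nc_cache$default_models
}

#' Read a scalar parameter from a configuration by path
#'
#' @param config An `nc_config` list.
#' @param path A dotted key path such as `"stimulus.eccentricity"` or
#'   `"v1.tuned_fraction"`.
#' @return The value at the path.
#' @seealso [config_set()], [config_paths()]
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node))
      stop_unknown_path(path)
    node <- node[[k]]
  }
  node
}

#' Set a scalar parameter in a configuration by path
#'
#' Returns a modified copy; the input config is never changed in place. The
#' result is revalidated so out-of-domain values fail with the constraint
#' named.
#'
#' @inheritParams config_get
#' @param value The new value.
#' @return The modified, validated `nc_config`.
#' @export
config_set <- function(config, path, value) {
  if (!path %in% config_paths())
    stop_unknown_path(path)
  keys <- strsplit(path, ".", fixed = TRUE)[[1L]]
  config[[keys]] <- value
  validate_config(config)
}

#' Enumerate the sweepable parameter paths
#'
#' @return Character vector of the dotted paths accepted by [config_set()],
#'   [sweep_pathway()] and [one_at_a_time()]: every numeric scalar leaf of the
#'   configuration.
#' @export
config_paths <- function() {
  c("stimulus.area", "stimulus.eccentricity",
    "v1.magnification.scale", "v1.magnification.offset", "v1.magnification.exponent",
    "v1.laminar_depth", "v1.excitatory_fraction", "v1.density",
    "v1.tuned_fraction", "v1.responsive_fraction",
    "lgn.parvo.scale", "lgn.parvo.offset", "lgn.parvo.exponent",
    "lgn.magno.scale", "lgn.magno.floor", "lgn.magno.center", "lgn.magno.exponent",
    "rounding.surface", "rounding.volume", "rounding.v1", "rounding.lgn",
    "rounding.rgc", "rounding.ratio")
}

stop_unknown_path <- function(path) {
  stop(sprintf("unknown parameter path '%s'; valid paths:\n  %s",
               path, paste(config_paths(), collapse = "\n  ")), call. = FALSE)
}

as_nc_config <- function(x) {
  class(x) <- "nc_config"
  x
}

#' @export
print.nc_config <- function(x, ...) {
  cat("neurocensus run configuration\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}

# Merge user overrides onto defaults, rejecting keys absent from the defaults.
merge_config <- function(default, user, prefix) {
  if (!is.list(user)) stop("config overrides must be a named list", call. = FALSE)
  # the anchors list is a sequence, replaced wholesale
  unknown <- setdiff(names(user), names(default))
  if (length(unknown) > 0L)
    stop(sprintf("unknown config key%s: %s",
                 if (length(unknown) > 1L) "s" else "",
                 paste(paste_path(prefix, unknown), collapse = ", ")),
         call. = FALSE)
  out <- unclass(default)
  for (k in names(user)) {
    if (is.list(default[[k]]) && !is.null(names(default[[k]])) &&
        k != "anchors" && is.list(user[[k]])) {
      out[[k]] <- merge_config(default[[k]], user[[k]], c(prefix, k))
    } else {
      out[k] <- list(user[[k]])  # preserves NULL (width/height)
    }
  }
  out
}

paste_path <- function(prefix, keys) {
  if (length(prefix) == 0L) keys
  else paste(paste(prefix, collapse = "."), keys, sep = ".")
}
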