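# Deterministic sensitivity analysis: grid sweeps and one-at-a-time perturbation.

#' Sweep one parameter over a grid
#'
#' Re-runs [estimate_pathway()] once per grid value with all other parameters
#' held at the base configuration, and stacks the flattened estimates into a
#' data frame in grid order. The whole grid is validated before any row is
#' computed, so an invalid value fails fast naming the parameter and value;
#' the base configuration is never modified.
#'
#' @param base_config An `nc_config` list; defaults to [default_config()].
#' @param parameter A dotted parameter path from [config_paths()], e.g.
#'   `"stimulus.eccentricity"` or `"v1.tuned_fraction"`.
#' @param grid Numeric vector of values to evaluate, in the order given.
#' @param long If `TRUE`, return long format with columns `grid_value`,
#'   `output` and `value` instead of one wide row per grid point.
#' @return A `data.frame` with one row per grid value (wide format: a
#'   `parameter` and a `grid_value` column followed by the columns of
#'   [as.data.frame.pathway_estimate()]).
#' @examples
#' sweep_pathway(parameter = "stimulus.eccentricity",
#'               grid = c(2, 3, 5))[, c("grid_value", "rgc_raw")]
#' @export
sweep_pathway <- function(base_config = default_config(), parameter, grid,
                          long = FALSE) {
  if (!is.numeric(grid) || length(grid) == 0L)
    stop("'grid' must be a non-empty numeric vector", call. = FALSE)
  # validate every grid value up front: no partial output on failure
  configs <- lapply(grid, function(v) {
    tryCatch(config_set(base_config, parameter, v),
             error = function(e) stop(sprintf(
               "invalid value %g for parameter '%s': %s",
               v, parameter, conditionMessage(e)), call. = FALSE))
  })
  rows <- lapply(configs, function(cfg) as.data.frame(estimate_pathway(cfg)))
  wide <- cbind(data.frame(parameter = parameter, grid_value = grid),
                do.call(rbind, rows))
  rownames(wide) <- NULL
  if (!long) return(wide)
  out_cols <- setdiff(names(wide), c("parameter", "grid_value"))
  long_df <- data.frame(
    parameter = parameter,
    grid_value = rep(wide$grid_value, each = length(out_cols)),
    output = rep(out_cols, times = nrow(wide)),
    value = as.vector(t(as.matrix(wide[, out_cols])))
  )
  rownames(long_df) <- NULL
  long_df
}

#' One-at-a-time relative perturbation analysis
#'
#' For each named parameter, evaluates the pathway at `base * (1 - delta)` and
#' `base * (1 + delta)` with every other parameter fixed, and stacks the
#' results together with the unperturbed base row. A perturbation that leaves
#' a parameter's domain is reported as an error for that parameter (via a
#' warning naming it) while the remaining parameters are still computed.
#'
#' @param base_config An `nc_config` list; defaults to [default_config()].
#' @param perturbations Named numeric vector mapping parameter paths to
#'   relative changes, e.g. `c(v1.density = 0.1)` for +/-10%.
#' @return A `data.frame` with columns `parameter`, `direction` (`"low"`,
#'   `"base"` or `"high"`), `value` (the parameter value used) and the
#'   flattened estimate columns. The base row has parameter `"(base)"`.
#'   Parameters whose perturbed value failed validation are absent from the
#'   output and listed in the `failed` attribute.
#' @examples
#' oat <- one_at_a_time(perturbations = c(v1.density = 0.1))
#' oat[, c("parameter", "direction", "v1_upper_raw")]
#' @export
one_at_a_time <- function(base_config = default_config(), perturbations) {
  if (is.null(names(perturbations)) || any(!nzchar(names(perturbations))))
    stop("'perturbations' must be a named numeric vector", call. = FALSE)
  base_row <- cbind(data.frame(parameter = "(base)", direction = "base",
                               value = NA_real_),
                    as.data.frame(estimate_pathway(base_config)))
  rows <- list(base_row)
  failed <- character()
  for (p in names(perturbations)) {
    delta <- perturbations[[p]]
    base_value <- config_get(base_config, p)
    res <- tryCatch({
      lo <- base_value * (1 - delta)
      hi <- base_value * (1 + delta)
      lo_est <- as.data.frame(estimate_pathway(config_set(base_config, p, lo)))
      hi_est <- as.data.frame(estimate_pathway(config_set(base_config, p, hi)))
      rbind(cbind(data.frame(parameter = p, direction = "low", value = lo), lo_est),
            cbind(data.frame(parameter = p, direction = "high", value = hi), hi_est))
    }, error = function(e) {
      warning(sprintf("perturbation of '%s' failed: %s", p,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (is.null(res)) failed <- c(failed, p) else rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "failed") <- failed
  out
}
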