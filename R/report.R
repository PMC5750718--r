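# Report rendering: plain-text report, CSV row, atomic writes.

#' Format a pathway estimate as a plain-text report
#'
#' Renders the per-stage counts with both the full-precision values (6
#' significant digits) and the paper-rounded reporting column, the expansion
#' ratios, and a provenance block echoing every parameter used.
#'
#' @param est A `pathway_estimate`.
#' @param provenance Include the YAML parameter block.
#' @return Character vector of report lines.
#' @export
format_report <- function(est, provenance = TRUE) {
  s <- est$config$stimulus
  labels <- c(
    v1_surface = "V1 surface (mm^2)",
    v1_effective_depth = "V1 effective depth (mm)",
    v1_volume = "V1 effective volume (mm^3)",
    v1_upper = "V1 upper bound (neurons)",
    v1_lower_tuned = "V1 lower bound, tuned (neurons)",
    v1_lower_loose = "V1 loose lower bound (neurons)",
    lgn_parvo = "LGN parvocellular (cells)",
    lgn_magno = "LGN magnocellular (cells)",
    lgn_total = "LGN total (cells)",
    rgc = "RGC (cells)"
  )
  lines <- c(
    "Visual pathway neuron count estimate",
    "====================================",
    sprintf("Stimulus: %g deg^2 at %g deg eccentricity (%s mode)",
            s$area, s$eccentricity, s$mode),
    "",
    sprintf("%-33s %14s %14s", "stage", "raw", "rounded"),
    vapply(names(labels), function(k) {
      sprintf("%-33s %14s %14s", labels[[k]],
              format(signif(est$raw[[k]], 6), big.mark = ",", scientific = FALSE),
              format(est$rounded[[k]], big.mark = ",", scientific = FALSE))
    }, character(1)),
    ""
  )
  if (is.null(est$ratios)) {
    lines <- c(lines, "Expansion ratios: undefined (zero upstream stage count)")
  } else {
    r <- est$ratios
    lines <- c(lines,
               sprintf("Expansion ratios (from rounded counts):"),
               sprintf("  LGN:V1  %d:1 to %d:1",
                       as.integer(r[["lgn_v1_low"]]), as.integer(r[["lgn_v1_high"]])),
               sprintf("  RGC:V1  %d:1 to %d:1",
                       as.integer(r[["rgc_v1_low"]]), as.integer(r[["rgc_v1_high"]])))
  }
  if (provenance) {
    lines <- c(lines, "", "Parameters:",
               paste0("  ", strsplit(yaml::as.yaml(unclass(est$config)), "\n")[[1L]]))
  }
  lines
}

#' Write a pathway report to disk
#'
#' Writes the plain-text report and/or the one-row CSV. Files are written
#' atomically: the output appears complete or not at all.
#'
#' @param est A `pathway_estimate`.
#' @param text_path,csv_path Output paths; `NULL` skips that format.
#' @return Invisibly, the paths written.
#' @export
write_report <- function(est, text_path = NULL, csv_path = NULL) {
  written <- character()
  if (!is.null(text_path)) {
    atomic_write(text_path, function(tmp)
      writeLines(format_report(est), tmp))
    written <- c(written, text_path)
  }
  if (!is.null(csv_path)) {
    atomic_write(csv_path, function(tmp)
      utils::write.csv(as.data.frame(est), tmp, row.names = FALSE))
    written <- c(written, csv_path)
  }
  invisible(written)
}

#' Write a sweep table to CSV atomically
#'
#' @param table A data frame from [sweep_pathway()] or [one_at_a_time()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sweep_csv <- function(table, path) {
  atomic_write(path, function(tmp)
    utils::write.csv(table, tmp, row.names = FALSE))
  invisible(path)
}

# Write via a temp file in the target directory, then rename into place.
atomic_write <- function(path, writer) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("could not move output into place at '%s'", path),
         call. = FALSE)
  invisible(path)
}
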