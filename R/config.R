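# Run configuration and the end-to-end orchestrator behind the command-line
# interface.

#' Assemble a run configuration
#'
#' Collects every tunable of the pipeline with its default: neighbor graph
#' (`k = 30`, `radius = 50` um, `orphan_min_n = 1`), assignment optimization
#' (`n_initial = 2000`, `max_swaps = 5000`, `patience = 100`), image palette
#' extraction (`bins_per_channel = 20`, `sigma = 80`, `L_range = c(20, 85)`,
#' `w_s = 0.15`, `percentile_cut = 3`), integration (`n_hvg = 5000`),
#' discernibility (`fov_size = 500` um), plus `seed`, `cvd_mode` and the
#' embedding method.
#'
#' @param ... Named overrides of any default.
#' @return A `run_config` (named list).
#' @export
run_config <- function(...) {
  defaults <- list(
    k = 30, radius = 50, orphan_min_n = 1,
    n_initial = 2000, max_swaps = 5000, patience = 100,
    bins_per_channel = 20, sigma = 80, L_range = c(20, 85),
    w_s = 0.15, percentile_cut = 3,
    n_hvg = 5000, fov_size = 500,
    seed = 42, cvd_mode = "none", embed_method = "umap"
  )
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0) {
    cw_abort(paste0("unknown config field(s): ", paste(unknown, collapse = ", ")),
             "config_error")
  }
  cfg <- modifyList(defaults, overrides)
  structure(cfg, class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat("  ", nm, ": ", paste(x[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read / write a run configuration as YAML
#'
#' A dumped configuration loads back identical, so runs are reproducible from
#' the config file plus the input data alone.
#'
#' @param config A [run_config()].
#' @param path File path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) cw_abort(paste0("no such file: ", path), "config_error")
  vals <- yaml::read_yaml(path)
  do.call(run_config, vals)
}

config_hash <- function(config) rlang::hash(unclass(config))

#' Run the full colorization pipeline
#'
#' Orchestrates the whole workflow on one section: CI-graph construction,
#' palette acquisition (generated by graph embedding unless one is supplied),
#' CD-graph construction under the configured CVD mode, and assignment
#' optimization. Logs the package version, seed, configuration hash, cluster
#' count and final matching loss, and optionally writes the mapping as JSON.
#'
#' @param cells A [spatial_cells()] table (or a path readable by
#'   [read_spatial_cells()]).
#' @param config A [run_config()].
#' @param palette Optional palette (hex vector or `cw_palette`).
#' @param fixed Optional named vector of user-fixed cluster colors.
#' @param out Optional path for the JSON color mapping.
#' @param quiet Suppress the log line.
#' @return A `cluster_coloring`, invisibly when `out` is given.
#' @export
run_colorize <- function(cells, config = run_config(), palette = NULL,
                         fixed = NULL, out = NULL, quiet = FALSE) {
  if (is.character(cells)) cells <- read_spatial_cells(cells)
  cells <- check_cells(cells)
  coloring <- assign_colors(
    cells, palette = palette, cvd_mode = config$cvd_mode,
    k = config$k, radius = config$radius, orphan_min_n = config$orphan_min_n,
    n_initial = config$n_initial, max_swaps = config$max_swaps,
    patience = config$patience, seed = config$seed, fixed = fixed,
    embed_method = config$embed_method, L_range = config$L_range
  )
  if (!quiet) {
    inform(sprintf(
      "colorweave %s | seed %d | config %s | %d clusters | loss %.6g",
      as.character(utils::packageVersion("colorweave")),
      as.integer(config$seed), config_hash(config),
      nrow(coloring$mapping), coloring$loss
    ))
  }
  if (!is.null(out)) {
    write_coloring(coloring, out)
    return(invisible(coloring))
  }
  coloring
}
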