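# Data model and I/O for spatially resolved labeled cells. A spatial_cells
# object is a plain tibble (cell_id, x, y[, z], cluster) so it chains with
# dplyr verbs; the cluster column is a factor whose levels are fixed in
# first-appearance order, which pins the ordering of every downstream matrix.

#' Construct a table of spatially resolved labeled cells
#'
#' @param data A data frame with one row per cell.
#' @param x_col,y_col Names of the coordinate columns (micrometers).
#' @param label_col Name of the categorical cluster-label column.
#' @param z_col Optional third coordinate. Supported, but interlacement
#'   defaults (`k`, `radius`) are calibrated for planar sections, so a warning
#'   is emitted.
#' @param id_col Optional column of unique cell identifiers; row numbers are
#'   used when absent.
#' @return A `spatial_cells` tibble with columns `cell_id`, `x`, `y`
#'   (optionally `z`) and `cluster` (factor, levels in first-appearance order).
#' @examples
#' df <- data.frame(px = c(0, 0, 1, 1), py = c(0, 1, 0, 1),
#'                  type = c("L", "L", "R", "R"))
#' spatial_cells(df, "px", "py", "type")
#' @export
spatial_cells <- function(data, x_col = "x", y_col = "y", label_col = "cluster",
                          z_col = NULL, id_col = NULL) {
  data <- as.data.frame(data)
  if (nrow(data) == 0) cw_abort("no cells in input", "empty_input")
  need <- c(x_col, y_col, label_col, z_col, id_col)
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols) > 0) {
    cw_abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")),
             "schema_error")
  }
  coords <- data[, c(x_col, y_col, z_col), drop = FALSE]
  for (cc in names(coords)) {
    v <- coords[[cc]]
    if (is.character(v) || is.factor(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
    }
    if (!is.numeric(v) || anyNA(v) || any(!is.finite(v))) {
      cw_abort(paste0("non-numeric or non-finite coordinates in `", cc, "`"),
               "parse_error")
    }
    coords[[cc]] <- as.numeric(v)
  }
  if (!is.null(z_col)) {
    warn(paste("3D coordinates supplied; interlacement defaults (k, radius)",
               "are calibrated for 2D sections"))
  }
  labels <- as.character(data[[label_col]])
  if (anyNA(labels)) cw_abort("missing cluster labels", "schema_error")
  ids <- if (is.null(id_col)) as.character(seq_len(nrow(data))) else
    as.character(data[[id_col]])
  if (anyDuplicated(ids)) cw_abort("cell ids are not unique", "schema_error")
  out <- tibble(
    cell_id = ids,
    x = coords[[x_col]],
    y = coords[[y_col]]
  )
  if (!is.null(z_col)) out$z <- coords[[z_col]]
  out$cluster <- factor(labels, levels = unique(labels))
  class(out) <- c("spatial_cells", class(out))
  out
}

#' Read spatially resolved labeled cells from delimited text
#'
#' Reads a CSV or TSV file (by extension, or `delim`) with a header and builds
#' a [spatial_cells()] table.
#'
#' @inheritParams spatial_cells
#' @param path Path to the file.
#' @param delim Field delimiter; guessed from the extension when `NULL`.
#' @return A `spatial_cells` tibble.
#' @export
read_spatial_cells <- function(path, x_col = "x", y_col = "y",
                               label_col = "cluster", z_col = NULL,
                               id_col = NULL, delim = NULL) {
  if (!file.exists(path)) cw_abort(paste0("no such file: ", path), "input_error")
  if (is.null(delim)) {
    delim <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  if (nrow(df) == 0) cw_abort("input table is empty", "empty_input")
  spatial_cells(df, x_col = x_col, y_col = y_col, label_col = label_col,
                z_col = z_col, id_col = id_col)
}

#' Coerce an annotated single-cell container to spatial cells
#'
#' For a SingleCellExperiment (the R analogue of an annotated-matrix container:
#' per-cell metadata in `colData`, coordinates in a reduced-dimension slot),
#' pulls an N-by-2 coordinate array from `reducedDim(x, coord_slot)` and labels
#' from `colData(x)[[label_key]]`.
#'
#' @param x Object to coerce (data frame or SingleCellExperiment).
#' @param coord_slot Name of the reduced-dimension slot holding coordinates.
#' @param label_key Name of the per-cell metadata column holding labels.
#' @param ... Passed on to [spatial_cells()] for the data-frame method.
#' @return A `spatial_cells` tibble.
#' @export
as_spatial_cells <- function(x, ...) UseMethod("as_spatial_cells")

#' @rdname as_spatial_cells
#' @export
as_spatial_cells.data.frame <- function(x, ...) spatial_cells(x, ...)

#' @rdname as_spatial_cells
#' @export
as_spatial_cells.SingleCellExperiment <- function(x, coord_slot = "spatial",
                                                  label_key = "cluster", ...) {
  if (!requireNamespace("SingleCellExperiment", quietly = TRUE)) {
    cw_abort("package SingleCellExperiment is required for this method",
             "input_error")
  }
  if (!coord_slot %in% SingleCellExperiment::reducedDimNames(x)) {
    cw_abort(paste0("no reducedDim slot '", coord_slot, "' in container"),
             "schema_error")
  }
  cd <- SummarizedExperiment::colData(x)
  if (!label_key %in% colnames(cd)) {
    cw_abort(paste0("no colData column '", label_key, "' in container"),
             "schema_error")
  }
  coords <- SingleCellExperiment::reducedDim(x, coord_slot)
  df <- data.frame(
    x = coords[, 1], y = coords[, 2],
    cluster = as.character(cd[[label_key]]),
    cell_id = if (is.null(colnames(x))) as.character(seq_len(ncol(x))) else colnames(x)
  )
  spatial_cells(df, "x", "y", "cluster", id_col = "cell_id")
}

coord_matrix <- function(cells) {
  cols <- intersect(c("x", "y", "z"), names(cells))
  as.matrix(cells[, cols])
}

cluster_levels <- function(cells) levels(cells$cluster)

check_cells <- function(cells) {
  if (!inherits(cells, "spatial_cells")) {
    if (is.data.frame(cells)) return(spatial_cells(cells))
    cw_abort("expected a spatial_cells table", "schema_error")
  }
  cells
}

#' @export
print.spatial_cells <- function(x, ...) {
  cat("<spatial_cells: ", nrow(x), " cells, ", nlevels(x$cluster),
      " clusters>\n", sep = "")
  NextMethod()
}
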