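#' Single-sample cell-by-marker intensity matrix
#'
#' The basic container for one sample's cytometry events: a numeric matrix
#' (cells in rows, markers in columns) together with the sample id, the
#' marker order and the transform state. Raw intensities are non-negative;
#' after [arcsinh_transform()] the `transform` field records it.
#'
#' @param values numeric matrix, cells x markers.
#' @param sample_id sample identifier.
#' @param marker_names character vector naming the columns.
#' @param transform `"raw"` or `"arcsinh"`.
#' @param cell_ids per-cell identifiers (default `cell_000001`, ...).
#' @return An object of class `cell_matrix`.
#' @export
cell_matrix <- function(values, sample_id, marker_names,
                        transform = c("raw", "arcsinh"), cell_ids = NULL) {
  transform <- match.arg(transform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (ncol(values) != length(marker_names)) {
    stop("column count (", ncol(values), ") != number of marker names (",
         length(marker_names), ")")
  }
  if (transform == "raw" && nrow(values) > 0 && min(values) < 0) {
    stop("raw intensities must be non-negative")
  }
  if (is.null(cell_ids)) cell_ids <- sprintf("cell_%06d", seq_len(nrow(values)))
  stopifnot(length(cell_ids) == nrow(values))
  dimnames(values) <- list(NULL, marker_names)
  structure(list(values = values, sample_id = as.character(sample_id),
                 marker_names = as.character(marker_names),
                 transform = transform, cell_ids = as.character(cell_ids)),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix '", x$sample_id, "': ", nrow(x$values), " cells x ",
      ncol(x$values), " markers [", x$transform, "]\n", sep = "")
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$values)

# Subset a cell_matrix by cells and/or markers, keeping metadata in step.
subset_cells <- function(m, cells = NULL, markers = NULL) {
  stopifnot(inherits(m, "cell_matrix"))
  v <- m$values; ids <- m$cell_ids; mk <- m$marker_names
  if (!is.null(cells)) { v <- v[cells, , drop = FALSE]; ids <- ids[cells] }
  if (!is.null(markers)) {
    idx <- if (is.character(markers)) match(markers, mk) else markers
    if (anyNA(idx)) stop("unknown marker: ",
                         paste(markers[is.na(idx)], collapse = ", "))
    v <- v[, idx, drop = FALSE]; mk <- mk[idx]
  }
  cell_matrix(v, m$sample_id, mk, m$transform, ids)
}

marker_column <- function(m, marker) {
  idx <- match(marker, m$marker_names)
  if (is.na(idx)) stop("marker not present: ", marker)
  m$values[, idx]
}
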