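# Delimited-text IO: cell matrices (CSV fallback for FCS), clinical tables,
# and GEO-series-matrix-style expression tables. All tables are UTF-8 text
# with a header row; the delimiter is auto-detected among tab and comma.

detect_delim <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!length(first)) return(",")
  if (lengths(regmatches(first, gregexpr("\t", first))) >=
      lengths(regmatches(first, gregexpr(",", first)))) "\t" else ","
}

read_delim_auto <- function(path, ...) {
  utils::read.table(path, header = TRUE, sep = detect_delim(path),
                    quote = "\"", comment.char = "", check.names = FALSE,
                    stringsAsFactors = FALSE, ...)
}

#' Write / read a cell matrix as CSV
#'
#' CSV fallback for the FCS path: first column `cell_id`, remaining columns
#' one per marker in matrix order.
#'
#' @param m a [cell_matrix()].
#' @param path file path.
#' @rdname cell_csv
#' @export
write_cell_csv <- function(m, path) {
  stopifnot(inherits(m, "cell_matrix"))
  df <- data.frame(cell_id = m$cell_ids, m$values, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @param panel optional panel; when given, columns are checked and
#'   reordered to panel order as in [read_fcs()].
#' @param sample_id sample id (default: file name sans extension).
#' @param transform transform state of the stored values.
#' @rdname cell_csv
#' @export
read_cell_csv <- function(path, panel = NULL, sample_id = NULL,
                          transform = "raw") {
  df <- read_delim_auto(path)
  cell_ids <- if ("cell_id" %in% names(df)) as.character(df$cell_id) else NULL
  df <- df[, setdiff(names(df), "cell_id"), drop = FALSE]
  markers <- names(df)
  if (!is.null(panel)) {
    want <- panel_markers(panel)
    miss <- setdiff(want, markers)
    if (length(miss)) stop("channel for marker '", miss[1L], "' not found")
    df <- df[, want, drop = FALSE]
    markers <- want
  }
  if (is.null(sample_id)) sample_id <- sub("\\.[^.]*$", "", basename(path))
  cell_matrix(as.matrix(df), sample_id, markers, transform = transform,
              cell_ids = cell_ids)
}

CLINICAL_COLUMNS <- c("sample_id", "response", "sex", "age", "disease_type",
                      "primary_abnormality", "tp53_del", "gain_1q",
                      "myc_rearr", "monosomy13", "del13q", "msmart",
                      "s_phase_pct", "os_time", "os_event", "dara_within_6mo",
                      "sampled_within_6mo_of_dx")
RESPONSE_LEVELS <- c("VGPR", "PR", "MR", "SD", "PD")
PRIMARY_LEVELS <- c("hyperdiploidy", "t(11;14)", "t(4;14)", "t(14;20)",
                    "hyperhaploid", "undefined")
BOOL_COLUMNS <- c("tp53_del", "gain_1q", "myc_rearr", "monosomy13", "del13q",
                  "os_event", "dara_within_6mo", "sampled_within_6mo_of_dx")

parse_bool <- function(x) {
  out <- rep(NA, length(x))
  x <- tolower(trimws(as.character(x)))
  out[x %in% c("true", "t", "1", "yes")] <- TRUE
  out[x %in% c("false", "f", "0", "no")] <- FALSE
  bad <- !is.na(x) & x != "" & x != "na" & is.na(out)
  if (any(bad)) stop("unparseable boolean value(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  out
}

#' Read a clinical metadata table
#'
#' One row per sample. Enumerated fields are validated: `response` must be
#' one of VGPR/PR/MR/SD/PD (the 90-day depth-of-response scale used here),
#' `disease_type` NDMM/RRMM, `msmart` high/standard, and the cytogenetic
#' flags are booleans. Missing values are preserved as `NA`.
#'
#' @param path delimited text file (tab or comma) with a header row.
#' @return A `data.frame` with one validated record per row.
#' @export
read_clinical_table <- function(path) {
  if (!file.size(path)) {
    empty <- stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(CLINICAL_COLUMNS))),
      CLINICAL_COLUMNS)
    return(empty)
  }
  df <- read_delim_auto(path, colClasses = "character")
  miss <- setdiff(CLINICAL_COLUMNS, names(df))
  if (length(miss)) stop("missing clinical columns: ",
                         paste(miss, collapse = ", "))
  df <- df[, CLINICAL_COLUMNS, drop = FALSE]
  df[df == "" | df == "NA"] <- NA
  validate_clinical(within(df, {
    age <- as.numeric(age)
    s_phase_pct <- as.numeric(s_phase_pct)
    os_time <- as.numeric(os_time)
  }))
}

validate_clinical <- function(df) {
  for (b in BOOL_COLUMNS) df[[b]] <- parse_bool(df[[b]])
  check_enum <- function(x, levels, what) {
    bad <- !is.na(x) & !(x %in% levels)
    if (any(bad)) stop("invalid ", what, " value(s): ",
                       paste(unique(x[bad]), collapse = ", "),
                       "; allowed: ", paste(levels, collapse = ", "))
    x
  }
  df$response <- check_enum(df$response, RESPONSE_LEVELS, "response")
  df$disease_type <- check_enum(df$disease_type, c("NDMM", "RRMM"),
                                "disease_type")
  df$primary_abnormality <- check_enum(df$primary_abnormality,
                                       PRIMARY_LEVELS, "primary_abnormality")
  df$msmart <- check_enum(df$msmart, c("high", "standard"), "msmart")
  if (any(!is.na(df$os_time) & df$os_time < 0)) stop("os_time must be >= 0")
  if (anyDuplicated(stats::na.omit(df$sample_id))) {
    stop("duplicate sample_id in clinical table")
  }
  df
}

#' Write a clinical table as CSV
#' @param records clinical `data.frame` as returned by [read_clinical_table()].
#' @param path output path.
#' @export
write_clinical_table <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Bulk expression cohort
#'
#' Probe-level expression with a probe-to-gene map and per-sample outcome
#' annotations, the container scored by [metacluster_activity_score()].
#'
#' @param exprs numeric matrix, probes x samples, probe ids as rownames.
#' @param probe_map data.frame with columns `probe`, `gene`.
#' @param annotations data.frame keyed by `sample_id` with outcome columns
#'   (e.g. `os_time`, `os_event`, `responder`).
#' @return An object of class `expression_cohort`.
#' @export
expression_cohort <- function(exprs, probe_map, annotations = NULL) {
  exprs <- as.matrix(exprs)
  stopifnot(!is.null(rownames(exprs)), !is.null(colnames(exprs)))
  if (anyDuplicated(colnames(exprs))) stop("sample ids must be unique")
  stopifnot(all(c("probe", "gene") %in% names(probe_map)))
  if (!nrow(probe_map)) stop("probe map is empty")
  probe_map <- probe_map[probe_map$probe %in% rownames(exprs), , drop = FALSE]
  if (!nrow(probe_map)) stop("no probe map entries match the matrix")
  if (!is.null(annotations)) {
    stopifnot("sample_id" %in% names(annotations))
    annotations <- annotations[match(colnames(exprs), annotations$sample_id),
                               , drop = FALSE]
  }
  structure(list(exprs = exprs, probe_map = probe_map,
                 annotations = annotations),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", nrow(x$exprs), "probes x", ncol(x$exprs),
      "samples;", length(unique(x$probe_map$gene)), "mapped genes\n")
  invisible(x)
}

#' Read a bulk expression table (probes x samples)
#'
#' Tab- or comma-delimited text, first column probe ids (GEO series-matrix
#' style); remaining columns numeric per-sample intensities.
#'
#' @param path expression table.
#' @param gene_map data.frame with columns `probe`, `gene` (explicit map,
#'   never inferred from annotation databases).
#' @param annotations optional per-sample annotation data.frame with a
#'   `sample_id` column.
#' @return An [expression_cohort()].
#' @export
read_expression_cohort <- function(path, gene_map, annotations = NULL) {
  df <- read_delim_auto(path)
  probes <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- probes
  expression_cohort(mat, gene_map, annotations)
}
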