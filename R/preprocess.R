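#' Arcsinh-transform a cell matrix
#'
#' The standard mass-cytometry variance-stabilizing transform:
#' `v -> asinh(v / cofactor)`, cofactor 5 by convention.
#'
#' @param m a raw [cell_matrix()].
#' @param cofactor positive cofactor (default 5).
#' @return The transformed `cell_matrix` (`transform = "arcsinh"`).
#' @export
arcsinh_transform <- function(m, cofactor = 5) {
  stopifnot(inherits(m, "cell_matrix"), cofactor > 0)
  if (m$transform != "raw") stop("matrix is already transformed")
  cell_matrix(asinh(m$values / cofactor), m$sample_id, m$marker_names,
              transform = "arcsinh", cell_ids = m$cell_ids)
}

#' Monotypic plasma-cell gating rules
#'
#' Plasma cells are kept when below threshold on every negative marker
#' (default CD16, CD3, CD19), at or above threshold on every positive
#' marker (default CD138, IRF4) and positive for the sample's restricted
#' light chain. CD38 is deliberately not a gating marker: anti-CD38
#' therapy masks its epitope for months after exposure.
#'
#' @param negative_markers markers that must be low.
#' @param positive_markers markers that must be high.
#' @param light_chain_pair the (kappa, lambda) marker names.
#' @param thresholds optional named numeric vector of fixed arcsinh-scale
#'   cutoffs covering the rule markers; when `NULL` each threshold is
#'   estimated per sample by a two-component 1-D split (Otsu) with a
#'   bimodality guard.
#' @param polytypic_max_fraction maximum tolerated opposite-chain fraction
#'   before the report flags the sample (default 0.05).
#' @param min_cells minimum gated cells before the report flags the sample
#'   (default 500).
#' @return An object of class `gating_rules`.
#' @export
gating_rules <- function(negative_markers = c("CD16", "CD3", "CD19"),
                         positive_markers = c("CD138", "IRF4"),
                         light_chain_pair = c("kappa", "lambda"),
                         thresholds = NULL,
                         polytypic_max_fraction = 0.05,
                         min_cells = 500L) {
  if (length(intersect(negative_markers, positive_markers))) {
    stop("negative and positive marker sets must be disjoint")
  }
  rule_markers <- c(negative_markers, positive_markers, light_chain_pair)
  if (!is.null(thresholds)) {
    miss <- setdiff(rule_markers, names(thresholds))
    if (length(miss)) stop("thresholds must cover all rule markers; missing: ",
                           paste(miss, collapse = ", "))
  }
  structure(list(negative_markers = negative_markers,
                 positive_markers = positive_markers,
                 light_chain_pair = light_chain_pair,
                 thresholds = thresholds,
                 polytypic_max_fraction = polytypic_max_fraction,
                 min_cells = as.integer(min_cells)),
            class = "gating_rules")
}

# Per-sample threshold for one marker: Otsu split with a bimodality guard.
# The split only counts as two real populations when it explains most of
# the variance AND the class means are at least `min_gap` arcsinh units
# apart (zero-inflation of a dim marker makes high-separability splits
# with tiny gaps). An effectively unimodal marker gets a pass-everything
# threshold, which also makes gating idempotent on already-gated data.
gate_threshold <- function(x, side, min_separability = 0.3, min_gap = 1.0) {
  sp <- otsu_split(x)
  bimodal <- !is.na(sp$threshold) && sp$separability >= min_separability &&
    (mean(x[x >= sp$threshold]) - mean(x[x < sp$threshold])) >= min_gap
  if (!bimodal) {
    return(if (side == "positive") min(x) - 1 else max(x) + 1)
  }
  sp$threshold
}

#' Gate monotypic plasma cells
#'
#' Applies the negative/positive marker rules, determines the restricted
#' light chain (the chain with the higher median among cells passing the
#' non-light-chain rules; ties go to kappa and are flagged) and keeps
#' cells positive for the restricted chain. No cell passing is reported,
#' not raised as an error.
#'
#' @param m a transformed [cell_matrix()] containing all rule markers.
#' @param rules a [gating_rules()] object.
#' @return list with `matrix` (gated `cell_matrix`) and `report`:
#'   kept count/fraction, restricted chain, polytypic fraction
#'   (opposite-chain-positive among all chain-positive plasma cells),
#'   thresholds used, and flags (`below_min_cells`, `polytypic_excess`,
#'   `chain_tie`).
#' @export
gate_plasma_cells <- function(m, rules = gating_rules()) {
  stopifnot(inherits(m, "cell_matrix"))
  if (m$transform == "raw") stop("gate on transformed data (arcsinh first)")
  rule_markers <- c(rules$negative_markers, rules$positive_markers,
                    rules$light_chain_pair)
  miss <- setdiff(rule_markers, m$marker_names)
  if (length(miss)) stop("rule markers absent from matrix: ",
                         paste(miss, collapse = ", "))

  thr <- rules$thresholds
  if (is.null(thr)) {
    thr <- vapply(rule_markers, function(mk) {
      side <- if (mk %in% rules$negative_markers) "negative" else "positive"
      gate_threshold(marker_column(m, mk), side)
    }, numeric(1))
  }

  pass_core <- rep(TRUE, nrow(m$values))
  for (mk in rules$negative_markers) {
    pass_core <- pass_core & marker_column(m, mk) < thr[[mk]]
  }
  for (mk in rules$positive_markers) {
    pass_core <- pass_core & marker_column(m, mk) >= thr[[mk]]
  }

  kap <- rules$light_chain_pair[1L]; lam <- rules$light_chain_pair[2L]
  kv <- marker_column(m, kap); lv <- marker_column(m, lam)
  chain_tie <- FALSE
  if (!any(pass_core)) {
    restricted <- kap
  } else {
    med_k <- stats::median(kv[pass_core]); med_l <- stats::median(lv[pass_core])
    chain_tie <- med_k == med_l
    restricted <- if (med_k >= med_l) kap else lam
  }
  rthr <- thr[[restricted]]
  othr <- thr[[setdiff(c(kap, lam), restricted)]]
  rv <- if (restricted == kap) kv else lv
  ov <- if (restricted == kap) lv else kv
  keep <- pass_core & rv >= rthr

  chain_pos <- pass_core & (rv >= rthr | ov >= othr)
  polytypic <- if (any(chain_pos)) {
    mean(ov[chain_pos] >= othr)
  } else NA_real_

  gated <- subset_cells(m, cells = which(keep))
  report <- list(
    n_input = nrow(m$values),
    n_kept = sum(keep),
    kept_fraction = if (nrow(m$values)) sum(keep) / nrow(m$values) else NA,
    restricted_chain = restricted,
    polytypic_fraction = polytypic,
    thresholds = as.list(thr),
    below_min_cells = sum(keep) < rules$min_cells,
    polytypic_excess = isTRUE(polytypic > rules$polytypic_max_fraction),
    chain_tie = chain_tie
  )
  list(matrix = gated, report = report)
}

#' Write a gating report as JSON
#' @param report the `report` element of [gate_plasma_cells()].
#' @param path output path.
#' @export
write_gating_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Drop excluded markers from every sample
#'
#' Applies the batch exclusion (or any marker exclusion) to a list of cell
#' matrices, preserving the remaining marker order. Gating markers cannot
#' be excluded: gating must happen first.
#'
#' @param samples list of [cell_matrix()] objects sharing a marker set.
#' @param exclusions character vector of markers to drop.
#' @param gating_markers markers protected from exclusion (defaults to the
#'   default [gating_rules()] rule set).
#' @return The list with excluded columns removed.
#' @export
filter_markers <- function(samples, exclusions,
                           gating_markers = unlist(gating_rules()[
                             c("negative_markers", "positive_markers",
                               "light_chain_pair")])) {
  if (!length(samples)) return(samples)
  markers <- samples[[1L]]$marker_names
  bad <- setdiff(exclusions, markers)
  if (length(bad)) stop("exclusions not in panel: ",
                        paste(bad, collapse = ", "))
  gm <- intersect(exclusions, gating_markers)
  if (length(gm)) stop("cannot exclude gating marker(s) ",
                       paste(gm, collapse = ", "), "; gate first")
  keep <- setdiff(markers, exclusions)
  lapply(samples, function(m) subset_cells(m, markers = keep))
}

#' Summarize a clinical cohort
#'
#' Counts and percentages per categorical level (denominator = non-missing
#' values, percentages to 1 decimal) plus medians and ranges for age and
#' S-phase, laid out like a patient-characteristics table.
#'
#' @param records clinical data.frame (see [read_clinical_table()]).
#' @return list with `categorical` (data.frame: field, level, n, pct) and
#'   `numeric` (data.frame: field, median, min, max), plus `n_records`.
#' @export
summarize_cohort <- function(records) {
  stopifnot(nrow(records) >= 1L)
  cat_fields <- c("sex", "response", "disease_type", "primary_abnormality",
                  "msmart", "tp53_del", "gain_1q", "myc_rearr",
                  "monosomy13", "del13q", "dara_within_6mo")
  cat_fields <- intersect(cat_fields, names(records))
  rows <- list()
  for (f in cat_fields) {
    x <- records[[f]]
    x <- x[!is.na(x)]
    if (!length(x)) next
    tab <- table(as.character(x))
    rows[[f]] <- data.frame(field = f, level = names(tab),
                            n = as.integer(tab),
                            pct = round(100 * as.integer(tab) / length(x), 1),
                            stringsAsFactors = FALSE)
  }
  categorical <- do.call(rbind, rows)
  rownames(categorical) <- NULL
  num_fields <- intersect(c("age", "s_phase_pct", "os_time"), names(records))
  numeric_summary <- do.call(rbind, lapply(num_fields, function(f) {
    x <- records[[f]][!is.na(records[[f]])]
    data.frame(field = f,
               median = if (length(x)) stats::median(x) else NA_real_,
               min = if (length(x)) min(x) else NA_real_,
               max = if (length(x)) max(x) else NA_real_,
               n = length(x), stringsAsFactors = FALSE)
  }))
  list(n_records = nrow(records), categorical = categorical,
       numeric = numeric_summary)
}
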