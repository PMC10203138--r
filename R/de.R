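# Per-cluster differential-expression signatures: an explicit two-part
# (hurdle) comparison of each cluster against the rest of its sample,
# emulating the single-cell hurdle-model Z-scores that drive the
# meta-clustering stage. Part 1 tests the detection rate (zero vs
# non-zero, the zero-inflated component of CyTOF signal); part 2 is a
# Welch z on the expression level among detected cells; the two are
# combined by a Stouffer sum.

#' Differential-expression signature of one cluster
#'
#' Per marker, against all other cells of the same sample:
#' part 1 is a two-proportion z on detection (`value > 0`); part 2 a
#' Welch z on the arcsinh values among detected cells; the combined
#' statistic is the Stouffer sum `(z1 + z2) / sqrt(2)` of the informative
#' parts, with its sign taken from the level difference. A part is
#' dropped when it carries no information: detection when all (or no)
#' cells are detected on both sides, the level part when either side has
#' fewer than 2 detected cells; the remaining part is used alone.
#' The two-sided p is the normal tail of the combined z. `frac_changed`
#' is the fraction of cluster cells outside the complement's
#' \[5th, 95th\] percentile band on the side matching the direction;
#' direction is up/down when `p < p_threshold`, otherwise none.
#'
#' @param m a transformed [cell_matrix()].
#' @param labels integer cluster labels along cells (see [cluster_cells()]).
#' @param cluster_id the cluster to profile.
#' @param p_threshold significance level for direction calls (default 0.001).
#' @return An object of class `cluster_signature`: sample_id, cluster_id,
#'   n_cells and a per-marker data.frame (marker, z, p, frac_changed,
#'   direction, plus the component statistics z_detect and z_level;
#'   a component is `NA` when uninformative and excluded from z).
#' @export
differential_expression <- function(m, labels, cluster_id,
                                    p_threshold = 0.001) {
  stopifnot(inherits(m, "cell_matrix"), length(labels) == nrow(m$values))
  inc <- labels == cluster_id
  if (!any(inc)) stop("cluster ", cluster_id, " is empty")
  if (all(inc)) stop("cluster ", cluster_id, " has an empty complement")
  v <- m$values
  det <- v > 0
  n1 <- sum(inc); n2 <- sum(!inc)

  d1 <- colSums(det[inc, , drop = FALSE])
  d2 <- colSums(det[!inc, , drop = FALSE])
  p1 <- d1 / n1; p2 <- d2 / n2
  phat <- (d1 + d2) / (n1 + n2)
  denom1 <- sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  z1 <- ifelse(denom1 > 0, (p1 - p2) / denom1, 0)

  # level part among detected cells (needs >= 2 detected on each side)
  s1 <- colSums(v[inc, , drop = FALSE] * det[inc, , drop = FALSE])
  s2 <- colSums(v[!inc, , drop = FALSE] * det[!inc, , drop = FALSE])
  q1 <- colSums(v[inc, , drop = FALSE]^2 * det[inc, , drop = FALSE])
  q2 <- colSums(v[!inc, , drop = FALSE]^2 * det[!inc, , drop = FALSE])
  m1 <- ifelse(d1 > 0, s1 / d1, NA_real_)
  m2 <- ifelse(d2 > 0, s2 / d2, NA_real_)
  var1 <- ifelse(d1 > 1, pmax(0, (q1 - d1 * m1^2) / (d1 - 1)), NA_real_)
  var2 <- ifelse(d2 > 1, pmax(0, (q2 - d2 * m2^2) / (d2 - 1)), NA_real_)
  level_diff <- m1 - m2
  se <- sqrt(var1 / d1 + var2 / d2)
  z2 <- ifelse(!is.na(se) & se > 0, level_diff / se,
               ifelse(!is.na(level_diff) & level_diff != 0,
                      sign(level_diff) * 37, 0))
  # combine only the informative, well-approximated parts: the level part
  # needs >= 2 detected cells per side; the detection part needs enough
  # zeros AND enough detected cells for the two-proportion z to be
  # near-normal (expected count >= 5 per group, the classic rule) —
  # a handful of zeros would make z1 a two-point variable and wreck
  # calibration of the Stouffer sum
  n_zero <- (n1 + n2) - (d1 + d2)
  have_levels <- d1 >= 2 & d2 >= 2
  have_detect <- n_zero >= 10 & (d1 + d2) >= 10
  z_comb <- ifelse(have_levels & have_detect, (z1 + z2) / sqrt(2),
                   ifelse(have_levels, z2, z1))

  # sign from the level difference where available, else the hurdle part
  sgn <- ifelse(have_levels & !is.na(level_diff) & level_diff != 0,
                sign(level_diff),
                ifelse(z1 != 0, sign(z1), sign(z_comb)))
  sgn[sgn == 0] <- 1
  z <- sgn * abs(z_comb)
  p <- 2 * stats::pnorm(-abs(z))

  lo <- apply(v[!inc, , drop = FALSE], 2L, stats::quantile, probs = 0.05)
  hi <- apply(v[!inc, , drop = FALSE], 2L, stats::quantile, probs = 0.95)
  above <- colMeans(v[inc, , drop = FALSE] >
                      matrix(hi, n1, ncol(v), byrow = TRUE))
  below <- colMeans(v[inc, , drop = FALSE] <
                      matrix(lo, n1, ncol(v), byrow = TRUE))
  frac_changed <- ifelse(z >= 0, above, below)
  direction <- ifelse(p < p_threshold, ifelse(z > 0, "up", "down"), "none")

  structure(list(
    sample_id = m$sample_id,
    cluster_id = cluster_id,
    n_cells = n1,
    stats = data.frame(marker = m$marker_names, z = unname(z), p = unname(p),
                       frac_changed = unname(frac_changed),
                       direction = unname(direction),
                       z_detect = unname(ifelse(have_detect, z1, NA_real_)),
                       z_level = unname(ifelse(have_levels, z2, NA_real_)),
                       stringsAsFactors = FALSE)
  ), class = "cluster_signature")
}

#' Signatures for every cluster of a sample
#' @param m a transformed [cell_matrix()].
#' @param labels integer cluster labels.
#' @param p_threshold passed to [differential_expression()].
#' @return list of `cluster_signature` objects (single-cluster samples give
#'   one all-zero signature).
#' @export
cluster_signatures <- function(m, labels, p_threshold = 0.001) {
  ids <- sort(unique(labels))
  if (length(ids) == 1L) {
    sig <- structure(list(
      sample_id = m$sample_id, cluster_id = ids, n_cells = nrow(m$values),
      stats = data.frame(marker = m$marker_names, z = 0, p = 1,
                         frac_changed = 0, direction = "none",
                         z_detect = NA_real_, z_level = NA_real_,
                         stringsAsFactors = FALSE)), class = "cluster_signature")
    return(list(sig))
  }
  lapply(ids, function(k) differential_expression(m, labels, k, p_threshold))
}

#' Pool cluster signatures into a signature matrix
#'
#' One row per (sample, cluster) over all samples; columns are markers,
#' entries are the signed combined Z-scores. The parallel p-value and
#' fraction-changed matrices and the per-row metadata (sample, cluster,
#' cell count) ride along for the meta-clustering stage.
#'
#' @param signatures list of `cluster_signature` objects (all sharing one
#'   marker set).
#' @return An object of class `signature_matrix` with elements `z`, `p`,
#'   `frac` (matrices) and `meta` (data.frame: sample_id, cluster_id,
#'   n_cells).
#' @export
assemble_signature_matrix <- function(signatures) {
  stopifnot(length(signatures) >= 1L)
  markers <- signatures[[1L]]$stats$marker
  for (s in signatures) {
    if (!identical(s$stats$marker, markers)) {
      stop("signatures have mismatched marker sets")
    }
  }
  grab <- function(field) {
    t(vapply(signatures, function(s) s$stats[[field]],
             numeric(length(markers))))
  }
  z <- grab("z"); p <- grab("p"); fr <- grab("frac_changed")
  colnames(z) <- colnames(p) <- colnames(fr) <- markers
  meta <- data.frame(
    sample_id = vapply(signatures, `[[`, "", "sample_id"),
    cluster_id = vapply(signatures, function(s) as.integer(s$cluster_id),
                        integer(1)),
    n_cells = vapply(signatures, function(s) as.integer(s$n_cells),
                     integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(z) <- rownames(p) <- rownames(fr) <-
    paste(meta$sample_id, meta$cluster_id, sep = ":")
  structure(list(z = z, p = p, frac = fr, meta = meta),
            class = "signature_matrix")
}

#' @export
print.signature_matrix <- function(x, ...) {
  cat("signature_matrix:", nrow(x$z), "cluster signatures x", ncol(x$z),
      "markers from", length(unique(x$meta$sample_id)), "samples\n")
  invisible(x)
}

#' Write / read a signature matrix as CSV
#' @param sig a `signature_matrix`.
#' @param path CSV path.
#' @rdname signature_csv
#' @export
write_signature_matrix <- function(sig, path) {
  df <- data.frame(sig$meta, sig$z, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname signature_csv
#' @export
read_signature_matrix <- function(path) {
  df <- read_delim_auto(path)
  meta_cols <- c("sample_id", "cluster_id", "n_cells")
  stopifnot(all(meta_cols %in% names(df)))
  z <- as.matrix(df[, setdiff(names(df), meta_cols), drop = FALSE])
  meta <- df[, meta_cols]
  rownames(z) <- paste(meta$sample_id, meta$cluster_id, sep = ":")
  structure(list(z = z, p = NULL, frac = NULL, meta = meta),
            class = "signature_matrix")
}
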