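#' Per-sample average marker profiles
#'
#' One row per gated sample, one column per marker; entries are the mean or
#' median marker signal over the sample's cells on the matrices' current
#' scale. Empty samples are excluded with a warning.
#'
#' @param samples list of gated [cell_matrix()] objects with one shared
#'   marker set.
#' @param statistic `"mean"` or `"median"`.
#' @return A numeric matrix (samples x markers) with sample ids as rownames.
#' @export
sample_profiles <- function(samples, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(length(samples) >= 1L)
  markers <- samples[[1L]]$marker_names
  for (m in samples) {
    if (!identical(m$marker_names, markers)) stop("marker sets differ")
  }
  empty <- vapply(samples, function(m) nrow(m$values) == 0L, logical(1))
  if (any(empty)) {
    warning("excluding empty sample(s): ",
            paste(vapply(samples[empty], `[[`, "", "sample_id"),
                  collapse = ", "))
    samples <- samples[!empty]
  }
  fn <- if (statistic == "mean") colMeans else {
    function(v) apply(v, 2L, stats::median)
  }
  out <- t(vapply(samples, function(m) fn(m$values), numeric(length(markers))))
  rownames(out) <- vapply(samples, `[[`, "", "sample_id")
  colnames(out) <- markers
  out
}

#' Compare sample-level marker profiles between two groups
#'
#' Per marker: group medians and ranges (reported on the raw scale when a
#' raw-scale profile is supplied, for readability), log2 fold change of
#' group means, Welch (unequal-variance) two-sided t test on the analysis
#' scale. A Benjamini-Hochberg FDR column is appended for transparency but
#' plays no part in the significance calls.
#'
#' @param profile samples x markers matrix on the analysis (arcsinh) scale.
#' @param grouping logical or two-level vector along rows of `profile`;
#'   `TRUE` (or the first level) is group A.
#' @param raw_profile optional samples x markers matrix on the raw scale
#'   used for the reported medians/ranges (defaults to `profile`).
#' @param pseudocount added to the group means before the log2 ratio.
#' @return data.frame: marker, n_a, n_b, median/range per group, log2fc,
#'   t, p, fdr.
#' @export
compare_groups <- function(profile, grouping, raw_profile = NULL,
                           pseudocount = 1e-4) {
  stopifnot(nrow(profile) == length(grouping))
  if (!is.logical(grouping)) {
    lev <- unique(grouping[!is.na(grouping)])
    if (length(lev) != 2L) stop("grouping must have exactly two levels")
    grouping <- grouping == lev[1L]
  }
  keep <- !is.na(grouping)
  profile <- profile[keep, , drop = FALSE]
  grouping <- grouping[keep]
  if (!any(grouping) || !any(!grouping)) stop("both groups must be non-empty")
  if (is.null(raw_profile)) raw_profile <- profile
  raw_profile <- raw_profile[keep, , drop = FALSE]

  res <- lapply(colnames(profile), function(mk) {
    xa <- profile[grouping, mk]; xb <- profile[!grouping, mk]
    ra <- raw_profile[grouping, mk]; rb <- raw_profile[!grouping, mk]
    tt <- if (length(xa) > 1L && length(xb) > 1L &&
              (stats::sd(xa) > 0 || stats::sd(xb) > 0)) {
      stats::t.test(xa, xb)            # Welch by default
    } else NULL
    data.frame(
      marker = mk, n_a = length(xa), n_b = length(xb),
      median_a = stats::median(ra), median_b = stats::median(rb),
      min_a = min(ra), max_a = max(ra), min_b = min(rb), max_b = max(rb),
      log2fc = log2((mean(xa) + pseudocount) / (mean(xb) + pseudocount)),
      t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
      p = if (is.null(tt)) NA_real_ else tt$p.value,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Signed Cramer's V for two binary variables
#'
#' `V = sqrt(chi^2 / n)` on the 2x2 table (no continuity correction), with
#' the sign taken from the Pearson correlation of the 0/1 codes. On a 2x2
#' table this equals the Pearson phi coefficient exactly.
#'
#' @param x,y vectors coded 0/1 (or logical).
#' @return A single number in \[-1, 1\]; `NA` if either input is constant.
#' @export
signed_cramers_v <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- as.numeric(x[keep]); y <- as.numeric(y[keep])
  if (length(x) < 2L || stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(NA_real_)
  }
  tab <- table(factor(x, levels = 0:1), factor(y, levels = 0:1))
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  v <- sqrt(unname(chi$statistic) / sum(tab))
  sgn <- sign(stats::cor(x, y))
  if (sgn == 0) sgn <- 1
  v * sgn
}

#' Mixed correlation matrix over numeric and binary variables
#'
#' Binary-binary entries use signed Cramer's V (sign from Pearson); every
#' other pair uses the Pearson correlation. Variables with zero variance
#' get missing entries. Columns coded with exactly the values {0, 1}
#' (or logical) are treated as binary.
#'
#' @param variables data.frame of per-sample numeric and 0/1 variables
#'   (>= 3 rows).
#' @return A symmetric matrix with unit diagonal, entries in \[-1, 1\].
#' @export
mixed_correlation_matrix <- function(variables) {
  stopifnot(is.data.frame(variables), nrow(variables) >= 3L)
  vars <- names(variables)
  is_bin <- vapply(variables, function(x) {
    x <- x[!is.na(x)]
    is.logical(x) || all(x %in% c(0, 1))
  }, logical(1))
  p <- length(vars)
  out <- matrix(NA_real_, p, p, dimnames = list(vars, vars))
  diag(out) <- 1
  for (i in seq_len(p - 1L)) {
    for (j in seq(i + 1L, p)) {
      xi <- as.numeric(variables[[i]]); xj <- as.numeric(variables[[j]])
      keep <- !is.na(xi) & !is.na(xj)
      if (sum(keep) < 2L || stats::sd(xi[keep]) == 0 ||
          stats::sd(xj[keep]) == 0) next
      val <- if (is_bin[i] && is_bin[j]) {
        signed_cramers_v(xi[keep], xj[keep])
      } else {
        stats::cor(xi[keep], xj[keep])
      }
      out[i, j] <- out[j, i] <- val
    }
  }
  zero_var <- vapply(variables, function(x) {
    x <- as.numeric(x[!is.na(x)])
    length(x) < 2L || stats::sd(x) == 0
  }, logical(1))
  out[zero_var, ] <- NA_real_
  out[, zero_var] <- NA_real_
  diag(out)[!zero_var] <- 1
  out
}
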