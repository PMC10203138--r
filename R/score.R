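# Meta-cluster activity scoring on bulk expression cohorts: per-gene
# median probe intensities are rank-summed across samples, transferring a
# CyTOF-derived subclonal phenotype to microarray cohorts where no
# single-cell data exist.

#' Gene signature
#'
#' @param genes character vector of unique gene symbols.
#' @param directions `"up"` or `"down"` per gene (recycled).
#' @param name signature name.
#' @return An object of class `gene_signature`.
#' @export
gene_signature <- function(genes, directions = "up", name = "signature") {
  directions <- rep_len(directions, length(genes))
  stopifnot(length(genes) >= 1L, !anyDuplicated(genes),
            all(directions %in% c("up", "down")))
  structure(list(entries = data.frame(gene = genes, direction = directions,
                                      stringsAsFactors = FALSE),
                 name = name),
            class = "gene_signature")
}

#' The CD45hi/BCL-2lo meta-cluster gene signature
#'
#' Five genes transferring the favorable-outcome phenotype (high CD45,
#' low BCL-2, high IKZF3/MYC/IkBa) to expression data: BCL2 (down),
#' IKZF3, MYC, NFKBIA and PTPRC (up).
#'
#' @return A [gene_signature()].
#' @export
metacluster1_signature <- function() {
  gene_signature(c("BCL2", "IKZF3", "MYC", "NFKBIA", "PTPRC"),
                 c("down", "up", "up", "up", "up"),
                 name = "metacluster1")
}

#' Per-sample, per-gene median probe intensity
#'
#' For each signature gene, the median intensity over all of its mapped
#' probes (probes pooled across chips), per sample.
#'
#' @param cohort an [expression_cohort()].
#' @param signature a [gene_signature()]; every gene must map to >= 1
#'   probe present in the matrix.
#' @return genes x samples numeric matrix of medians.
#' @export
gene_median_intensity <- function(cohort, signature) {
  stopifnot(inherits(cohort, "expression_cohort"),
            inherits(signature, "gene_signature"))
  genes <- signature$entries$gene
  out <- matrix(NA_real_, length(genes), ncol(cohort$exprs),
                dimnames = list(genes, colnames(cohort$exprs)))
  for (g in genes) {
    probes <- cohort$probe_map$probe[cohort$probe_map$gene == g]
    probes <- intersect(probes, rownames(cohort$exprs))
    if (!length(probes)) stop("no probes map to signature gene '", g, "'")
    sub <- cohort$exprs[probes, , drop = FALSE]
    out[g, ] <- apply(sub, 2L, stats::median)
  }
  out
}

#' Meta-cluster activity score by rank summation
#'
#' Per gene, samples are ranked by median intensity (ascending, average
#' ranks for ties); the score is the per-sample sum of ranks over the
#' signature genes. `"literal"` mode uses ascending ranks for every gene;
#' `"signed"` mode uses descending ranks for direction-`down` genes, so a
#' high score always means high signature activity. The two coincide when
#' the signature has no down genes.
#'
#' @param medians genes x samples matrix from [gene_median_intensity()].
#' @param signature the [gene_signature()] the medians were computed for.
#' @param mode `"literal"` or `"signed"`.
#' @return Named numeric vector of per-sample scores, with attribute
#'   `mode`.
#' @export
metacluster_activity_score <- function(medians, signature,
                                       mode = c("literal", "signed")) {
  mode <- match.arg(mode)
  stopifnot(ncol(medians) >= 2L,
            all(signature$entries$gene %in% rownames(medians)))
  n <- ncol(medians)
  score <- numeric(n)
  for (i in seq_len(nrow(signature$entries))) {
    g <- signature$entries$gene[i]
    r <- rank(medians[g, ], ties.method = "average")
    if (mode == "signed" && signature$entries$direction[i] == "down") {
      r <- n + 1 - r          # descending ranks for down genes
    }
    score <- score + r
  }
  names(score) <- colnames(medians)
  attr(score, "mode") <- mode
  score
}

# Odds ratio of a 2x2 table (a b / c d) with Woolf (log) 95% CI and a
# Haldane-Anscombe 0.5 correction when any cell is empty.
odds_ratio_woolf <- function(a, b, c, d) {
  corrected <- any(c(a, b, c, d) == 0)
  if (corrected) { a <- a + 0.5; b <- b + 0.5; c <- c + 0.5; d <- d + 0.5 }
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- log(or) / se
  list(or = or, lcl = exp(log(or) - 1.96 * se),
       ucl = exp(log(or) + 1.96 * se),
       p = 2 * stats::pnorm(-abs(z)), haldane_corrected = corrected)
}

#' Outcome analysis of activity-score tails
#'
#' Takes the bottom and top `tail_fraction` of samples by score
#' (`floor(tail_fraction * n)` from each extreme; boundary ties broken by
#' stable sample order and flagged), then compares the low vs high tails:
#' Kaplan-Meier + log-rank and Cox hazard ratio (low vs high) for
#' survival, and the odds ratio of no-response vs response (low over
#' high) with a Woolf 95% CI, Haldane-corrected if a cell is empty.
#'
#' @param scores per-sample scores (from [metacluster_activity_score()]).
#' @param cohort the scored [expression_cohort()]; annotations must carry
#'   `os_time`, `os_event` and (for the odds ratio) `responder`.
#' @param tail_fraction fraction per tail in (0, 0.5\] (default 0.20).
#' @return list: `tails` (data.frame sample/score/tail), `survival`
#'   ([km_logrank()] of low vs high), `cox` (hazard ratio of low vs high),
#'   `odds_ratio` (list or NULL when responder status is absent),
#'   `boundary_ties` flag, `mode`.
#' @export
score_outcome_analysis <- function(scores, cohort, tail_fraction = 0.20) {
  stopifnot(tail_fraction > 0, tail_fraction <= 0.5)
  ann <- cohort$annotations
  if (is.null(ann)) stop("cohort has no outcome annotations")
  ids <- names(scores)
  stopifnot(!is.null(ids), all(ids %in% ann$sample_id))
  n <- length(scores)
  if (n < 10L) stop("need >= 10 samples with outcomes")
  n_tail <- floor(tail_fraction * n)
  ord <- order(scores)                      # stable: ties keep input order
  low_ids <- ids[ord[seq_len(n_tail)]]
  high_ids <- ids[ord[seq(n - n_tail + 1L, n)]]
  sorted <- scores[ord]
  boundary_ties <- sorted[n_tail] == sorted[n_tail + 1L] ||
    sorted[n - n_tail + 1L] == sorted[n - n_tail]

  tails <- data.frame(
    sample_id = ids, score = as.numeric(scores),
    tail = ifelse(ids %in% low_ids, "low",
                  ifelse(ids %in% high_ids, "high", "mid")),
    stringsAsFactors = FALSE)
  sel <- tails$tail != "mid"
  a2 <- ann[match(tails$sample_id[sel], ann$sample_id), , drop = FALSE]
  grp <- tails$tail[sel]

  surv <- km_logrank(a2$os_time, a2$os_event, grp)
  cx <- tryCatch(
    cox_fit(a2$os_time, a2$os_event, data.frame(low_tail = grp == "low")),
    error = function(e) NULL)

  or <- NULL
  if ("responder" %in% names(ann)) {
    resp <- a2$responder
    ok <- !is.na(resp)
    # odds(no response | low) / odds(no response | high)
    a <- sum(!resp[ok] & grp[ok] == "low")
    b <- sum(resp[ok] & grp[ok] == "low")
    cc <- sum(!resp[ok] & grp[ok] == "high")
    d <- sum(resp[ok] & grp[ok] == "high")
    or <- c(odds_ratio_woolf(a, b, cc, d),
            list(table = matrix(c(a, b, cc, d), 2L, byrow = TRUE,
                                dimnames = list(c("low", "high"),
                                                c("NR", "R")))))
  }
  list(tails = tails, survival = surv, cox = cx, odds_ratio = or,
       boundary_ties = boundary_ties,
       mode = attr(scores, "mode") %||% "literal")
}
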