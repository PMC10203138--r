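# Cross-patient meta-clustering: pooled per-patient cluster signatures are
# grouped by hierarchical clustering of their Z-score vectors (correlation
# distance, average linkage), matching phenotypically equivalent clusters
# across patients. Rows whose signature never clears a significance floor
# form a dedicated "no significant change" group.

#' Meta-cluster the pooled signature matrix
#'
#' Hierarchical agglomerative clustering of the Z-score rows with
#' correlation distance (1 - Pearson) and average linkage. K is chosen by
#' maximizing the mean silhouette over `k_range` unless `fixed_k` is
#' given. Rows with no marker reaching `z_floor` in absolute value are
#' assigned to a separate no-signal group before clustering and do not
#' influence K. Meta-clusters are numbered by descending total cell count
#' (the no-signal group is numbered within the same ordering).
#'
#' @param sig a [assemble_signature_matrix()] result (>= 2 rows).
#' @param k_range range of K searched by silhouette (default 8-20).
#' @param fixed_k optional fixed K overriding the silhouette search.
#' @param z_floor |z| floor below which a row counts as no-signal
#'   (default `qnorm(1 - 0.001/2)`, i.e. p < 0.001 two-sided).
#' @param seed recorded in the model; the partition itself is
#'   deterministic given fixed K or the silhouette rule.
#' @return An object of class `metacluster_model`: `assignment` (integer
#'   meta-cluster per signature row), `K` (number of signal meta-clusters),
#'   `no_signal_id` (id of the no-signal group, `NA` if empty), `meta`
#'   (row metadata), `params`.
#' @export
metacluster_signatures <- function(sig, k_range = c(8L, 20L),
                                   fixed_k = NULL,
                                   z_floor = stats::qnorm(1 - 0.001 / 2),
                                   seed = 1L) {
  stopifnot(inherits(sig, "signature_matrix"), nrow(sig$z) >= 2L)
  z <- sig$z
  n <- nrow(z)
  no_signal <- apply(abs(z), 1L, max) < z_floor
  idx <- which(!no_signal)
  raw_assign <- integer(n)

  if (length(idx) == 0L) {
    raw_assign[] <- 1L
    K <- 0L
  } else if (length(idx) == 1L) {
    raw_assign[idx] <- 1L
    K <- 1L
  } else {
    zs <- z[idx, , drop = FALSE]
    d <- correlation_distance(zs)
    if (max(d) < 1e-12) {                      # all-identical rows
      raw_assign[idx] <- 1L
      K <- 1L
    } else {
      hc <- stats::hclust(d, method = "average")
      if (!is.null(fixed_k)) {
        K <- min(as.integer(fixed_k), length(idx))
        raw_assign[idx] <- stats::cutree(hc, k = K)
      } else {
        ks <- seq(max(2L, k_range[1L]), min(k_range[2L], length(idx) - 1L))
        if (!length(ks)) {
          K <- min(2L, length(idx))
          raw_assign[idx] <- stats::cutree(hc, k = K)
        } else {
          sil <- vapply(ks, function(k) {
            mean_silhouette(d, stats::cutree(hc, k = k))
          }, numeric(1))
          K <- ks[which.max(sil)]
          raw_assign[idx] <- stats::cutree(hc, k = K)
        }
      }
    }
  }
  if (any(no_signal)) raw_assign[no_signal] <- K + 1L

  # renumber by descending total cell count for stable naming
  cells <- tapply(sig$meta$n_cells, raw_assign, sum)
  ord <- names(sort(cells, decreasing = TRUE))
  relabel <- stats::setNames(seq_along(ord), ord)
  assignment <- unname(relabel[as.character(raw_assign)])
  no_signal_id <- if (any(no_signal)) {
    unname(relabel[as.character(K + 1L)])
  } else NA_integer_

  structure(list(
    assignment = assignment,
    K = K,
    no_signal_id = no_signal_id,
    meta = sig$meta,
    params = list(k_range = k_range, fixed_k = fixed_k, z_floor = z_floor,
                  distance = "1 - Pearson", linkage = "average",
                  seed = as.integer(seed))
  ), class = "metacluster_model")
}

#' @export
print.metacluster_model <- function(x, ...) {
  cat("metacluster_model:", x$K, "signal meta-clusters",
      if (!is.na(x$no_signal_id)) "(+1 no-signal group)" else "",
      "over", length(x$assignment), "cluster signatures\n")
  invisible(x)
}

#' Defining markers of each meta-cluster
#'
#' A marker defines a meta-cluster when (a) the cell-count-weighted median
#' of its Z-scores over the member clusters exceeds `z_threshold` in
#' absolute value, and (b) the member clusters in which the marker is
#' significant (`p < p_threshold`, direction matching the weighted-median
#' sign) jointly contain more than `cell_fraction` of the meta-cluster's
#' cells. Direction is the weighted-median sign, written `"hi"`/`"lo"`.
#' With `count_clusters = TRUE`, rule (b) counts member clusters instead
#' of cells.
#'
#' @param model a [metacluster_signatures()] model.
#' @param sig the signature matrix the model was fit on (needs `p`).
#' @param z_threshold |weighted median z| threshold (default 5).
#' @param cell_fraction required significant-cell coverage (default 0.5).
#' @param p_threshold member-cluster significance level (default 0.001).
#' @param count_clusters count member clusters instead of cells in (b).
#' @return data.frame: meta_cluster, marker, direction, weighted_median_z,
#'   coverage.
#' @export
defining_markers <- function(model, sig, z_threshold = 5,
                             cell_fraction = 0.5, p_threshold = 0.001,
                             count_clusters = FALSE) {
  stopifnot(inherits(model, "metacluster_model"),
            inherits(sig, "signature_matrix"),
            length(model$assignment) == nrow(sig$z))
  if (is.null(sig$p)) stop("signature matrix lacks p-values")
  out <- list()
  for (k in sort(unique(model$assignment))) {
    rows <- which(model$assignment == k)
    w <- sig$meta$n_cells[rows]
    for (mk in colnames(sig$z)) {
      zv <- sig$z[rows, mk]
      wm <- weighted_median(zv, w)
      if (abs(wm) <= z_threshold) next
      sig_rows <- sig$p[rows, mk] < p_threshold & sign(zv) == sign(wm)
      coverage <- if (count_clusters) {
        mean(sig_rows)
      } else {
        sum(w[sig_rows]) / sum(w)
      }
      if (coverage <= cell_fraction) next
      out[[length(out) + 1L]] <- data.frame(
        meta_cluster = k, marker = mk,
        direction = if (wm > 0) "hi" else "lo",
        weighted_median_z = wm, coverage = coverage,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) {
    return(data.frame(meta_cluster = integer(), marker = character(),
                      direction = character(), weighted_median_z = numeric(),
                      coverage = numeric(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res[order(res$meta_cluster, -abs(res$weighted_median_z)), , drop = FALSE]
}

#' Meta-cluster abundance and presence per sample
#'
#' Abundance is the fraction of a sample's gated cells assigned to each
#' meta-cluster (cell counts travel with the signature metadata); presence
#' dichotomizes abundance at `presence_threshold`.
#'
#' @param model a [metacluster_signatures()] model.
#' @param presence_threshold minimum abundance to call a meta-cluster
#'   present (default 0.01 of gated cells).
#' @return list with `abundance` and `presence` (samples x meta-clusters
#'   matrices) and `presence_threshold`.
#' @export
metacluster_abundance <- function(model, presence_threshold = 0.01) {
  stopifnot(inherits(model, "metacluster_model"))
  samples <- unique(model$meta$sample_id)
  ks <- sort(unique(model$assignment))
  ab <- matrix(0, length(samples), length(ks),
               dimnames = list(samples, paste0("MC", ks)))
  for (i in seq_along(model$assignment)) {
    s <- model$meta$sample_id[i]
    k <- match(model$assignment[i], ks)
    ab[s, k] <- ab[s, k] + model$meta$n_cells[i]
  }
  tot <- rowSums(ab)
  ab <- sweep(ab, 1L, pmax(tot, 1L), "/")
  list(abundance = ab, presence = ab >= presence_threshold,
       presence_threshold = presence_threshold)
}

#' Full pooled pipeline: cluster, profile and meta-cluster a cohort
#'
#' Convenience wrapper running, per sample: arcsinh transform, plasma-cell
#' gating, marker exclusion, kNN-Louvain clustering and hurdle
#' differential expression; then pooling all signatures and
#' meta-clustering them. Inputs are raw per-sample matrices.
#'
#' @param samples list of raw [cell_matrix()] objects.
#' @param exclusions markers dropped after gating (default: none).
#' @param rules [gating_rules()] used for plasma-cell gating; `NULL` skips
#'   gating (inputs already gated).
#' @param cofactor arcsinh cofactor.
#' @param cparams [cluster_params()] for the per-sample stage.
#' @param k_range,fixed_k,z_floor passed to [metacluster_signatures()].
#' @param seed master seed; per-sample seeds are derived from it.
#' @return list: `gated` (transformed gated matrices), `labels` (per-sample
#'   cluster labels), `signatures`, `sig` (signature matrix), `model`,
#'   `abundance` (from [metacluster_abundance()]), `cell_meta`
#'   (per-sample data.frame of cell_id, cluster_id, meta_cluster).
#' @export
run_pipeline <- function(samples, exclusions = character(),
                         rules = gating_rules(), cofactor = 5,
                         cparams = cluster_params(),
                         k_range = c(8L, 20L), fixed_k = NULL,
                         z_floor = stats::qnorm(1 - 0.001 / 2), seed = 1L) {
  stopifnot(length(samples) >= 1L)
  gated <- vector("list", length(samples))
  for (i in seq_along(samples)) {
    m <- samples[[i]]
    if (m$transform == "raw") m <- arcsinh_transform(m, cofactor)
    if (!is.null(rules)) m <- gate_plasma_cells(m, rules)$matrix
    gated[[i]] <- m
  }
  names(gated) <- vapply(gated, `[[`, "", "sample_id")
  if (length(exclusions)) {
    analysis <- filter_markers(gated, exclusions,
                               gating_markers = character())
  } else {
    analysis <- gated
  }
  labels <- vector("list", length(analysis))
  signatures <- list()
  for (i in seq_along(analysis)) {
    lab <- cluster_cells(analysis[[i]], cparams,
                         seed = derive_seed(seed, i))
    labels[[i]] <- lab
    signatures <- c(signatures, cluster_signatures(analysis[[i]], lab))
  }
  names(labels) <- names(analysis)
  sig <- assemble_signature_matrix(signatures)
  model <- metacluster_signatures(sig, k_range = k_range, fixed_k = fixed_k,
                                  z_floor = z_floor, seed = seed)
  ab <- metacluster_abundance(model)
  key <- paste(model$meta$sample_id, model$meta$cluster_id, sep = ":")
  mc_of <- stats::setNames(model$assignment, key)
  cell_meta <- lapply(names(analysis), function(s) {
    data.frame(sample_id = s,
               cell_id = analysis[[s]]$cell_ids,
               cluster_id = as.integer(labels[[s]]),
               meta_cluster = unname(mc_of[paste(s, labels[[s]], sep = ":")]),
               stringsAsFactors = FALSE)
  })
  names(cell_meta) <- names(analysis)
  list(gated = gated, labels = labels, signatures = signatures, sig = sig,
       model = model, abundance = ab, cell_meta = cell_meta)
}

#' Marker-exclusion robustness reanalysis
#'
#' Reruns clustering, differential expression and meta-clustering with one
#' marker excluded, and maps every original meta-cluster's cells to their
#' new meta-cluster. The redistribution report gives, per original
#' meta-cluster, the best-matching new meta-cluster (maximum cell overlap)
#' and the fraction of its cells redistributed elsewhere.
#'
#' @param pipeline result of [run_pipeline()] on the full marker set.
#' @param excluded_marker the marker to drop (must not be a gating marker).
#' @param rules the gating rules used (to refuse excluding gate markers).
#' @param ... further arguments passed to [run_pipeline()].
#' @param seed master seed of the rerun.
#' @return list: `model` (new pipeline result) and `redistribution`
#'   (data.frame: orig_mc, new_mc, n_cells, fraction, best_match,
#'   redistributed_fraction).
#' @export
marker_exclusion_reanalysis <- function(pipeline, excluded_marker,
                                        rules = gating_rules(), seed = 1L,
                                        ...) {
  gate_mk <- c(rules$negative_markers, rules$positive_markers,
               rules$light_chain_pair)
  if (excluded_marker %in% gate_mk) {
    stop("cannot exclude gating marker ", excluded_marker)
  }
  if (!excluded_marker %in% pipeline$gated[[1L]]$marker_names) {
    stop("marker not in panel: ", excluded_marker)
  }
  redo <- run_pipeline(pipeline$gated, exclusions = excluded_marker,
                       rules = NULL, seed = seed, ...)
  orig <- do.call(rbind, pipeline$cell_meta)
  new <- do.call(rbind, redo$cell_meta)
  key <- function(df) paste(df$sample_id, df$cell_id, sep = "/")
  new_mc <- stats::setNames(new$meta_cluster, key(new))
  orig$new_mc <- unname(new_mc[key(orig)])
  tab <- as.data.frame(table(orig_mc = orig$meta_cluster,
                             new_mc = orig$new_mc),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, , drop = FALSE]
  names(tab)[3L] <- "n_cells"
  tab$orig_mc <- as.integer(tab$orig_mc)
  tab$new_mc <- as.integer(tab$new_mc)
  tot <- tapply(tab$n_cells, tab$orig_mc, sum)
  tab$fraction <- tab$n_cells / tot[as.character(tab$orig_mc)]
  best <- do.call(rbind, lapply(split(tab, tab$orig_mc), function(d) {
    b <- d[which.max(d$n_cells), ]
    data.frame(orig_mc = b$orig_mc, best_match = b$new_mc,
               redistributed_fraction = 1 - b$fraction)
  }))
  rownames(best) <- NULL
  list(model = redo, redistribution = tab[order(tab$orig_mc, -tab$n_cells), ],
       best_match = best)
}

#' 2-D embedding of the pooled cluster signatures
#'
#' Classical multidimensional scaling of the correlation distance between
#' Z-score rows, exported with meta-cluster labels for plotting. The
#' layout is deterministic; `seed` is recorded for provenance.
#'
#' @param sig a `signature_matrix` (>= 3 rows).
#' @param model optional model supplying meta-cluster labels.
#' @param seed recorded seed.
#' @return data.frame: sample_id, cluster_id, dim1, dim2, meta_cluster.
#' @export
embed_signatures <- function(sig, model = NULL, seed = 1L) {
  stopifnot(inherits(sig, "signature_matrix"), nrow(sig$z) >= 3L)
  d <- correlation_distance(sig$z)
  xy <- suppressWarnings(stats::cmdscale(d, k = 2L))
  if (ncol(xy) < 2L) {              # degenerate (e.g. identical rows)
    xy <- cbind(xy, matrix(0, nrow(sig$z), 2L - ncol(xy)))
  }
  out <- data.frame(sample_id = sig$meta$sample_id,
                    cluster_id = sig$meta$cluster_id,
                    dim1 = xy[, 1L], dim2 = xy[, 2L],
                    stringsAsFactors = FALSE)
  out$meta_cluster <- if (!is.null(model)) model$assignment else NA_integer_
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Write a meta-cluster model as JSON
#' @param model a `metacluster_model`.
#' @param path output path.
#' @param defining optional [defining_markers()] table to embed.
#' @export
write_metacluster_model <- function(model, path, defining = NULL) {
  obj <- list(
    assignment = data.frame(model$meta,
                            meta_cluster = model$assignment,
                            stringsAsFactors = FALSE),
    K = model$K, no_signal_id = model$no_signal_id,
    params = model$params, defining_markers = defining
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
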