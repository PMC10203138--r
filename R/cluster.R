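# Per-patient unsupervised clustering: Louvain community detection on a
# k-nearest-neighbour graph of cells, with the resolution tuned so the
# cluster count lands in a target band when attainable. Clustering is
# strictly per sample; no cross-sample batch correction.

#' Clustering parameters for [cluster_cells()]
#'
#' @param k neighbours per cell in the kNN graph (default 30).
#' @param target_k length-2 target band for the cluster count (default
#'   11-29, the per-patient range this pipeline is tuned to).
#' @param min_cluster_size clusters below this are merged to the nearest
#'   centroid (default 25 cells).
#' @param resolution_band band of Louvain resolutions searched.
#' @param resolution_steps grid size of the search.
#' @param n_pc number of principal components for the kNN graph (the usual
#'   single-cell denoising step; signatures are still computed on the
#'   markers). `0` builds the graph on the raw marker space.
#' @return A list of parameters.
#' @export
cluster_params <- function(k = 30L, target_k = c(11L, 29L),
                           min_cluster_size = 25L,
                           resolution_band = c(0.05, 8),
                           resolution_steps = 12L,
                           n_pc = 10L) {
  list(k = as.integer(k), target_k = as.integer(target_k),
       min_cluster_size = as.integer(min_cluster_size),
       resolution_band = resolution_band,
       resolution_steps = as.integer(resolution_steps),
       n_pc = as.integer(n_pc))
}

# Exact kNN by blocked Euclidean distance (BLAS crossprod); returns an
# n x k index matrix.
knn_index <- function(x, k, block = 2048L) {
  n <- nrow(x)
  k <- min(k, n - 1L)
  sq <- rowSums(x^2)
  out <- matrix(0L, n, k)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    d2 <- outer(sq[idx], sq, "+") - 2 * tcrossprod(x[idx, , drop = FALSE], x)
    for (r in seq_along(idx)) {
      d2[r, idx[r]] <- Inf
      out[idx[r], ] <- order(d2[r, ])[seq_len(k)]
    }
  }
  out
}

knn_graph <- function(x, k) {
  nn <- knn_index(x, k)
  n <- nrow(x)
  edges <- cbind(rep(seq_len(n), ncol(nn)), as.vector(nn))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  igraph::simplify(g)
}

merge_small_clusters <- function(x, labels, min_size) {
  repeat {
    sizes <- table(labels)
    small <- names(sizes)[sizes < min_size]
    if (!length(small) || length(sizes) == 1L) break
    big <- setdiff(names(sizes), small)
    if (!length(big)) {             # everything small: collapse to largest
      keep <- names(sizes)[which.max(sizes)]
      labels[] <- keep
      break
    }
    centroids <- t(vapply(big, function(l) {
      colMeans(x[labels == l, , drop = FALSE])
    }, numeric(ncol(x))))
    worst <- small[which.min(sizes[small])]
    cells <- which(labels == worst)
    d2 <- outer(rowSums(x[cells, , drop = FALSE]^2), rowSums(centroids^2),
                "+") - 2 * tcrossprod(x[cells, , drop = FALSE], centroids)
    labels[cells] <- big[apply(d2, 1L, which.min)]
  }
  as.integer(factor(labels))
}

#' Cluster one sample's cells
#'
#' Louvain community detection on the kNN graph of the (gated, transformed,
#' marker-filtered) cells. The resolution is searched over
#' `params$resolution_band` for a post-merge cluster count inside
#' `params$target_k`; when the band cannot reach the target the closest
#' attainable count is used with a warning. Clusters smaller than
#' `min_cluster_size` are dissolved into the nearest remaining centroid.
#'
#' @param m a transformed [cell_matrix()].
#' @param params a [cluster_params()] list.
#' @param seed integer seed (Louvain is stochastic).
#' @return Integer label vector (one label per cell, 1..K) with attributes
#'   `resolution` and `k`.
#' @export
cluster_cells <- function(m, params = cluster_params(), seed = 1L) {
  stopifnot(inherits(m, "cell_matrix"))
  x <- m$values
  n <- nrow(x)
  if (n < params$min_cluster_size) {
    warning("fewer cells (", n, ") than min cluster size; single cluster")
    return(structure(rep(1L, n), resolution = NA_real_, k = 1L))
  }
  if (nrow(unique(x)) == 1L) {
    return(structure(rep(1L, n), resolution = NA_real_, k = 1L))
  }
  if (params$n_pc > 0L && params$n_pc < ncol(x)) {
    x <- stats::prcomp(x, rank. = params$n_pc)$x
  }
  g <- knn_graph(x, params$k)
  grid <- exp(seq(log(params$resolution_band[1L]),
                  log(params$resolution_band[2L]),
                  length.out = params$resolution_steps))
  best <- NULL
  for (res in grid) {
    set.seed(as.integer(seed))
    comm <- igraph::cluster_louvain(g, resolution = res)
    lab <- merge_small_clusters(x, igraph::membership(comm),
                                params$min_cluster_size)
    kk <- max(lab)
    in_range <- kk >= params$target_k[1L] && kk <= params$target_k[2L]
    score <- if (in_range) {
      abs(kk - mean(params$target_k))          # prefer mid-band counts
    } else {
      1e6 + min(abs(kk - params$target_k))     # out of band: closest
    }
    if (is.null(best) || score < best$score) {
      best <- list(labels = lab, k = kk, res = res, score = score,
                   in_range = in_range)
    }
  }
  if (!best$in_range) {
    warning("target cluster-count range [", params$target_k[1L], ", ",
            params$target_k[2L], "] not attainable; got ", best$k)
  }
  structure(best$labels, resolution = best$res, k = best$k)
}
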