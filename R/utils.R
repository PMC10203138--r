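`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 means identical partitions, 0 is the expectation under random labeling.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return A single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) > 0L)
  tab <- table(a, b)
  n <- length(a)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

# Lower weighted median: smallest x with cumulative weight >= half the total.
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w >= 0), sum(w) > 0)
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1L]]
}

# Otsu's threshold on a 1-D sample: exact scan over sorted split points,
# maximizing between-class variance. Returns the midpoint between the two
# class-boundary values, plus a separability score (fraction of total
# variance explained by the split) used as a bimodality guard.
otsu_split <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 2L || stats::var(x) == 0) {
    return(list(threshold = NA_real_, separability = 0))
  }
  csum <- cumsum(x)
  tot <- csum[n]
  k <- seq_len(n - 1L)
  m1 <- csum[k] / k
  m2 <- (tot - csum[k]) / (n - k)
  between <- (k / n) * (1 - k / n) * (m1 - m2)^2
  kbest <- which.max(between)
  list(
    threshold = (x[kbest] + x[kbest + 1L]) / 2,
    separability = max(between) / (stats::var(x) * (n - 1) / n)
  )
}

# Mean silhouette width for a labeling given a full distance matrix.
# Singleton clusters get silhouette 0 (the usual convention).
mean_silhouette <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  labels <- as.character(labels)
  ids <- unique(labels)
  if (length(ids) < 2L) return(NA_real_)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    n_own <- sum(own) - 1L
    if (n_own == 0L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / n_own
    b <- min(vapply(ids[ids != labels[i]],
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Correlation distance (1 - Pearson) between rows of a matrix, with
# zero-variance rows placed at maximal distance (1) from everything.
correlation_distance <- function(m) {
  sds <- apply(m, 1L, stats::sd)
  ok <- sds > 0
  cc <- matrix(0, nrow(m), nrow(m))
  if (sum(ok) >= 2L) cc[ok, ok] <- stats::cor(t(m[ok, , drop = FALSE]))
  diag(cc) <- 1
  stats::as.dist(1 - cc)
}

#' Derive a stream-specific seed from a master seed
#'
#' Deterministic 32-bit seed for a named sub-stream (per-sample
#' clustering, expression arm, ...) so one master seed drives every
#' stochastic stage without reuse.
#'
#' @param seed master integer seed.
#' @param offset integer stream index.
#' @return An integer below 2^31.
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# Structured per-stage run metadata, written as a JSON sidecar.
write_run_metadata <- function(path, stage, params = list(), seed = NULL,
                               inputs = character(), outputs = character()) {
  meta <- list(
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    params = params,
    inputs = as.list(inputs),
    outputs = as.list(outputs)
  )
  jsonlite::write_json(meta, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
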