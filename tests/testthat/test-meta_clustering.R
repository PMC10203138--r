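# Build a signature matrix directly: per archetype a fixed z-pattern over
# the markers, one row per (sample, archetype), plus Gaussian row noise.
synth_sig <- function(n_samples = 10, K = 4, n_markers = 20, noise = 0.5,
                      z_scale = 12, seed = 1, n_cells = NULL) {
  set.seed(seed)
  markers <- sprintf("M%02d", seq_len(n_markers))
  patterns <- matrix(0, K, n_markers)
  for (k in seq_len(K)) {
    patterns[k, ((k - 1) * 3 + 1):((k - 1) * 3 + 3)] <-
      z_scale * sample(c(-1, 1), 3, replace = TRUE)
  }
  rows <- list(); meta <- list()
  for (s in seq_len(n_samples)) {
    for (k in seq_len(K)) {
      rows[[length(rows) + 1L]] <-
        patterns[k, ] + rnorm(n_markers, sd = noise)
      meta[[length(meta) + 1L]] <-
        data.frame(sample_id = sprintf("S%02d", s), cluster_id = k,
                   n_cells = if (is.null(n_cells)) {
                     sample(50:200, 1)
                   } else n_cells,
                   stringsAsFactors = FALSE)
    }
  }
  z <- do.call(rbind, rows)
  colnames(z) <- markers
  meta <- do.call(rbind, meta)
  rownames(z) <- paste(meta$sample_id, meta$cluster_id, sep = ":")
  p <- 2 * pnorm(-abs(z))
  structure(list(z = z, p = p, frac = (abs(z) > 5) * 0.9, meta = meta),
            class = "signature_matrix")
}

test_that("planted signature archetypes are recovered exactly at low noise", {
  sig <- synth_sig(n_samples = 10, K = 4, noise = 0.3, seed = 2)
  model <- metacluster_signatures(sig, k_range = c(2L, 10L))
  expect_equal(model$K, 4L)
  truth <- rep(1:4, 10)
  expect_equal(adjusted_rand_index(model$assignment, truth), 1.0)
  # abundances per sample sum to 1 over assigned cells
  ab <- metacluster_abundance(model)
  expect_true(all(abs(rowSums(ab$abundance) - 1) < 1e-9))
})

test_that("the partition is invariant to row order", {
  sig <- synth_sig(n_samples = 8, K = 3, noise = 0.4, seed = 3)
  model <- metacluster_signatures(sig, k_range = c(2L, 8L))
  perm <- sample(nrow(sig$z))
  sig2 <- sig
  sig2$z <- sig$z[perm, ]; sig2$p <- sig$p[perm, ]
  sig2$frac <- sig$frac[perm, ]; sig2$meta <- sig$meta[perm, ]
  model2 <- metacluster_signatures(sig2, k_range = c(2L, 8L))
  expect_equal(adjusted_rand_index(model$assignment[perm],
                                   model2$assignment), 1.0)
})

test_that("degenerate signature matrices collapse to one group", {
  sig <- synth_sig(n_samples = 3, K = 1, noise = 0, seed = 4)
  model <- metacluster_signatures(sig, k_range = c(2L, 6L))
  expect_equal(length(unique(model$assignment)), 1L)
})

test_that("no-signal rows form their own group and do not disturb K", {
  sig <- synth_sig(n_samples = 8, K = 3, noise = 0.3, seed = 5)
  # append flat rows (max |z| below the p < 0.001 floor)
  flat <- matrix(rnorm(5 * ncol(sig$z), sd = 0.5), 5,
                 dimnames = list(paste0("S99:", 1:5), colnames(sig$z)))
  sig$z <- rbind(sig$z, flat)
  sig$p <- rbind(sig$p, 2 * pnorm(-abs(flat)))
  sig$frac <- rbind(sig$frac, flat * 0)
  sig$meta <- rbind(sig$meta,
                    data.frame(sample_id = "S99", cluster_id = 1:5,
                               n_cells = 30))
  model <- metacluster_signatures(sig, k_range = c(2L, 8L))
  expect_equal(model$K, 3L)
  expect_false(is.na(model$no_signal_id))
  expect_true(all(model$assignment[25:29] == model$no_signal_id))
})

test_that("defining markers follow the weighted-median and coverage rules", {
  markers <- c("CD45", "BCL-2", "CD71")
  z <- rbind(c(8, -7, 0.5), c(9, -6, -0.2), c(7.5, -8, 0.1))
  p <- 2 * pnorm(-abs(z))
  colnames(z) <- colnames(p) <- markers
  rownames(z) <- rownames(p) <- paste0("S", 1:3, ":1")
  meta <- data.frame(sample_id = paste0("S", 1:3), cluster_id = 1,
                     n_cells = c(100, 120, 80))
  sig <- structure(list(z = z, p = p, frac = abs(z) / 10, meta = meta),
                   class = "signature_matrix")
  model <- structure(list(assignment = rep(1L, 3), K = 1L,
                          no_signal_id = NA_integer_, meta = meta,
                          params = list()),
                     class = "metacluster_model")
  dm <- defining_markers(model, sig)
  expect_setequal(dm$marker, c("CD45", "BCL-2"))
  expect_identical(dm$direction[dm$marker == "CD45"], "hi")
  expect_identical(dm$direction[dm$marker == "BCL-2"], "lo")

  # weighted-median z of 4 stays below the threshold of 5
  z2 <- z; z2[, "CD45"] <- c(4, 4.2, 3.8)
  sig2 <- sig; sig2$z <- z2; sig2$p <- 2 * pnorm(-abs(z2))
  dm2 <- defining_markers(model, sig2)
  expect_false("CD45" %in% dm2$marker)

  # coverage rule: significance must span > half the cells
  p3 <- p; p3[2:3, "CD45"] <- 0.5        # only 100 of 300 cells significant
  sig3 <- sig; sig3$p <- p3
  dm3 <- defining_markers(model, sig3)
  expect_false("CD45" %in% dm3$marker)
})

test_that("abundance and presence follow the cell counts", {
  meta <- data.frame(sample_id = c("A", "A", "B"), cluster_id = c(1, 2, 1),
                     n_cells = c(995, 5, 200))
  model <- structure(list(assignment = c(1L, 2L, 1L), K = 2L,
                          no_signal_id = NA_integer_, meta = meta,
                          params = list()),
                     class = "metacluster_model")
  ab <- metacluster_abundance(model, presence_threshold = 0.01)
  expect_equal(unname(ab$abundance["A", ]), c(0.995, 0.005))
  expect_equal(unname(ab$abundance["B", ]), c(1, 0))
  expect_false(ab$presence["A", "MC2"])    # 0.005 below the 1% floor
  expect_true(ab$presence["A", "MC1"])
})

test_that("excluding an irrelevant marker leaves the meta-structure intact", {
  lib <- random_archetypes(3, seed = 21)
  co <- simulate_cohort(8, archetypes = lib,
                        params = quick_params(cells = c(500, 700)), seed = 61)
  pipe <- suppressWarnings(
    run_pipeline(co$samples, exclusions = ANALYSIS_EXCLUSIONS,
                 k_range = c(2L, 8L), seed = 5))
  # exclude a marker that defines no planted archetype
  planted <- unlist(lapply(lib, function(a) a$defining_markers$marker))
  irrelevant <- setdiff(c("pAKT", "pCREB", "pRB", "CD274", "CRBN"),
                        planted)[1]
  redo <- suppressWarnings(
    marker_exclusion_reanalysis(pipe, irrelevant, k_range = c(2L, 8L),
                                seed = 6))
  orig <- do.call(rbind, pipe$cell_meta)
  new <- do.call(rbind, redo$model$cell_meta)
  key <- paste(orig$sample_id, orig$cell_id)
  m2 <- match(key, paste(new$sample_id, new$cell_id))
  expect_gte(adjusted_rand_index(orig$meta_cluster, new$meta_cluster[m2]),
             0.95)
  expect_error(marker_exclusion_reanalysis(pipe, "CD138"), "gating")
  expect_error(marker_exclusion_reanalysis(pipe, "NOPE"), "NOPE")
})

test_that("excluding an archetype's sole defining marker removes its group", {
  lib <- list(
    archetype("T01", "CD56", "hi", 4),                 # sole defining marker
    archetype("T02", c("CD81", "MCL-1", "pS6"), "hi", 3),
    archetype("T03", c("CD71", "pERK", "Ki-67"), "hi", 3))
  pp <- quick_params(cells = c(600, 800), n_arch = c(3L, 3L),
                     noise_sd = 0.25)
  co <- simulate_cohort(8, archetypes = lib, params = pp, seed = 62)
  pipe <- suppressWarnings(
    run_pipeline(co$samples, exclusions = ANALYSIS_EXCLUSIONS,
                 k_range = c(2L, 8L), seed = 7))
  redo <- suppressWarnings(
    marker_exclusion_reanalysis(pipe, "CD56", k_range = c(2L, 8L), seed = 8))
  k_before <- length(unique(pipe$model$assignment))
  k_after <- length(unique(redo$model$model$assignment))
  expect_equal(k_before - k_after, 1L)
  # without its only marker the archetype is baseline: its old group and
  # the old baseline group must land in the same new meta-cluster
  truth <- row_truth_labels(pipe, co)
  t01_mc <- as.integer(names(which.max(table(
    pipe$model$assignment[truth == "T01"]))))
  base_mc <- as.integer(names(which.max(table(
    pipe$model$assignment[truth == "baseline"]))))
  expect_false(t01_mc == base_mc)
  bm <- redo$best_match
  expect_equal(bm$best_match[bm$orig_mc == t01_mc],
               bm$best_match[bm$orig_mc == base_mc])
})

test_that("the 2-D embedding is deterministic and separates planted groups", {
  sig <- synth_sig(n_samples = 6, K = 4, noise = 0.4, seed = 7)
  model <- metacluster_signatures(sig, k_range = c(2L, 8L))
  e1 <- embed_signatures(sig, model, seed = 1)
  e2 <- embed_signatures(sig, model, seed = 1)
  expect_identical(e1$dim1, e2$dim1)
  d <- dist(cbind(e1$dim1, e1$dim2))
  sil <- cytometa:::mean_silhouette(d, model$assignment)
  expect_gt(sil, 0)

  # identical rows land on coincident points
  zid <- matrix(rep(c(6, -6, 1, 0), each = 3), 3, 4,
                dimnames = list(paste0("S", 1:3, ":1"),
                                paste0("M", 1:4)))
  sid <- structure(list(z = zid, p = 2 * pnorm(-abs(zid)), frac = zid * 0,
                        meta = data.frame(sample_id = paste0("S", 1:3),
                                          cluster_id = 1, n_cells = 50)),
                   class = "signature_matrix")
  ei <- embed_signatures(sid, seed = 1)
  expect_lt(max(dist(cbind(ei$dim1, ei$dim2))), 1e-8)
})
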