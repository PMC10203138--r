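# Shared fixture builders. Cohort sizes are scaled down from the
# real-world defaults (500-50,000 cells/sample) so the suite stays fast;
# the planted structure is unchanged.

quick_params <- function(cells = c(600, 900), n_arch = c(2L, 4L),
                         noise_sd = 0.25, effect_archetype = "T01",
                         clinical_effects = list(),
                         hr_presence = 0.21, ...) {
  cohort_params(cells_per_sample = cells,
                archetypes_per_sample = n_arch,
                noise_sd = noise_sd,
                clinical_effects = clinical_effects,
                survival_effect = list(archetype = effect_archetype,
                                       hr_presence = hr_presence,
                                       baseline_hazard = log(2) / 2.2,
                                       censor_horizon = 12),
                ...)
}

ANALYSIS_EXCLUSIONS <- c("SOX2", "CD27", "CD147")

# Majority planted label of every pooled cluster row of a pipeline run.
row_truth_labels <- function(pipe, cohort) {
  vapply(seq_len(nrow(pipe$model$meta)), function(i) {
    sid <- pipe$model$meta$sample_id[i]
    cl <- pipe$model$meta$cluster_id[i]
    cm <- pipe$cell_meta[[sid]]
    ids <- cm$cell_id[cm$cluster_id == cl]
    labs <- cohort$truth$cell_labels[[sid]][
      match(ids, cohort$samples[[sid]]$cell_ids)]
    names(sort(table(labs), decreasing = TRUE))[1L]
  }, character(1))
}

# A small clinical table with the exact marginal counts of a 49-patient
# myeloma cohort (33 M / 16 F, 20 NDMM / 29 RRMM, response 7/20/6/7/9,
# primary 24/15/4/2/2/2, TP53 12, 1q 28, MYC 13, mSMART 34 high).
clinical_fixture_49 <- function() {
  n <- 49L
  rep_counts <- function(levels, counts) rep(levels, counts)
  df <- data.frame(
    sample_id = sprintf("P%02d", 1:n),
    response = rep_counts(c("VGPR", "PR", "MR", "SD", "PD"),
                          c(7, 20, 6, 7, 9)),
    sex = rep_counts(c("M", "F"), c(33, 16)),
    age = rep(67, n),
    disease_type = rep_counts(c("NDMM", "RRMM"), c(20, 29)),
    primary_abnormality = rep_counts(
      c("hyperdiploidy", "t(11;14)", "t(4;14)", "t(14;20)",
        "hyperhaploid", "undefined"),
      c(24, 15, 4, 2, 2, 2)),
    tp53_del = rep(c(TRUE, FALSE), c(12, 37)),
    gain_1q = rep(c(TRUE, FALSE), c(28, 21)),
    myc_rearr = rep(c(TRUE, FALSE), c(13, 36)),
    monosomy13 = rep(c(TRUE, FALSE), c(34, 15)),
    del13q = rep(c(TRUE, FALSE), c(20, 29)),
    msmart = rep_counts(c("high", "standard"), c(34, 15)),
    s_phase_pct = rep(1.5, n),
    os_time = rep(5, n),
    os_event = rep(FALSE, n),
    dara_within_6mo = rep(c(TRUE, FALSE), c(14, 35)),
    sampled_within_6mo_of_dx = rep(c(TRUE, FALSE), c(24, 25)),
    stringsAsFactors = FALSE
  )
  df
}

# Hand-made cell matrix on the arcsinh scale covering the gating markers.
gating_fixture_matrix <- function(values_by_marker, sample_id = "fix") {
  markers <- names(values_by_marker)
  v <- do.call(cbind, values_by_marker)
  cell_matrix(v, sample_id, markers, transform = "arcsinh")
}
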