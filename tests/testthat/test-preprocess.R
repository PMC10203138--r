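test_that("arcsinh transform matches the closed form and is monotone", {
  m <- cell_matrix(matrix(c(0, 5, 1, 10, 2, 100), 3, 2), "s",
                   c("A", "B"))
  t5 <- arcsinh_transform(m, cofactor = 5)
  expect_identical(t5$transform, "arcsinh")
  expect_equal(unname(t5$values[1, 1]), 0)
  expect_equal(unname(t5$values[2, 1]), asinh(1))  # = log(1 + sqrt(2))
  expect_equal(asinh(1), log(1 + sqrt(2)))
  x <- sort(runif(50, 0, 1000))
  tx <- arcsinh_transform(cell_matrix(matrix(x), "s", "A"))$values[, 1]
  expect_true(all(diff(tx) > 0))
  expect_error(arcsinh_transform(t5), "transformed")
  expect_error(arcsinh_transform(m, cofactor = 0))
})

test_that("hand-constructed gating fixture keeps exactly the rule-passing cells", {
  lo <- 0.3; hi <- 4
  # 10 cells; cells 1-4 satisfy every rule with kappa dominant
  fix <- gating_fixture_matrix(list(
    CD16  = c(lo, lo, lo, lo, hi, lo, lo, lo, lo, lo),
    CD3   = c(lo, lo, lo, lo, lo, hi, lo, lo, lo, lo),
    CD19  = c(lo, lo, lo, lo, lo, lo, hi, lo, lo, lo),
    CD138 = c(hi, hi, hi, hi, hi, hi, hi, lo, hi, hi),
    IRF4  = c(hi, hi, hi, hi, hi, hi, hi, hi, lo, hi),
    kappa = c(hi, hi, hi, hi, hi, hi, hi, hi, hi, lo),
    lambda = rep(lo, 10)
  ))
  thr <- setNames(rep(2, 7), fix$marker_names)
  rules <- gating_rules(thresholds = thr, min_cells = 4L)
  g <- gate_plasma_cells(fix, rules)
  expect_equal(g$report$n_kept, 4L)
  expect_equal(g$matrix$cell_ids, fix$cell_ids[1:4])
  expect_identical(g$report$restricted_chain, "kappa")
  expect_false(g$report$below_min_cells)
  expect_equal(g$report$polytypic_fraction, 0)
})

test_that("all-CD3-high input yields zero kept cells and a flag, not an error", {
  fix <- gating_fixture_matrix(list(
    CD16 = rep(0.3, 8), CD3 = rep(4, 8), CD19 = rep(0.3, 8),
    CD138 = rep(4, 8), IRF4 = rep(4, 8), kappa = rep(4, 8),
    lambda = rep(0.3, 8)))
  thr <- setNames(rep(2, 7), fix$marker_names)
  g <- gate_plasma_cells(fix, gating_rules(thresholds = thr))
  expect_equal(g$report$n_kept, 0L)
  expect_true(g$report$below_min_cells)
  expect_equal(nrow(g$matrix$values), 0L)
})

test_that("on a clean simulated sample gating recovers the planted PCs exactly", {
  lib <- random_archetypes(2, seed = 3)
  pp <- quick_params(cells = c(500, 500), n_arch = c(2L, 2L),
                     noise_sd = 0.15, dropout = 0,
                     contaminant_fraction = 0.3)
  co <- simulate_cohort(2, archetypes = lib, params = pp, seed = 17)
  m <- arcsinh_transform(co$samples[[1]])
  thr <- setNames(rep(2, 7), c("CD16", "CD3", "CD19", "CD138", "IRF4",
                               "kappa", "lambda"))
  g <- gate_plasma_cells(m, gating_rules(thresholds = thr))
  truth_pc <- !grepl("contaminant", co$truth$cell_labels[[1]])
  kept <- m$cell_ids %in% g$matrix$cell_ids
  expect_identical(kept, truth_pc)
})

test_that("gating is idempotent and monotone in its thresholds", {
  lib <- random_archetypes(2, seed = 8)
  co <- simulate_cohort(2, archetypes = lib,
                        params = quick_params(cells = c(600, 600)), seed = 19)
  m <- arcsinh_transform(co$samples[[1]])
  g1 <- gate_plasma_cells(m)            # adaptive thresholds
  g2 <- gate_plasma_cells(g1$matrix)    # re-gate the gated matrix
  expect_identical(g2$matrix$cell_ids, g1$matrix$cell_ids)

  thr <- setNames(rep(2, 7), c("CD16", "CD3", "CD19", "CD138", "IRF4",
                               "kappa", "lambda"))
  kept_at <- function(th) gate_plasma_cells(m, gating_rules(thresholds = th))$report$n_kept
  # raising a positive-marker threshold can only shrink the gate
  up <- thr; up["CD138"] <- 3
  expect_lte(kept_at(up), kept_at(thr))
  # raising a negative-marker threshold can only grow it
  neg <- thr; neg["CD3"] <- 3
  expect_gte(kept_at(neg), kept_at(thr))
})

test_that("marker filtering drops the batch exclusions and guards the gate", {
  lib <- random_archetypes(2, seed = 12)
  co <- simulate_cohort(2, archetypes = lib,
                        params = quick_params(cells = c(80, 80)), seed = 23)
  filtered <- filter_markers(co$samples, ANALYSIS_EXCLUSIONS)
  expect_length(filtered[[1]]$marker_names, 34L)
  expect_false(any(ANALYSIS_EXCLUSIONS %in% filtered[[1]]$marker_names))
  # order of the remaining markers is preserved
  expect_identical(filtered[[1]]$marker_names,
                   setdiff(co$samples[[1]]$marker_names, ANALYSIS_EXCLUSIONS))
  expect_identical(filter_markers(co$samples, character())[[1]]$values,
                   co$samples[[1]]$values)
  expect_error(filter_markers(co$samples, "CD138"), "gating")
  expect_error(filter_markers(co$samples, "NOPE"), "NOPE")
  # the CD38-exclusion reanalysis input is just another filter call
  no38 <- filter_markers(co$samples, "CD38")
  expect_false("CD38" %in% no38[[1]]$marker_names)
})

test_that("cohort summary reproduces printed-style percentages", {
  df <- clinical_fixture_49()
  sm <- summarize_cohort(df)
  cat_row <- function(field, level) {
    sm$categorical[sm$categorical$field == field &
                     sm$categorical$level == level, ]
  }
  expect_equal(cat_row("sex", "M")$pct, 67.3)
  expect_equal(cat_row("sex", "F")$pct, 32.7)
  expect_equal(cat_row("primary_abnormality", "hyperdiploidy")$pct, 49.0)
  # per-field percentages sum to 100 +/- rounding
  for (f in unique(sm$categorical$field)) {
    tot <- sum(sm$categorical$pct[sm$categorical$field == f])
    expect_lt(abs(tot - 100), 0.2)
  }
  one <- summarize_cohort(df[1, ])
  expect_true(all(one$categorical$pct == 100))
  expect_equal(sm$numeric$median[sm$numeric$field == "age"], 67)
})
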