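test_that("two well-separated planted archetypes are recovered as 2 clusters", {
  lib <- list(archetype("T01", c("CD45", "BCL-2", "CD81"), "hi", 3),
              archetype("T02", c("CD71", "MCL-1", "pS6"), "hi", 3))
  pp <- quick_params(cells = c(2000, 2000), n_arch = c(2L, 2L),
                     noise_sd = 0.2, baseline_fraction = 0,
                     contaminant_fraction = 0, archetype_weight = 0.5,
                     clinical_effects = list(
                       list(archetype = "T01", covariate = "msmart_high",
                            log2fc = 0)))
  co <- simulate_cohort(2, archetypes = lib, params = pp, seed = 51)
  m <- arcsinh_transform(co$samples[[1]])
  lab <- cluster_cells(m, cluster_params(target_k = c(2L, 4L)), seed = 3)
  expect_equal(attr(lab, "k"), 2L)
  truth <- co$truth$cell_labels[[1]]
  expect_gte(adjusted_rand_index(lab, truth), 0.95)
})

test_that("clustering is deterministic and degenerate inputs behave", {
  lib <- random_archetypes(3, seed = 2)
  co <- simulate_cohort(2, archetypes = lib,
                        params = quick_params(cells = c(500, 500)), seed = 52)
  m <- arcsinh_transform(co$samples[[1]])
  a <- suppressWarnings(cluster_cells(m, cluster_params(), seed = 9))
  b <- suppressWarnings(cluster_cells(m, cluster_params(), seed = 9))
  expect_identical(as.integer(a), as.integer(b))

  ident <- cell_matrix(matrix(2, 100, 4), "s", c("A", "B", "C", "D"),
                       transform = "arcsinh")
  expect_equal(max(cluster_cells(ident, cluster_params(), seed = 1)), 1L)

  tiny <- cell_matrix(matrix(rnorm(10 * 4, 5), 10, 4), "s",
                      c("A", "B", "C", "D"), transform = "arcsinh")
  expect_warning(lt <- cluster_cells(tiny, cluster_params(), seed = 1),
                 "single cluster")
  expect_equal(max(lt), 1L)
})

test_that("cluster sizes always sum to the sample's cell count", {
  lib <- random_archetypes(3, seed = 6)
  co <- simulate_cohort(3, archetypes = lib,
                        params = quick_params(cells = c(400, 700)), seed = 53)
  for (m in co$samples) {
    mt <- arcsinh_transform(m)
    lab <- suppressWarnings(cluster_cells(mt, cluster_params(), seed = 4))
    expect_equal(sum(table(lab)), nrow(mt$values))
    expect_true(all(table(lab) >= 25) || max(lab) == 1L)
  }
})

test_that("hurdle z matches the hand-computed worked fixtures", {
  # fixture A: 6 cells, one zero -> detection part uninformative,
  # combined = level part alone
  vals <- c(2.0, 2.5, 3.0, 0, 0.5, 1.0)
  m <- cell_matrix(matrix(vals), "s", "M", transform = "arcsinh")
  de <- differential_expression(m, c(1, 1, 1, 2, 2, 2), 1)
  o <- oracle_hurdle(c(2.0, 2.5, 3.0), c(0, 0.5, 1.0))
  # hand values: z1 = (1 - 2/3)/sqrt((5/6)(1/6)(2/3)), z2 = 1.75/0.38188
  expect_equal(o$z1, 1.095445, tolerance = 1e-6)
  expect_equal(o$z2, 4.582576, tolerance = 1e-6)
  expect_true(is.na(de$stats$z_detect))     # 1 zero < informative minimum
  expect_equal(de$stats$z_level, o$z2, tolerance = 1e-10)
  expect_equal(de$stats$z, o$z, tolerance = 1e-10)
  expect_equal(de$stats$p, o$p, tolerance = 1e-10)

  # fixture B: enough zeros on both sides -> full Stouffer combination
  set.seed(88)
  cl_vals <- c(rep(0, 12), rnorm(48, 3, 0.5))
  rest_vals <- c(rep(0, 25), rnorm(75, 2, 0.5))
  m2 <- cell_matrix(matrix(pmax(c(cl_vals, rest_vals), 0)), "s", "M",
                    transform = "arcsinh")
  lab2 <- rep(c(1, 2), c(60, 100))
  de2 <- differential_expression(m2, lab2, 1)
  o2 <- oracle_hurdle(cl_vals, rest_vals)
  expect_equal(de2$stats$z_detect, o2$z1, tolerance = 1e-10)
  expect_equal(de2$stats$z_level, o2$z2, tolerance = 1e-10)
  expect_equal(de2$stats$z, (o2$z1 + o2$z2) / sqrt(2) * sign(o2$z),
               tolerance = 1e-10)
  expect_equal(de2$stats$z, o2$z, tolerance = 1e-10)
})

test_that("planted +3 SD fully-detected marker clears the defining threshold", {
  set.seed(90)
  cl <- rnorm(100, 3.75, 0.25)       # +3 SD above a 3.0 baseline
  rest <- rnorm(400, 3.0, 0.25)
  m <- cell_matrix(matrix(c(cl, rest)), "s", "M", transform = "arcsinh")
  de <- differential_expression(m, rep(c(1, 2), c(100, 400)), 1)
  expect_identical(de$stats$direction, "up")
  expect_gt(de$stats$z, 5)
  expect_gt(de$stats$frac_changed, 0.5)
})

test_that("constant markers and antisymmetry behave as specified", {
  set.seed(91)
  v <- cbind(rep(2, 300), rnorm(300, 2, 0.3))
  m <- cell_matrix(v, "s", c("C", "X"), transform = "arcsinh")
  lab <- rep(c(1, 2), each = 150)
  de1 <- differential_expression(m, lab, 1)
  expect_equal(de1$stats$z[1], 0)
  expect_equal(de1$stats$p[1], 1)
  expect_identical(de1$stats$direction[1], "none")
  de2 <- differential_expression(m, lab, 2)
  expect_equal(de1$stats$z, -de2$stats$z, tolerance = 1e-10)
  expect_equal(de1$stats$p, de2$stats$p, tolerance = 1e-10)
})

test_that("signature matrix assembly pools rows and round-trips CSV", {
  lib <- random_archetypes(3, seed = 14)
  co <- simulate_cohort(3, archetypes = lib,
                        params = quick_params(cells = c(300, 400)), seed = 54)
  sigs <- list()
  for (m in co$samples) {
    mt <- arcsinh_transform(m)
    lab <- suppressWarnings(
      cluster_cells(mt, cluster_params(target_k = c(3L, 6L)), seed = 2))
    sigs <- c(sigs, cluster_signatures(mt, lab))
  }
  sm <- assemble_signature_matrix(sigs)
  expect_equal(nrow(sm$z), length(sigs))
  expect_equal(ncol(sm$z), 37L)
  # per-sample conservation of cells across cluster rows
  for (sid in names(co$samples)) {
    expect_equal(sum(sm$meta$n_cells[sm$meta$sample_id == sid]),
                 nrow(co$samples[[sid]]$values))
  }
  f <- withr::local_tempfile(fileext = ".csv")
  write_signature_matrix(sm, f)
  back <- read_signature_matrix(f)
  expect_lt(max(abs(back$z - sm$z)), 1e-6)
  expect_equal(back$meta$n_cells, sm$meta$n_cells)

  three <- assemble_signature_matrix(sigs[1:3])
  expect_equal(nrow(three$z), 3L)
  bad <- sigs[[1]]
  bad$stats <- bad$stats[-1, ]
  expect_error(assemble_signature_matrix(list(sigs[[1]], bad)), "mismatch")
})
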