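test_that("abundance contrasts compute exact fold changes", {
  ab <- matrix(c(0.2, 0.2, 0.2, 0.2,     # MC1 equal in both groups
                 0.4, 0.4, 0.2, 0.2),    # MC2 exactly double in group A
               4, 2, dimnames = list(paste0("S", 1:4), c("MC1", "MC2")))
  rec <- data.frame(sample_id = paste0("S", 1:4),
                    msmart = c("high", "high", "standard", "standard"),
                    stringsAsFactors = FALSE)
  res <- abundance_contrast(ab, rec, "msmart", pseudocount = 0)
  expect_equal(res$log2fc[res$meta_cluster == "MC1"], 0)
  expect_equal(res$log2fc[res$meta_cluster == "MC2"], 1)

  # named specs cover the standard contrasts
  expect_setequal(
    names(contrast_specs()),
    c("response", "sex", "age", "type", "primary", "tp53_del", "gain_1q",
      "myc_rearr", "monosomy13", "del13q", "msmart", "s_phase"))
  # undersized groups are skipped with a warning
  rec2 <- rec; rec2$msmart <- c("high", rep("standard", 3))
  expect_warning(out <- abundance_contrast(ab, rec2, "msmart"), "skipped")
  expect_null(out)
})

test_that("planted abundance effects are recovered from generator truth", {
  lib <- random_archetypes(4, seed = 8)
  pp <- quick_params(cells = c(60, 100), n_arch = c(4L, 4L),
                     clinical_effects = list(
                       list(archetype = "T03", covariate = "rrmm",
                            log2fc = 1.5)))
  est <- c(); sig <- c()
  for (r in 1:200) {
    co <- simulate_cohort(30, archetypes = lib, params = pp, seed = 3000 + r)
    ab <- t(vapply(names(co$samples), function(sid) {
      labs <- co$truth$cell_labels[[sid]]
      vapply(paste0("T0", 1:4), function(a) mean(labs == a), numeric(1))
    }, numeric(4)))
    res <- abundance_contrast(ab, co$records, "type")
    row <- res[res$meta_cluster == "T03", ]
    est <- c(est, row$log2fc); sig <- c(sig, row$p < 0.05)
  }
  expect_lt(abs(mean(est) - 1.5), 0.15)
  expect_gte(mean(sig), 0.8)
})

test_that("KM medians and log-rank match hand-computed fixtures", {
  # single uncensored group: median is the middle event time
  km1 <- km_logrank(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km1$medians$median, 2)
  expect_null(km1$logrank)

  # identical groups: no separation
  t2 <- c(1, 2, 3, 1, 2, 3); e2 <- c(1, 0, 1, 1, 0, 1)
  km2 <- km_logrank(t2, e2, rep(c("a", "b"), each = 3))
  expect_equal(km2$logrank$chisq, 0, tolerance = 1e-12)
  expect_equal(km2$logrank$p, 1, tolerance = 1e-12)

  # 6-subject fixture A: 1, 3+, 5 / B: 2, 4, 6 against the risk-table oracle
  times <- c(1, 3, 5, 2, 4, 6); events <- c(1, 0, 1, 1, 1, 1)
  grp <- rep(c("A", "B"), each = 3)
  km3 <- km_logrank(times, events, grp)
  o <- oracle_logrank(times, events, grp)
  expect_equal(km3$logrank$chisq, o$chisq, tolerance = 1e-10)
  expect_equal(km3$logrank$p, o$p, tolerance = 1e-10)
  expect_equal(unname(km3$logrank$observed[1]), o$observed)
  expect_equal(unname(km3$logrank$expected[1]), o$expected, tolerance = 1e-10)
})

test_that("KM curves are valid survival functions", {
  set.seed(101)
  for (r in 1:10) {
    n <- sample(5:20, 1)
    times <- round(rexp(n, 0.2), 2)
    events <- rbinom(n, 1, 0.7)
    if (sum(events) == 0) events[1] <- 1L
    km <- km_logrank(times, events)
    expect_true(all(diff(km$curves$surv) <= 1e-12))
    expect_true(all(km$curves$surv <= 1 + 1e-12))
    # with no censoring KM equals the empirical survival function
    km_all <- km_logrank(times, rep(1, n))
    emp <- vapply(km_all$curves$time, function(t) mean(times > t), numeric(1))
    expect_equal(km_all$curves$surv, emp, tolerance = 1e-12)
  }
  # all-censored: median not reached
  kmc <- km_logrank(c(1, 2, 3), c(0, 0, 0))
  expect_true(is.na(kmc$medians$median))
})

test_that("log-rank agrees with the risk-table oracle on random fixtures", {
  set.seed(102)
  for (r in 1:10) {
    n <- sample(8:20, 1)
    times <- sample(1:12, n, replace = TRUE) + runif(n) * 0.01
    events <- rbinom(n, 1, 0.8)
    grp <- sample(c("A", "B"), n, replace = TRUE)
    if (length(unique(grp)) < 2 || sum(events) == 0) next
    km <- km_logrank(times, events, grp)
    o <- oracle_logrank(times, events, grp)
    expect_equal(km$logrank$chisq, o$chisq, tolerance = 1e-10)
    expect_equal(km$logrank$p, o$p, tolerance = 1e-10)
  }
})

test_that("Cox fits match the grid-searched partial likelihood", {
  # 4-subject fixture, binary covariate, no ties, events interleaved so
  # the partial likelihood has an interior maximum
  times <- c(2, 5, 7, 10); events <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(times, events, data.frame(grp = x))
  o_hr <- oracle_cox_grid(times, events, x)
  expect_equal(fit$hr, o_hr, tolerance = 1e-3)

  set.seed(103)
  for (r in 1:5) {
    n <- 12
    times <- sort(runif(n, 1, 50)) + seq_len(n) * 1e-3   # no ties
    events <- rep(1, n)
    x <- rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) next
    fit <- cox_fit(times, events, data.frame(x = x))
    if (fit$flagged) next                                # separation
    expect_equal(fit$hr, oracle_cox_grid(times, events, x),
                 tolerance = 1e-3)
  }
  expect_error(cox_fit(c(1, 2), c(0, 0), c(0, 1)), "events")
  expect_error(cox_fit(c(1, 2), c(1, 1), c(1, 1)), "constant")
})

test_that("Cox recovers null and planted hazard ratios on simulated data", {
  set.seed(104)
  # null: covariate independent of hazard, mean HR within 5% of 1
  hrs <- vapply(1:500, function(r) {
    n <- 50
    x <- rbinom(n, 1, 0.5)
    t <- rexp(n, 0.3); e <- rep(1, n)
    cox_fit(t, e, data.frame(x = x))$hr
  }, numeric(1))
  expect_lt(abs(mean(hrs) - 1), 0.05)

  # planted protective presence HR 0.25 at n = 200
  ghr <- vapply(1:200, function(r) {
    n <- 200
    x <- rbinom(n, 1, 0.6)
    t <- rexp(n, 0.3 * 0.25^x)
    cox_fit(t, rep(1, n), data.frame(x = x))$hr
  }, numeric(1))
  expect_lt(abs(exp(mean(log(ghr))) - 0.25) / 0.25, 0.15)
})

test_that("the presence-survival screen flags a strong protective archetype", {
  set.seed(105)
  n <- 60
  pres <- matrix(c(runif(n) < 0.7, runif(n) < 0.5), n, 2,
                 dimnames = list(sprintf("S%02d", 1:n), c("MC1", "MC2")))
  lam <- 0.4 * ifelse(pres[, "MC1"], 0.15, 1)     # MC1 strongly protective
  rec <- data.frame(sample_id = rownames(pres),
                    os_time = pmin(rexp(n, lam), 15),
                    os_event = TRUE, msmart = "high",
                    stringsAsFactors = FALSE)
  rec$os_event <- rec$os_time < 15
  scr <- presence_survival_screen(pres, rec, subset_rule = NULL)
  expect_true(scr$significant[scr$meta_cluster == "MC1"])
  expect_lt(scr$hr_presence[scr$meta_cluster == "MC1"], 1)
  # a meta-cluster present everywhere is skipped
  pres2 <- cbind(pres, MC3 = TRUE)
  scr2 <- presence_survival_screen(pres2, rec, subset_rule = NULL)
  expect_false("MC3" %in% scr2$meta_cluster)
})
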