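# Synthetic cohort generator. Every downstream stage is tested against the
# ground truth this module plants: which cells belong to which phenotypic
# archetype, which covariates shift which archetype's abundance, and which
# archetype's presence carries a survival hazard ratio.

#' Phenotypic archetype
#'
#' A shared subclonal phenotype: a small set of markers shifted high or low
#' against a common plasma-cell baseline. Shifts are expressed in
#' arcsinh-scale standard-deviation units so planted effect sizes survive
#' the preprocessing transform.
#'
#' @param archetype_id identifier.
#' @param markers character vector of defining markers.
#' @param directions `"hi"` or `"lo"`, recycled along `markers`.
#' @param shifts positive shifts in SD units, recycled along `markers`.
#' @return An object of class `archetype`.
#' @export
archetype <- function(archetype_id, markers, directions = "hi", shifts = 2) {
  directions <- rep_len(directions, length(markers))
  shifts <- rep_len(shifts, length(markers))
  stopifnot(length(markers) >= 1L, all(shifts > 0),
            all(directions %in% c("hi", "lo")))
  structure(list(archetype_id = as.character(archetype_id),
                 defining_markers = data.frame(
                   marker = markers, direction = directions, shift = shifts,
                   stringsAsFactors = FALSE)),
            class = "archetype")
}

#' Default archetype library
#'
#' Thirteen archetypes mirroring the phenotypic meta-cluster families seen
#' in myeloma CyTOF cohorts (CD45hi/BCL-2lo, CD81hi, BCL-2hi, CD38lo,
#' MCL-1hi, CD49dlo, CD49dhi+pS6hi, CD38hi, CD71hi+pERKhi, clCasp3hi,
#' CD56hi, Ki-67hi+CD117hi).
#'
#' @param shift shift magnitude in SD units (default 2).
#' @return A named list of [archetype()] objects.
#' @export
default_archetypes <- function(shift = 2) {
  specs <- list(
    A01 = list(m = c("CD45", "BCL-2"), d = c("hi", "lo")),
    A02 = list(m = "CD81", d = "hi"),
    A03 = list(m = "BCL-2", d = "hi"),
    A04 = list(m = "CD38", d = "lo"),
    A05 = list(m = "MCL-1", d = "hi"),
    A06 = list(m = "CD49d", d = "lo"),
    A07 = list(m = c("CD49d", "pS6"), d = c("hi", "hi")),
    A08 = list(m = "CD38", d = "hi"),
    A09 = list(m = c("CD71", "pERK"), d = c("hi", "hi")),
    A10 = list(m = "clCasp3", d = "hi"),
    A11 = list(m = "CD56", d = "hi"),
    A12 = list(m = c("Ki-67", "CD117"), d = c("hi", "hi"))
  )
  out <- lapply(names(specs), function(id) {
    archetype(id, specs[[id]]$m, specs[[id]]$d, shift)
  })
  stats::setNames(out, names(specs))
}

#' Random archetype library
#'
#' Draws an archetype library for recovery experiments: each archetype
#' gets `n_markers` distinct defining markers (disjoint across
#' archetypes, drawn from the non-gating analysis markers) with random
#' hi/lo directions and shifts drawn uniformly from `shift_range` (in
#' arcsinh-scale SD units). A subclone is only operationally
#' distinguishable at the single-cell level when its total squared shift
#' clears the d-dimensional noise floor (about sqrt(8 d) SD^2, i.e. ~16
#' SD^2 for a 31-marker panel); the default 3 markers at 2.5-3.5 SD sits
#' just above that floor and well below the 4-8 SD separations real
#' subclone phenotypes show.
#'
#' @param n_archetypes number of archetypes.
#' @param n_markers defining markers per archetype.
#' @param shift_range range of per-marker shifts in SD units.
#' @param panel panel supplying candidate markers.
#' @param seed integer seed.
#' @return Named list of [archetype()] objects.
#' @export
random_archetypes <- function(n_archetypes, n_markers = 3L,
                              shift_range = c(2.5, 3.5),
                              panel = default_panel(), seed = 1L) {
  gate_mk <- c("CD16", "CD3", "CD19", "CD138", "IRF4", "kappa", "lambda",
               "CD34")
  pool <- setdiff(panel_markers(panel, analysis_only = TRUE), gate_mk)
  if (length(pool) < n_archetypes * n_markers) {
    stop("panel too small for ", n_archetypes, " x ", n_markers, " markers")
  }
  set.seed(as.integer(seed))
  picks <- split(sample(pool, n_archetypes * n_markers),
                 rep(seq_len(n_archetypes), each = n_markers))
  out <- lapply(seq_len(n_archetypes), function(i) {
    archetype(sprintf("T%02d", i), picks[[i]],
              sample(c("hi", "lo"), n_markers, replace = TRUE),
              stats::runif(n_markers, shift_range[1L], shift_range[2L]))
  })
  stats::setNames(out, vapply(out, `[[`, "", "archetype_id"))
}

#' Simulation parameters for [simulate_cohort()]
#'
#' Defaults describe the cohort the pipeline is aimed at: ~49 bone-marrow
#' samples of 500-50,000 gated plasma cells over the default panel, with
#' contaminant T-like and progenitor-like cells, zero-inflated intensities,
#' daratumumab CD38 masking, a planted protective archetype and realistic
#' myeloma clinical marginals. Tests scale `cells_per_sample` down for runtime.
#'
#' @param cells_per_sample length-2 range; per-sample counts are drawn
#'   log-uniformly within it.
#' @param noise_sd per-marker arcsinh-scale SD of cell-to-cell noise.
#' @param dropout zero-inflation probability per marker measurement.
#' @param contaminant_fraction fraction of non-plasma-cell events.
#' @param baseline_fraction fraction of plasma cells carrying no archetype.
#' @param archetypes_per_sample integer range of archetypes mixed per sample.
#' @param cofactor arcsinh cofactor linking raw and transformed scales.
#' @param clinical_effects list of planted abundance effects, each
#'   `list(archetype=, covariate=, log2fc=)`; `covariate` is one of
#'   `"response_poor"`, `"rrmm"`, `"gain_1q"`, `"msmart_high"`,
#'   `"s_phase_high"`, `"tp53_del"`.
#' @param survival_effect `list(archetype=, hr_presence=)` plus baseline
#'   hazard (per year, for samples lacking the archetype) and the
#'   administrative censoring horizon in years.
#' @param dara_cd38_shift arcsinh-scale reduction of CD38 signal in samples
#'   exposed to daratumumab within 6 months.
#' @param archetype_weight base mixture weight of an effect-carrying
#'   archetype in the reference covariate group.
#' @return A list of parameters.
#' @export
cohort_params <- function(cells_per_sample = c(500, 50000),
                          noise_sd = 0.3,
                          dropout = 0.15,
                          contaminant_fraction = 0.10,
                          baseline_fraction = 0.20,
                          archetypes_per_sample = c(2L, 6L),
                          cofactor = 5,
                          clinical_effects = list(
                            list(archetype = "A01", covariate = "response_poor",
                                 log2fc = -1)),
                          survival_effect = list(
                            archetype = "A01", hr_presence = 0.21,
                            baseline_hazard = log(2) / 2.2,
                            censor_horizon = 12),
                          dara_cd38_shift = 1.8,
                          archetype_weight = 0.15) {
  list(cells_per_sample = cells_per_sample, noise_sd = noise_sd,
       dropout = dropout, contaminant_fraction = contaminant_fraction,
       baseline_fraction = baseline_fraction,
       archetypes_per_sample = as.integer(archetypes_per_sample),
       cofactor = cofactor, clinical_effects = clinical_effects,
       survival_effect = survival_effect, dara_cd38_shift = dara_cd38_shift,
       archetype_weight = archetype_weight)
}

# Baseline arcsinh-scale means for a plasma-cell population on the given
# panel. Unlisted markers sit at 2.0.
baseline_profile <- function(markers, restricted_chain = "kappa") {
  mu <- stats::setNames(rep(2.0, length(markers)), markers)
  hi <- c(CD138 = 5.0, IRF4 = 5.0, CD38 = 5.5, CD49d = 4.5, CD71 = 4.0,
          CD45 = 2.5)
  lo <- c(CD3 = 0.3, CD19 = 0.3, CD16 = 0.3, CD34 = 0.3, CD20 = 0.5)
  for (nm in names(hi)) if (nm %in% markers) mu[nm] <- hi[[nm]]
  for (nm in names(lo)) if (nm %in% markers) mu[nm] <- lo[[nm]]
  other_chain <- setdiff(c("kappa", "lambda"), restricted_chain)
  if (restricted_chain %in% markers) mu[restricted_chain] <- 5.0
  if (other_chain %in% markers) mu[other_chain] <- 0.3
  mu
}

contaminant_profile <- function(kind, markers, restricted_chain) {
  mu <- baseline_profile(markers, restricted_chain)
  flat <- intersect(c("CD138", "IRF4", "kappa", "lambda", "CD38"), markers)
  mu[flat] <- 0.5
  if (kind == "tcell") {
    if ("CD3" %in% markers) mu["CD3"] <- 4.5
    if ("CD45" %in% markers) mu["CD45"] <- 4.5
  } else {               # progenitor
    if ("CD34" %in% markers) mu["CD34"] <- 4.5
    if ("CD19" %in% markers) mu["CD19"] <- 3.5
  }
  mu
}

# Draw one group of cells around an arcsinh-scale mean profile and map back
# to raw intensities (raw = sinh(x) * cofactor, floored at 0). Zero
# inflation is expression-dependent, as in real CyTOF data: the dropout
# probability decays exponentially with the marker's mean arcsinh level,
# so dim markers are zero-inflated and bright ones essentially never drop.
draw_cells <- function(n, mu, noise_sd, dropout, cofactor) {
  p <- length(mu)
  x <- matrix(stats::rnorm(n * p, mean = rep(mu, each = n), sd = noise_sd),
              nrow = n)
  raw <- pmax(sinh(x), 0) * cofactor
  if (dropout > 0) {
    # decay on the raw ion-count scale: a marker whose mean signal is many
    # counts essentially never reads zero
    p_drop <- dropout * exp(-sinh(pmax(mu, 0)) * cofactor / 5)
    drop <- matrix(stats::runif(n * p) <
                     matrix(p_drop, n, p, byrow = TRUE), nrow = n)
    raw[drop] <- 0
  }
  colnames(raw) <- names(mu)
  raw
}

covariate_group <- function(covariate, rec) {
  switch(covariate,
    response_poor = !is.na(rec$response) && rec$response == "PD",
    rrmm = !is.na(rec$disease_type) && rec$disease_type == "RRMM",
    gain_1q = isTRUE(rec$gain_1q),
    msmart_high = !is.na(rec$msmart) && rec$msmart == "high",
    s_phase_high = !is.na(rec$s_phase_pct) && rec$s_phase_pct >= 2,
    tp53_del = isTRUE(rec$tp53_del),
    stop("unknown planted covariate: ", covariate))
}

draw_clinical_record <- function(sample_id) {
  resp <- sample(RESPONSE_LEVELS, 1L,
                 prob = c(0.143, 0.408, 0.122, 0.143, 0.184))
  prim <- sample(PRIMARY_LEVELS, 1L,
                 prob = c(0.49, 0.306, 0.082, 0.041, 0.041, 0.041))
  data.frame(
    sample_id = sample_id,
    response = resp,
    sex = sample(c("M", "F"), 1L, prob = c(2, 1)),
    age = round(min(95, max(46, stats::rnorm(1, 67, 9)))),
    disease_type = sample(c("NDMM", "RRMM"), 1L, prob = c(0.408, 0.592)),
    primary_abnormality = prim,
    tp53_del = stats::runif(1) < 0.245,
    gain_1q = stats::runif(1) < 0.571,
    myc_rearr = stats::runif(1) < 0.265,
    monosomy13 = stats::runif(1) < 0.55,
    del13q = stats::runif(1) < 0.35,
    msmart = sample(c("high", "standard"), 1L, prob = c(0.694, 0.306)),
    s_phase_pct = round(exp(stats::rnorm(1, log(1.5), 0.9)), 1),
    os_time = NA_real_, os_event = NA,
    dara_within_6mo = stats::runif(1) < 0.286,
    sampled_within_6mo_of_dx = stats::runif(1) < 0.5,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-sample CyTOF cohort with planted ground truth
#'
#' Each sample is a mixture of 2-6 archetypes from a shared library, plus
#' baseline-only plasma cells and contaminant (CD3-high T-like and
#' CD34/CD19-high progenitor-like, CD138-low) events. Intensities are
#' zero-inflated with archetype shifts applied on the arcsinh scale.
#' Clinical covariates are drawn so planted abundance effects hold in
#' expectation, and survival times follow an exponential model with the
#' planted per-archetype-presence hazard ratio and administrative censoring.
#'
#' @param n_samples number of samples (>= 2).
#' @param panel a [panel_definition()].
#' @param archetypes named list of [archetype()] objects.
#' @param params a [cohort_params()] list.
#' @param seed integer seed; a fixed seed gives bit-identical output.
#' @return list with `samples` (raw [cell_matrix()] objects), `records`
#'   (clinical data.frame) and `truth` (per-sample archetype proportions,
#'   per-cell labels, planted effects, seed).
#' @export
simulate_cohort <- function(n_samples, panel = default_panel(),
                            archetypes = default_archetypes(),
                            params = cohort_params(), seed = 1L) {
  stopifnot(n_samples >= 2L)
  markers <- panel_markers(panel)
  for (a in archetypes) {
    bad <- setdiff(a$defining_markers$marker, markers)
    if (length(bad)) stop("archetype ", a$archetype_id,
                          " references markers absent from panel: ",
                          paste(bad, collapse = ", "))
  }
  arch_ids <- vapply(archetypes, `[[`, "", "archetype_id")
  names(archetypes) <- arch_ids
  planted <- c(vapply(params$clinical_effects, `[[`, "", "archetype"),
               params$survival_effect$archetype)
  bad <- setdiff(planted, arch_ids)
  if (length(bad)) stop("planted effect names unknown archetype(s): ",
                        paste(bad, collapse = ", "))
  set.seed(as.integer(seed))

  records <- do.call(rbind, lapply(seq_len(n_samples), function(i) {
    draw_clinical_record(sprintf("S%03d", i))
  }))

  # per-sample archetype subsets and mixture weights
  k_range <- pmin(params$archetypes_per_sample, length(arch_ids))
  prop_mat <- matrix(0, n_samples, length(arch_ids),
                     dimnames = list(records$sample_id, arch_ids))
  samples <- vector("list", n_samples)
  cell_labels <- vector("list", n_samples)
  cr <- log(params$cells_per_sample)
  for (i in seq_len(n_samples)) {
    rec <- records[i, ]
    m <- k_range[1L] + sample.int(k_range[2L] - k_range[1L] + 1L, 1L) - 1L
    chosen <- sample(arch_ids, m)
    # Planted effects fix an archetype's mixture weight absolutely
    # (base weight times 2^log2fc in the exposed group); the remaining
    # archetypes share the leftover equally. Keeping effect weights
    # absolute rather than renormalized makes the expected abundance
    # ratio between covariate groups exactly 2^log2fc.
    w <- stats::setNames(rep(NA_real_, m), chosen)
    for (a in chosen) {
      eff <- Filter(function(e) e$archetype == a, params$clinical_effects)
      if (!length(eff)) next
      mult <- 1
      for (e in eff) if (covariate_group(e$covariate, rec)) {
        mult <- mult * 2^e$log2fc
      }
      w[a] <- params$archetype_weight * mult
    }
    fixed <- sum(w, na.rm = TRUE)
    if (fixed > 0.9) { w <- w * 0.9 / fixed; fixed <- 0.9 }
    n_free <- sum(is.na(w))
    if (n_free > 0) {
      w[is.na(w)] <- (1 - fixed) / n_free
    } else {
      w <- w / sum(w)   # every chosen archetype carries an effect
    }
    prop_mat[i, chosen] <- w

    n_cells <- round(exp(stats::runif(1, cr[1L], cr[2L])))
    n_cont <- round(n_cells * params$contaminant_fraction)
    n_pc <- n_cells - n_cont
    n_base <- round(n_pc * params$baseline_fraction)
    n_arch <- stats::rmultinom(1L, n_pc - n_base, w)[, 1L]
    chain <- sample(c("kappa", "lambda"), 1L, prob = c(0.592, 0.408))
    mu0 <- baseline_profile(markers, chain)
    if (isTRUE(rec$dara_within_6mo) && "CD38" %in% markers) {
      mu0["CD38"] <- max(0.2, mu0["CD38"] - params$dara_cd38_shift)
    }

    blocks <- list(); labels <- character(0)
    if (n_base > 0) {
      blocks <- c(blocks, list(draw_cells(n_base, mu0, params$noise_sd,
                                          params$dropout, params$cofactor)))
      labels <- c(labels, rep("baseline", n_base))
    }
    for (a in chosen) {
      if (n_arch[a] == 0) next
      mu <- mu0
      dm <- archetypes[[a]]$defining_markers
      sgn <- ifelse(dm$direction == "hi", 1, -1)
      mu[dm$marker] <- pmax(0.05, mu[dm$marker] +
                              sgn * dm$shift * params$noise_sd)
      blocks <- c(blocks, list(draw_cells(n_arch[a], mu, params$noise_sd,
                                          params$dropout, params$cofactor)))
      labels <- c(labels, rep(a, n_arch[a]))
    }
    if (n_cont > 0) {
      n_t <- round(n_cont / 2); n_pr <- n_cont - n_t
      for (kind in c("tcell", "progenitor")) {
        nk <- if (kind == "tcell") n_t else n_pr
        if (nk == 0) next
        mu <- contaminant_profile(kind, markers, chain)
        blocks <- c(blocks, list(draw_cells(nk, mu, params$noise_sd,
                                            params$dropout, params$cofactor)))
        labels <- c(labels, rep(paste0(kind, "_contaminant"), nk))
      }
    }
    vals <- do.call(rbind, blocks)
    ord <- sample.int(nrow(vals))          # shuffle cell order
    samples[[i]] <- cell_matrix(vals[ord, , drop = FALSE], rec$sample_id,
                                markers, transform = "raw")
    cell_labels[[i]] <- labels[ord]
  }
  names(samples) <- records$sample_id
  names(cell_labels) <- records$sample_id

  # survival: exponential, hazard scaled by presence of the effect archetype
  se <- params$survival_effect
  presence <- prop_mat[, se$archetype] > 0
  lam <- se$baseline_hazard * ifelse(presence, se$hr_presence, 1)
  t_death <- stats::rexp(n_samples, rate = lam)
  records$os_time <- round(pmin(t_death, se$censor_horizon), 4)
  records$os_event <- t_death <= se$censor_horizon

  truth <- list(proportions = prop_mat, cell_labels = cell_labels,
                clinical_effects = params$clinical_effects,
                survival_effect = se, seed = as.integer(seed))
  list(samples = samples, records = validate_clinical(records), truth = truth)
}

#' Export a simulated cohort to disk in the formats the readers consume
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param panel panel used for FCS channel ids.
#' @param format `"fcs"` or `"csv"` per-sample files.
#' @return `dir`, invisibly.
#' @export
export_cohort <- function(cohort, dir, panel = default_panel(),
                          format = c("fcs", "csv")) {
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (m in cohort$samples) {
    f <- file.path(dir, paste0(m$sample_id, ".", format))
    if (format == "fcs") write_fcs(m, f, panel) else write_cell_csv(m, f)
  }
  write_clinical_table(cohort$records, file.path(dir, "clinical.csv"))
  truth <- cohort$truth
  truth$proportions <- as.data.frame(truth$proportions)
  truth$cell_labels <- NULL    # bulky; cells are recoverable from the seed
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Parameters for [simulate_expression_cohort()]
#'
#' Defaults emulate a bortezomib-era relapsed/refractory myeloma trial
#' cohort (n = 156, Affymetrix-style probe intensities, ~3 probes/gene).
#'
#' @param probes_per_gene probes measured per gene.
#' @param n_background_genes unrelated genes included in the matrix.
#' @param activity_loading expression shift per SD of latent activity.
#' @param noise_sd residual probe noise SD.
#' @param hr_low_high planted hazard ratio between the bottom and top 20%
#'   activity tails (1 = no association).
#' @param response_loading log-odds of response per SD of latent activity.
#' @param baseline_hazard events per day; `censor_horizon` in days.
#' @param censor_horizon administrative censoring time (days).
#' @return A list of parameters.
#' @export
expression_params <- function(probes_per_gene = 3L,
                              n_background_genes = 20L,
                              activity_loading = 1.0,
                              noise_sd = 0.5,
                              hr_low_high = 2.0,
                              response_loading = 0.8,
                              baseline_hazard = log(2) / 700,
                              censor_horizon = 2000) {
  list(probes_per_gene = as.integer(probes_per_gene),
       n_background_genes = as.integer(n_background_genes),
       activity_loading = activity_loading, noise_sd = noise_sd,
       hr_low_high = hr_low_high, response_loading = response_loading,
       baseline_hazard = baseline_hazard, censor_horizon = censor_horizon)
}

# Expected gap between the means of the top and bottom `frac` tails of a
# standard normal: 2 * phi(z_{1-frac}) / frac.
normal_tail_gap <- function(frac) 2 * stats::dnorm(stats::qnorm(1 - frac)) / frac

#' Simulate a bulk expression cohort with a planted activity signal
#'
#' A latent per-sample activity drives the signature genes in their stated
#' directions (up genes increase with activity, down genes decrease),
#' survival (exponential; hazard decreasing with activity, calibrated so
#' the bottom-vs-top 20% activity tails differ by `hr_low_high`) and
#' response (logistic in activity).
#'
#' @param n_samples cohort size.
#' @param signature a [gene_signature()].
#' @param params an [expression_params()] list.
#' @param seed integer seed.
#' @return list with `cohort` (an [expression_cohort()]) and `truth`
#'   (latent activity, params, seed).
#' @export
simulate_expression_cohort <- function(n_samples = 156L,
                                       signature = metacluster1_signature(),
                                       params = expression_params(),
                                       seed = 1L) {
  stopifnot(n_samples >= 2L)
  set.seed(as.integer(seed))
  activity <- stats::rnorm(n_samples)
  sample_ids <- sprintf("GSM%04d", seq_len(n_samples))

  genes <- signature$entries$gene
  dirs <- ifelse(signature$entries$direction == "up", 1, -1)
  bg <- if (params$n_background_genes > 0) {
    sprintf("BG%03d", seq_len(params$n_background_genes))
  } else character(0)
  all_genes <- c(genes, bg)
  loadings <- c(dirs * params$activity_loading,
                rep(0, length(bg)))
  ppg <- params$probes_per_gene
  probe_ids <- unlist(lapply(all_genes, function(g) {
    sprintf("%s_at_%d", g, seq_len(ppg))
  }))
  probe_gene <- rep(all_genes, each = ppg)
  centers <- stats::setNames(stats::runif(length(all_genes), 6, 10), all_genes)
  mat <- matrix(NA_real_, length(probe_ids), n_samples,
                dimnames = list(probe_ids, sample_ids))
  for (k in seq_along(probe_ids)) {
    g <- probe_gene[k]
    load <- loadings[match(g, all_genes)]
    mat[k, ] <- centers[g] + load * activity +
      stats::rnorm(n_samples, sd = params$noise_sd)
  }

  beta <- if (params$hr_low_high == 1) 0 else {
    log(params$hr_low_high) / normal_tail_gap(0.20)
  }
  lam <- params$baseline_hazard * exp(-beta * activity)
  t_death <- stats::rexp(n_samples, rate = lam)
  responder <- stats::runif(n_samples) <
    stats::plogis(0.4 + params$response_loading * activity)
  ann <- data.frame(
    sample_id = sample_ids,
    os_time = round(pmin(t_death, params$censor_horizon), 2),
    os_event = t_death <= params$censor_horizon,
    responder = responder,
    stringsAsFactors = FALSE
  )
  cohort <- expression_cohort(mat,
                              data.frame(probe = probe_ids, gene = probe_gene,
                                         stringsAsFactors = FALSE),
                              annotations = ann)
  list(cohort = cohort,
       truth = list(activity = stats::setNames(activity, sample_ids),
                    params = params, seed = as.integer(seed)))
}
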