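# Clinical association of meta-cluster composition: abundance contrasts
# across named clinical dichotomies, Kaplan-Meier/log-rank comparison of
# presence vs absence, and Cox proportional-hazards fits (Efron ties,
# via the survival package).

#' Named clinical contrast specifications
#'
#' The standard dichotomies used for abundance contrasts: 90-day response
#' (poor = PD vs good = PR/VGPR; MR and SD sit in neither arm), sex, age
#' > 60, RRMM vs NDMM, hyperdiploidy vs t(11;14), TP53 deletion, 1q gain,
#' MYC disruption, monosomy 13, deletion 13q, mSMART high vs standard and
#' S-phase >= 2%. Each spec maps a clinical table to a logical vector
#' (TRUE = first-named group, NA = excluded).
#'
#' @return Named list of functions `records -> logical`.
#' @export
contrast_specs <- function() {
  list(
    response = function(r) ifelse(is.na(r$response), NA,
      ifelse(r$response == "PD", TRUE,
             ifelse(r$response %in% c("PR", "VGPR"), FALSE, NA))),
    sex = function(r) ifelse(is.na(r$sex), NA, r$sex == "M"),
    age = function(r) ifelse(is.na(r$age), NA, r$age > 60),
    type = function(r) ifelse(is.na(r$disease_type), NA,
                              r$disease_type == "RRMM"),
    primary = function(r) ifelse(is.na(r$primary_abnormality), NA,
      ifelse(r$primary_abnormality == "hyperdiploidy", TRUE,
             ifelse(r$primary_abnormality == "t(11;14)", FALSE, NA))),
    tp53_del = function(r) r$tp53_del,
    gain_1q = function(r) r$gain_1q,
    myc_rearr = function(r) r$myc_rearr,
    monosomy13 = function(r) r$monosomy13,
    del13q = function(r) r$del13q,
    msmart = function(r) ifelse(is.na(r$msmart), NA, r$msmart == "high"),
    s_phase = function(r) ifelse(is.na(r$s_phase_pct), NA,
                                 r$s_phase_pct >= 2)
  )
}

#' Contrast meta-cluster abundance between clinical groups
#'
#' Per meta-cluster: `log2((mean abundance in group A + eps) /
#' (mean in group B + eps))` with a Welch t test (two-sided) on the
#' abundances. The pseudocount keeps the fold change finite when a
#' meta-cluster is absent from a whole group.
#'
#' @param abundance samples x meta-clusters matrix
#'   (see [metacluster_abundance()]).
#' @param records clinical data.frame with matching `sample_id`s.
#' @param variable name of a spec in [contrast_specs()], or a function
#'   `records -> logical`.
#' @param pseudocount epsilon on the group means (default 1e-4).
#' @return data.frame: meta_cluster, variable, n_a, n_b, mean_a, mean_b,
#'   log2fc, t, p.
#' @export
abundance_contrast <- function(abundance, records, variable,
                               pseudocount = 1e-4) {
  spec_name <- if (is.character(variable)) variable else "custom"
  fn <- if (is.function(variable)) variable else {
    specs <- contrast_specs()
    if (!variable %in% names(specs)) {
      stop("unknown contrast '", variable, "'; available: ",
           paste(names(specs), collapse = ", "))
    }
    specs[[variable]]
  }
  idx <- match(rownames(abundance), records$sample_id)
  if (anyNA(idx)) stop("abundance rows missing from clinical table: ",
                       paste(rownames(abundance)[is.na(idx)], collapse = ", "))
  g <- fn(records[idx, , drop = FALSE])
  keep <- !is.na(g)
  if (sum(g[keep]) < 2L || sum(!g[keep]) < 2L) {
    warning("contrast '", spec_name, "' has a group with < 2 samples; skipped")
    return(NULL)
  }
  ab <- abundance[keep, , drop = FALSE]
  g <- g[keep]
  out <- lapply(colnames(ab), function(k) {
    xa <- ab[g, k]; xb <- ab[!g, k]
    tt <- if (stats::sd(xa) > 0 || stats::sd(xb) > 0) {
      stats::t.test(xa, xb)
    } else NULL
    data.frame(meta_cluster = k, variable = spec_name,
               n_a = length(xa), n_b = length(xb),
               mean_a = mean(xa), mean_b = mean(xb),
               log2fc = log2((mean(xa) + pseudocount) /
                               (mean(xb) + pseudocount)),
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Abundance contrasts over all named clinical dichotomies
#' @param abundance samples x meta-clusters matrix.
#' @param records clinical data.frame.
#' @param variables subset of [contrast_specs()] names (default: all).
#' @param pseudocount epsilon on the group means.
#' @return data.frame stacking [abundance_contrast()] rows; skipped
#'   contrasts are absent.
#' @export
abundance_contrast_panel <- function(abundance, records,
                                     variables = names(contrast_specs()),
                                     pseudocount = 1e-4) {
  out <- lapply(variables, function(v) {
    tryCatch(abundance_contrast(abundance, records, v, pseudocount),
             warning = function(w) NULL)
  })
  do.call(rbind, out)
}

km_median <- function(fit) {
  # first time at which the KM curve drops to or below 0.5, with the
  # log-log 95% CI bounds read off the same way
  smry <- summary(fit)
  grab <- function(time, surv) {
    i <- which(surv <= 0.5)
    if (!length(i)) NA_real_ else time[i[1L]]
  }
  if (is.null(smry$strata)) {
    data.frame(group = "all",
               median = grab(smry$time, smry$surv),
               lcl = grab(smry$time, smry$upper),
               ucl = grab(smry$time, smry$lower),
               n = fit$n, stringsAsFactors = FALSE)
  } else {
    strata <- smry$strata
    do.call(rbind, lapply(levels(strata), function(s) {
      sel <- strata == s
      data.frame(group = sub("^.*=", "", s),
                 median = grab(smry$time[sel], smry$surv[sel]),
                 lcl = grab(smry$time[sel], smry$upper[sel]),
                 ucl = grab(smry$time[sel], smry$lower[sel]),
                 n = sum(fit$n[match(s, levels(strata))]),
                 stringsAsFactors = FALSE)
    }))
  }
}

#' Kaplan-Meier estimate and log-rank comparison
#'
#' Kaplan-Meier curves per group (Greenwood variance, log-log 95% CIs),
#' per-group median survival (first time the curve reaches 0.5; reported
#' `NA` when never reached) and, for >= 2 groups, the log-rank chi-square
#' and p-value.
#'
#' @param times follow-up times (>= 0).
#' @param events event indicators (TRUE/1 = death).
#' @param groups group labels (a single group gives curves only).
#' @return list: `medians` (data.frame), `logrank` (chisq, df, p or NULL),
#'   `curves` (data.frame of step-function points), `fit` (the survfit).
#' @export
km_logrank <- function(times, events, groups = NULL) {
  stopifnot(length(times) == length(events), all(times >= 0, na.rm = TRUE))
  events <- as.integer(events)
  if (is.null(groups)) groups <- rep("all", length(times))
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- events[keep]
  groups <- factor(groups[keep])
  df <- data.frame(times = times, events = events, groups = groups)
  fit <- survival::survfit(survival::Surv(times, events) ~ groups, data = df,
                           conf.type = "log-log")
  med <- km_median(fit)
  lr <- NULL
  if (nlevels(groups) >= 2L) {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups,
                             data = df)
    lr <- list(chisq = sd$chisq, df = length(sd$n) - 1L,
               p = stats::pchisq(sd$chisq, length(sd$n) - 1L,
                                 lower.tail = FALSE),
               observed = sd$obs, expected = sd$exp)
  }
  smry <- summary(fit)
  curves <- data.frame(
    group = if (is.null(smry$strata)) {
      rep("all", length(smry$time))
    } else sub("^.*=", "", smry$strata),
    time = smry$time, surv = smry$surv, lower = smry$lower,
    upper = smry$upper, n_risk = smry$n.risk, n_event = smry$n.event,
    stringsAsFactors = FALSE)
  list(medians = med, logrank = lr, curves = curves, fit = fit)
}

#' Cox proportional-hazards fit
#'
#' Partial-likelihood maximization with Efron tie handling; Wald 95% CIs
#' and p-values per covariate. Non-convergence or separation (monotone
#' likelihood) is flagged rather than raised.
#'
#' @param times,events survival outcome.
#' @param covariates data.frame (or vector) of covariates; logicals are
#'   fitted as 0/1.
#' @return data.frame: term, hr, lcl, ucl, se_loghr, z, p, n, n_events,
#'   flagged (TRUE when the fit is unreliable).
#' @export
cox_fit <- function(times, events, covariates) {
  if (!is.data.frame(covariates)) {
    covariates <- data.frame(x = covariates)
  }
  df <- data.frame(.time = times, .event = as.integer(events), covariates,
                   check.names = FALSE)
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (sum(df$.event) < 1L) stop("no events in the data")
  for (nm in names(covariates)) {
    if (is.logical(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
    if (length(unique(df[[nm]])) < 2L) {
      stop("covariate '", nm, "' is constant")
    }
  }
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(fml, data = df, ties = "efron"),
    warning = function(w) {
      f <- suppressWarnings(survival::coxph(fml, data = df, ties = "efron"))
      attr(f, "flagged") <- TRUE
      f
    })
  flagged <- isTRUE(attr(fit, "flagged")) || !is.null(fit$fail)
  s <- summary(fit)
  co <- s$coefficients
  out <- data.frame(
    term = rownames(co),
    hr = co[, "exp(coef)"],
    lcl = exp(co[, "coef"] - 1.96 * co[, "se(coef)"]),
    ucl = exp(co[, "coef"] + 1.96 * co[, "se(coef)"]),
    se_loghr = co[, "se(coef)"],
    z = co[, "z"],
    p = co[, "Pr(>|z|)"],
    n = nrow(df), n_events = sum(df$.event),
    flagged = flagged | abs(co[, "coef"]) > 15,   # separation guard
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Presence/absence survival screen over all meta-clusters
#'
#' For each meta-cluster: Kaplan-Meier + log-rank comparison of samples
#' with vs without the meta-cluster, and a univariate Cox fit of presence,
#' on the subset selected by `subset_rule` (default: samples collected
#' within 6 months of diagnosis). Uncorrected p-values are flagged at
#' 0.05, mirroring a 13-way uncorrected screen; a BH FDR column is
#' appended for transparency only.
#'
#' @param presence samples x meta-clusters logical matrix.
#' @param records clinical data.frame (needs os_time/os_event).
#' @param subset_rule function `records -> logical` (default
#'   `sampled_within_6mo_of_dx`); `NULL` keeps all samples.
#' @param multivariate_msmart also fit presence + mSMART-high jointly.
#' @return data.frame, one row per testable meta-cluster: n_present,
#'   n_absent, median OS per group with CI bounds, log-rank chisq and p,
#'   Cox hr/lcl/ucl/p (presence vs absence), optional multivariate hr,
#'   `significant` flag, fdr.
#' @export
presence_survival_screen <- function(presence, records,
                                     subset_rule = function(r)
                                       isTRUE_vec(r$sampled_within_6mo_of_dx),
                                     multivariate_msmart = FALSE) {
  idx <- match(rownames(presence), records$sample_id)
  if (anyNA(idx)) stop("presence rows missing from clinical table")
  rec <- records[idx, , drop = FALSE]
  keep <- if (is.null(subset_rule)) rep(TRUE, nrow(rec)) else subset_rule(rec)
  keep <- keep & !is.na(rec$os_time) & !is.na(rec$os_event)
  if (!any(keep)) stop("survival subset is empty")
  rec <- rec[keep, , drop = FALSE]
  pres <- presence[keep, , drop = FALSE]

  rows <- lapply(colnames(pres), function(k) {
    g <- pres[, k]
    if (all(g) || !any(g)) return(NULL)     # degenerate grouping: skip
    km <- km_logrank(rec$os_time, rec$os_event,
                     ifelse(g, "present", "absent"))
    cx <- tryCatch(cox_fit(rec$os_time, rec$os_event,
                           data.frame(presence = g)),
                   error = function(e) NULL)
    med <- km$medians
    mp <- med[med$group == "present", ]; ma <- med[med$group == "absent", ]
    row <- data.frame(
      meta_cluster = k, n_present = sum(g), n_absent = sum(!g),
      median_present = mp$median, median_present_lcl = mp$lcl,
      median_present_ucl = mp$ucl,
      median_absent = ma$median, median_absent_lcl = ma$lcl,
      median_absent_ucl = ma$ucl,
      logrank_chisq = km$logrank$chisq, logrank_p = km$logrank$p,
      hr_presence = if (is.null(cx)) NA_real_ else cx$hr,
      hr_lcl = if (is.null(cx)) NA_real_ else cx$lcl,
      hr_ucl = if (is.null(cx)) NA_real_ else cx$ucl,
      cox_p = if (is.null(cx)) NA_real_ else cx$p,
      stringsAsFactors = FALSE)
    if (multivariate_msmart && !all(is.na(rec$msmart))) {
      mcx <- tryCatch(cox_fit(rec$os_time, rec$os_event,
                              data.frame(presence = g,
                                         msmart_high = rec$msmart == "high")),
                      error = function(e) NULL)
      row$hr_presence_adj <- if (is.null(mcx)) NA_real_ else {
        mcx$hr[mcx$term == "presence"]
      }
    }
    row
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no meta-cluster had both presence and absence")
  out$significant <- !is.na(out$logrank_p) & out$logrank_p < 0.05
  out$fdr <- stats::p.adjust(out$logrank_p, method = "BH")
  out
}

# NA-safe elementwise isTRUE for subset rules
isTRUE_vec <- function(x) !is.na(x) & x
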