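# Independent oracles used across the suite. These deliberately re-derive
# the statistics from first principles (explicit risk tables, grid-search
# likelihoods, hand formulas) and never call the implementation paths they
# check.

# Two-group log-rank by explicit risk-table accounting: returns observed,
# expected and hypergeometric variance for group 1, plus chi-square and p.
oracle_logrank <- function(times, events, groups) {
  groups <- as.integer(factor(groups))
  stopifnot(all(groups %in% 1:2))
  o1 <- 0; e1 <- 0; v <- 0
  for (t in sort(unique(times[events == 1]))) {
    at_risk <- times >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & groups == 1L)
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == 1L)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- if (v > 0) (o1 - e1)^2 / v else 0
  list(observed = o1, expected = e1, variance = v, chisq = chisq,
       p = stats::pchisq(chisq, 1, lower.tail = FALSE))
}

# Kaplan-Meier by explicit product-limit accounting (single group).
oracle_km <- function(times, events) {
  ts <- sort(unique(times[events == 1]))
  surv <- numeric(length(ts)); s <- 1
  for (i in seq_along(ts)) {
    n <- sum(times >= ts[i])
    d <- sum(times == ts[i] & events == 1)
    s <- s * (1 - d / n)
    surv[i] <- s
  }
  data.frame(time = ts, surv = surv)
}

# Cox partial likelihood for one binary covariate, no ties assumed;
# maximized by grid search over log hazard ratio.
oracle_cox_grid <- function(times, events, x, grid = seq(-5, 5, by = 1e-4)) {
  loglik <- function(beta) {
    ll <- 0
    for (t in times[events == 1]) {
      i <- which(times == t & events == 1)
      risk <- times >= t
      ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
    }
    ll
  }
  lls <- vapply(grid, loglik, numeric(1))
  exp(grid[which.max(lls)])
}

# Hand evaluation of the two-part hurdle z on explicit vectors, following
# the documented combination rule.
oracle_hurdle <- function(cluster_vals, rest_vals) {
  n1 <- length(cluster_vals); n2 <- length(rest_vals)
  d1 <- sum(cluster_vals > 0); d2 <- sum(rest_vals > 0)
  p1 <- d1 / n1; p2 <- d2 / n2
  phat <- (d1 + d2) / (n1 + n2)
  z1 <- if (phat > 0 && phat < 1) {
    (p1 - p2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  } else 0
  cv <- cluster_vals[cluster_vals > 0]; rv <- rest_vals[rest_vals > 0]
  have_levels <- length(cv) >= 2 && length(rv) >= 2
  z2 <- if (have_levels) {
    (mean(cv) - mean(rv)) /
      sqrt(stats::var(cv) / length(cv) + stats::var(rv) / length(rv))
  } else NA_real_
  n_zero <- (n1 + n2) - (d1 + d2)
  have_detect <- n_zero >= 10 && (d1 + d2) >= 10
  z_comb <- if (have_levels && have_detect) {
    (z1 + z2) / sqrt(2)
  } else if (have_levels) z2 else z1
  sgn <- if (have_levels && mean(cv) != mean(rv)) {
    sign(mean(cv) - mean(rv))
  } else if (z1 != 0) sign(z1) else 1
  z <- sgn * abs(z_comb)
  list(z1 = z1, z2 = z2, z = z, p = 2 * stats::pnorm(-abs(z)))
}

# Phi coefficient of a 2x2 table computed directly from the counts.
oracle_phi <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  (a * d - b * c) /
    sqrt((a + b) * (c + d) * (a + c) * (b + d))
}
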