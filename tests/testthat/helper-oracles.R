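# Independent brute-force oracles. These deliberately re-derive each
# statistic from its definition, without calling the package code paths
# (or the library functions standing behind them).

# Benjamini-Hochberg step-up, from the textbook definition:
# adj_(i) = min_{j >= i} m * p_(j) / j, capped at 1, on the sorted scale.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  adj <- pmin(cummin(rev(m * ranked / seq_len(m))), 1)
  adj <- rev(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

# Kaplan-Meier product-limit by direct looping over distinct event times.
km_oracle <- function(time, event) {
  stopifnot(length(time) == length(event))
  ev_times <- sort(unique(time[event == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

# Two-group log-rank chi-square from the observed-minus-expected sums
# over pooled event times (hypergeometric variance).
logrank_oracle <- function(tA, eA, tB, eB) {
  time <- c(tA, tB); event <- c(eA, eB)
  grp <- rep(c("A", "B"), c(length(tA), length(tB)))
  ev_times <- sort(unique(time[event == 1]))
  OmE <- 0; V <- 0; O <- 0
  for (t in ev_times) {
    at_risk <- time >= t
    n <- sum(at_risk)
    nA <- sum(at_risk & grp == "A")
    d <- sum(time == t & event == 1)
    dA <- sum(time == t & event == 1 & grp == "A")
    O <- O + dA
    OmE <- OmE + dA - d * nA / n
    if (n > 1) V <- V + d * (nA / n) * (1 - nA / n) * (n - d) / (n - 1)
  }
  chi2 <- OmE^2 / V
  list(chi2 = chi2, p = pchisq(chi2, 1, lower.tail = FALSE))
}

# Exact two-sided Wilcoxon rank-sum p by full enumeration of which ranks
# belong to the first sample (valid without ties).
ranksum_exact_oracle <- function(x, y) {
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(n, nx)
  w_all <- apply(combs, 2, function(idx) sum(idx) - nx * (nx + 1) / 2)
  lo <- mean(w_all <= w_obs)
  hi <- mean(w_all >= w_obs)
  min(1, 2 * min(lo, hi))
}

# Pearson correlation from raw sums (cross-check for cor-based paths).
pearson_oracle <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}
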