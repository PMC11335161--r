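# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from its definition by direct summation/search and
# share no code with the package implementations.

# Negative Breslow partial log-likelihood by direct summation over events.
breslow_nll_oracle <- function(scores, times, events) {
  ll <- 0
  for (i in seq_along(scores)) {
    if (events[i] == 1) {
      risk <- which(times >= times[i])
      ll <- ll + scores[i] - log(sum(exp(scores[risk])))
    }
  }
  -ll / sum(events)
}

# Nelson-Aalen cumulative hazard at the unique event times.
nelson_aalen_oracle <- function(times, events) {
  et <- sort(unique(times[events == 1]))
  haz <- cumsum(vapply(et, function(tt) {
    sum(events[times == tt]) / sum(times >= tt)
  }, numeric(1)))
  list(time = et, hazard = haz)
}

# Harrell's C by exhaustive enumeration of pairs (expects untied times).
cindex_oracle <- function(scores, times, events) {
  num <- 0; den <- 0
  n <- length(scores)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (times[i] < times[j] && events[i] == 1) {
      den <- den + 1
      if (scores[i] > scores[j]) num <- num + 1
      else if (scores[i] == scores[j]) num <- num + 0.5
    }
  }
  num / den
}

# IPCW integrated Brier score by naive double loops (trapezoid in time).
ibs_oracle <- function(surv_pred, pred_times, times, events, tau) {
  n <- length(times)
  # censoring KM (right-continuous) evaluated by scanning
  cet <- sort(unique(times[events == 0]))
  g_of <- function(t, left = FALSE) {
    s <- 1
    for (tt in cet) {
      if ((left && tt < t) || (!left && tt <= t)) {
        yk <- sum(times >= tt)
        dk <- sum(times == tt & events == 0)
        s <- s * (1 - dk / yk)
      }
    }
    s
  }
  grid <- pred_times[pred_times <= tau]
  if (max(grid) < tau) grid <- c(grid, tau)
  bs <- numeric(length(grid))
  for (k in seq_along(grid)) {
    t <- grid[k]
    tot <- 0
    for (i in seq_len(n)) {
      sp <- surv_pred[i, max(which(pred_times <= t))]
      if (times[i] <= t && events[i] == 1) {
        tot <- tot + sp^2 / g_of(times[i], left = TRUE)
      } else if (times[i] > t) {
        tot <- tot + (1 - sp)^2 / g_of(t)
      }
    }
    bs[k] <- tot / n
  }
  sum(diff(grid) * (bs[-1] + bs[-length(bs)]) / 2) / tau
}

# Objective of the per-feature hierarchical proximal problem at a candidate
# (b, with W at its optimal clamp), and its numeric minimum over b.
hier_prox_objective <- function(b, u, v, lambda, m_const) {
  w <- sign(v) * pmin(abs(v), m_const * abs(b))
  0.5 * (b - u)^2 + lambda * abs(b) + 0.5 * sum((w - v)^2)
}

hier_prox_numeric_min <- function(u, v, lambda, m_const) {
  bmax <- abs(u) + m_const * max(abs(v), 0) + 1
  f <- function(b) hier_prox_objective(b, u, v, lambda, m_const)
  o1 <- stats::optimize(f, c(0, bmax), tol = 1e-10)
  o2 <- stats::optimize(f, c(-bmax, 0), tol = 1e-10)
  min(o1$objective, o2$objective, f(0))
}

# Entropic OT value by direct normal-domain Sinkhorn matrix scaling;
# the value is the primal cost plus eps * KL(P || a x b).
sinkhorn_primal_oracle <- function(x, y, eps, iters = 2000) {
  cmat <- as.matrix(stats::dist(rbind(x, y)))^2
  cmat <- cmat[seq_len(nrow(x)), nrow(x) + seq_len(nrow(y)), drop = FALSE]
  n <- nrow(x); m <- nrow(y)
  a <- rep(1 / n, n); b <- rep(1 / m, m)
  kmat <- exp(-cmat / eps)
  u <- rep(1, n); v <- rep(1, m)
  for (i in seq_len(iters)) {
    u <- a / (kmat %*% v)
    v <- b / (t(kmat) %*% u)
  }
  p <- diag(as.numeric(u)) %*% kmat %*% diag(as.numeric(v))
  kl <- sum(p * log(p / outer(a, b)), na.rm = TRUE)
  sum(p * cmat) + eps * kl
}

# Weighted (or unweighted) log-rank observed-minus-expected by direct tally.
logrank_oracle <- function(times, events, group, weights = rep(1, length(times))) {
  lev <- levels(factor(group))
  et <- sort(unique(times[events == 1]))
  o_e <- 0; v <- 0
  for (tt in et) {
    y <- sum(weights[times >= tt])
    y1 <- sum(weights[times >= tt & group == lev[2]])
    d <- sum(weights[times == tt & events == 1])
    d1 <- sum(weights[times == tt & events == 1 & group == lev[2]])
    o_e <- o_e + d1 - d * y1 / y
    if (y > 1) v <- v + d * (y1 / y) * (1 - y1 / y) * (y - d) / (y - 1)
  }
  list(chisq = o_e^2 / v, o_minus_e = o_e, var = v)
}
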