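#' Mean negative Cox partial log-likelihood of a vector of risk scores
#'
#' Computes the negative partial log-likelihood of linear risk scores under
#' the proportional hazards model, averaged over events. Ties are handled
#' with the Breslow approximation by default (follow-up recorded in whole
#' months produces heavy ties); the Efron approximation is available via
#' `ties = "efron"`. The loss is invariant to adding a constant to all
#' scores.
#'
#' @param scores Numeric risk scores, one per subject (higher = worse).
#' @param times Follow-up times, same length.
#' @param events 0/1 event indicators; at least one event required.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A single non-negative number.
#' @export
cox_partial_nll <- function(scores, times, events,
                            ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(length(scores) == length(times),
            length(times) == length(events))
  if (!all(events %in% c(0, 1))) stop_bsl("events must be 0/1")
  if (any(!is.finite(scores))) stop_bsl("scores must be finite")
  d_total <- sum(events)
  if (d_total == 0) stop_bsl("cox_partial_nll: no events; loss undefined")

  ord <- order(times)
  s <- scores[ord]; t <- times[ord]; e <- events[ord]
  n <- length(s)
  # log cumulative risk-set sums from the tail, numerically stable
  m <- max(s)
  rev_cum <- rev(cumsum(rev(exp(s - m))))
  log_risk <- m + log(rev_cum)            # log sum_{j: t_j >= t_i} exp(s_j)
  # first index of each tied time block
  first_idx <- match(t, t)
  ll <- 0
  ut <- unique(t)
  for (tt in ut) {
    idx <- which(t == tt & e == 1)
    if (!length(idx)) next
    d <- length(idx)
    lr <- log_risk[first_idx[idx[1]]]
    if (ties == "breslow") {
      ll <- ll + sum(s[idx]) - d * lr
    } else {
      # Efron: average out the tied deaths' own contribution
      m2 <- max(s[idx])
      tie_sum <- exp(m2 + log(sum(exp(s[idx] - m2))))
      risk_sum <- exp(lr)
      ll <- ll + sum(s[idx]) -
        sum(log(risk_sum - (seq_len(d) - 1) / d * tie_sum))
    }
  }
  -ll / d_total
}

# Gradient of cox_partial_nll (Breslow) with respect to the scores.
# Used by the training loop; returns a vector aligned with the input order.
cox_nll_grad <- function(scores, times, events) {
  ord <- order(times)
  s <- scores[ord]; t <- times[ord]; e <- events[ord]
  n <- length(s)
  d_total <- sum(e)
  w <- exp(s - max(s))
  rev_cum <- rev(cumsum(rev(w)))           # sum_{j: t_j >= t_i} w_j
  first_idx <- match(t, t)
  # per unique event time: d_k / risk_sum_k, accumulated for all subjects at
  # risk (t_i >= t_k): grad_i = (sum_{k: t_k <= t_i} d_k w_i / S_k - e_i)/D
  ut_idx <- which(!duplicated(t))
  coef <- numeric(n)                       # d_k / S_k at each block start
  for (fi in ut_idx) {
    d_k <- sum(e[t == t[fi]])
    if (d_k > 0) coef[fi] <- d_k / rev_cum[fi]
  }
  cum_coef <- cumsum(coef)                 # sum over event times <= t_i
  g_sorted <- (w * cum_coef - e) / d_total
  g <- numeric(n)
  g[ord] <- g_sorted
  g
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' Given fitted risk scores for the subjects of one treatment arm, computes
#' the non-decreasing step function
#' \deqn{H_0(t) = \sum_{t_i \le t} d_i / \sum_{j \in R(t_i)} e^{s_j}}
#' over the arm's unique event times. With all scores zero this reduces to
#' the Nelson-Aalen estimator.
#'
#' @param scores Risk scores of the arm's subjects.
#' @param times Follow-up times.
#' @param events 0/1 event indicators; at least one event required.
#' @return Object of class `bsl_basehaz`: list with `time` (unique event
#'   times, ascending) and `hazard` (cumulative baseline hazard at each).
#' @export
breslow_baseline <- function(scores, times, events) {
  stopifnot(length(scores) == length(times),
            length(times) == length(events))
  if (sum(events) == 0) {
    return(structure(list(time = numeric(0), hazard = numeric(0)),
                     class = "bsl_basehaz"))
  }
  ord <- order(times)
  s <- scores[ord]; t <- times[ord]; e <- events[ord]
  w <- exp(s)
  rev_cum <- rev(cumsum(rev(w)))
  first_idx <- match(t, t)
  ev_times <- sort(unique(t[e == 1]))
  inc <- vapply(ev_times, function(tt) {
    fi <- first_idx[match(tt, t)]
    sum(e[t == tt]) / rev_cum[fi]
  }, numeric(1))
  structure(list(time = ev_times, hazard = cumsum(inc)),
            class = "bsl_basehaz")
}

# Evaluate a cumulative baseline hazard step function at arbitrary times
# (right-continuous; 0 before the first event time).
eval_basehaz <- function(bh, t) {
  if (!length(bh$time)) return(rep(0, length(t)))
  idx <- findInterval(t, bh$time)
  c(0, bh$hazard)[idx + 1L]
}
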