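#' Hierarchical proximal operator of the sparse risk head
#'
#' Solves, independently per input feature j, the proximal problem
#' \deqn{\min_{b, W_j} \tfrac12 (b - u_j)^2 + \tfrac12 \|W_j - V_j\|^2 +
#'   s\lambda |b| \quad \text{s.t.} \quad \|W_j\|_\infty \le M |b|}
#' where \eqn{u_j} is the (post-gradient-step) linear skip weight and
#' \eqn{V_j} the corresponding first-layer weight row. The constraint is
#' enforced exactly, so a feature whose skip weight is driven to zero has its
#' entire first-layer row zeroed as well -- it drops out of both the linear
#' and the non-linear path. With `lambda = 0` the operator is the identity on
#' feasible inputs; with `M = Inf` it reduces to a plain soft-threshold on
#' the skip weights.
#'
#' @param theta Numeric vector of skip weights (one per input feature).
#' @param w Numeric matrix of first-layer weights, one row per input feature.
#' @param lambda L1 penalty (>= 0).
#' @param m_const Hierarchy constant M (> 0; `Inf` allowed).
#' @param step Proximal step size multiplying lambda (the optimizer's
#'   learning rate in training). Default 1.
#' @return List with components `theta` and `w` satisfying
#'   `max(abs(w[j,])) <= m_const * abs(theta[j])` for every feature.
#' @export
hier_prox <- function(theta, w, lambda, m_const, step = 1) {
  if (lambda < 0) stop_bsl("lambda must be >= 0")
  if (m_const <= 0) stop_bsl("hierarchy constant M must be > 0")
  w <- as.matrix(w)
  if (length(theta) != nrow(w)) {
    stop_bsl("theta has %d entries but w has %d rows", length(theta), nrow(w))
  }
  thr <- lambda * step
  if (is.infinite(m_const)) {
    return(list(theta = sign(theta) * pmax(abs(theta) - thr, 0), w = w))
  }
  k <- ncol(w)
  theta_out <- numeric(length(theta))
  w_out <- w
  for (j in seq_along(theta)) {
    u <- theta[j]
    v <- w[j, ]
    av <- sort(abs(v), decreasing = TRUE)
    cums <- cumsum(c(0, av))
    # candidate magnitudes w_m = M/(1 + m M^2) * soft(|u| + M * sum_{i<=m}|v|)
    ms <- 0:k
    wm <- (m_const / (1 + ms * m_const^2)) *
      pmax(abs(u) + m_const * cums - thr, 0)
    bounds_hi <- c(Inf, av)                # |v_(m)|
    bounds_lo <- c(av, 0)                  # |v_(m+1)|
    sel <- which(wm <= bounds_hi & wm >= bounds_lo)[1]
    if (is.na(sel)) sel <- k + 1           # numerical guard: full clipping
    wsel <- wm[sel]
    sgn <- if (u >= 0) 1 else -1
    theta_out[j] <- sgn * wsel / m_const
    w_out[j, ] <- sign(v) * pmin(abs(v), wsel)
  }
  list(theta = theta_out, w = w_out)
}
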