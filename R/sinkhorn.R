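# Debiased entropic optimal transport between latent point clouds.
#
# All computations run in the log domain with uniform weights and squared
# Euclidean cost. OT_eps(a, b) is the dual value <a, f> + <b, g> at the
# Sinkhorn fixed point; the divergence is the debiased form
#   S_eps(a, b) = OT_eps(a, b) - 1/2 OT_eps(a, a) - 1/2 OT_eps(b, b),
# which is symmetric, non-negative, and zero iff the clouds coincide.

sq_dist <- function(x, y) {
  # |x_i - y_j|^2 for row-point matrices
  xx <- rowSums(x^2)
  yy <- rowSums(y^2)
  d <- outer(xx, yy, "+") - 2 * tcrossprod(x, y)
  pmax(d, 0)
}

# Sinkhorn iterations for one OT_eps term; returns duals and the dual value.
sinkhorn_duals <- function(cost, eps, max_iter = 100, tol = 1e-6) {
  n <- nrow(cost); m <- ncol(cost)
  la <- -log(n); lb <- -log(m)             # log uniform weights
  f <- numeric(n); g <- numeric(m)
  for (it in seq_len(max_iter)) {
    f_old <- f
    # f_i = -eps * log sum_j b_j exp((g_j - C_ij)/eps)
    f <- -eps * row_logsumexp(sweep(-cost, 2, g, "+") / eps + lb)
    g <- -eps * row_logsumexp(t(sweep(-cost, 1, f, "+")) / eps + la)
    if (max(abs(f - f_old)) < tol) break
  }
  list(f = f, g = g, value = mean(f) + mean(g))
}

# Self-transport OT_eps(a, a): by symmetry f = g, and the averaged
# fixed-point update converges much faster than alternating projections.
sinkhorn_duals_sym <- function(cost, eps, max_iter = 100, tol = 1e-6) {
  n <- nrow(cost)
  la <- -log(n)
  f <- numeric(n)
  for (it in seq_len(max_iter)) {
    f_new <- -eps * row_logsumexp(sweep(-cost, 2, f, "+") / eps + la)
    delta <- max(abs(f_new - f))
    f <- 0.5 * (f + f_new)
    if (delta < tol) break
  }
  list(f = f, g = f, value = 2 * mean(f))
}

# Transport plan implied by converged duals (n x m, sums to 1).
sinkhorn_plan <- function(cost, f, g, eps) {
  n <- nrow(cost); m <- ncol(cost)
  lp <- (outer(f, g, "+") - cost) / eps - log(n) - log(m)
  exp(lp)
}

#' Sinkhorn divergence between the latent representations of two arms
#'
#' The smoothed optimal-transport balancing term of the model: a debiased
#' entropic Wasserstein discrepancy between the two treatment arms' latent
#' point clouds, with squared Euclidean ground cost and uniform weights. It
#' is symmetric, non-negative up to numerical tolerance, zero when the two
#' clouds coincide, and approaches the squared 2-Wasserstein distance as
#' `epsilon` shrinks.
#'
#' @param latent_arm0 Numeric matrix, one row per arm-0 subject.
#' @param latent_arm1 Numeric matrix, one row per arm-1 subject.
#' @param epsilon Entropic blur (> 0), on the squared-distance scale.
#' @param max_iter,tol Sinkhorn iteration controls.
#' @return Single non-negative number.
#' @export
ot_balance_loss <- function(latent_arm0, latent_arm1, epsilon = 0.5,
                            max_iter = 100, tol = 1e-6) {
  x <- as.matrix(latent_arm0); y <- as.matrix(latent_arm1)
  if (nrow(x) == 0 || nrow(y) == 0) {
    warn_bsl("ot_balance_loss: an arm is empty in this batch; term skipped")
    return(0)
  }
  if (epsilon <= 0) stop_bsl("epsilon must be > 0")
  # one solver for all three terms: identical clouds cancel exactly
  ab <- sinkhorn_duals(sq_dist(x, y), epsilon, max_iter, tol)
  aa <- sinkhorn_duals(sq_dist(x, x), epsilon, max_iter, tol)
  bb <- sinkhorn_duals(sq_dist(y, y), epsilon, max_iter, tol)
  ab$value - 0.5 * aa$value - 0.5 * bb$value
}

# Gradient of the Sinkhorn divergence with respect to both point clouds,
# via the envelope theorem: d OT/d x_i = sum_j P_ij * dC(x_i, y_j)/d x_i
# with the plan held fixed at its optimum.
ot_balance_grad <- function(x, y, epsilon, max_iter = 100, tol = 1e-6) {
  n <- nrow(x); m <- nrow(y)
  c_ab <- sq_dist(x, y); c_aa <- sq_dist(x, x); c_bb <- sq_dist(y, y)
  d_ab <- sinkhorn_duals(c_ab, epsilon, max_iter, tol)
  d_aa <- sinkhorn_duals_sym(c_aa, epsilon, max_iter, tol)
  d_bb <- sinkhorn_duals_sym(c_bb, epsilon, max_iter, tol)
  p_ab <- sinkhorn_plan(c_ab, d_ab$f, d_ab$g, epsilon)
  p_aa <- sinkhorn_plan(c_aa, d_aa$f, d_aa$g, epsilon)
  p_bb <- sinkhorn_plan(c_bb, d_bb$f, d_bb$g, epsilon)

  # cross term: 2 * (rowsum_i(P) x_i - P y)
  gx <- 2 * (rowSums(p_ab) * x - p_ab %*% y)
  gy <- 2 * (colSums(p_ab) * y - t(p_ab) %*% x)
  # self terms enter twice (point appears as source and target)
  p_aa_s <- p_aa + t(p_aa)
  p_bb_s <- p_bb + t(p_bb)
  gx <- gx - 0.5 * 2 * (rowSums(p_aa_s) * x - p_aa_s %*% x)
  gy <- gy - 0.5 * 2 * (rowSums(p_bb_s) * y - p_bb_s %*% y)
  list(
    grad0 = gx,
    grad1 = gy,
    value = d_ab$value - 0.5 * d_aa$value - 0.5 * d_bb$value
  )
}
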