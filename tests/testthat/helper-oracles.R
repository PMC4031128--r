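# Independent oracles kept deliberately separate from the package code.

# Dense PLS2 by the classical NIPALS inner iteration (u-loop to
# convergence), used to check that eta = 0 sparse fits reduce to
# ordinary PLS. Signs per component are fixed the same way as the
# package (largest-|w| element positive) so scores are comparable.
pls2_nipals_oracle <- function(X, Y, K, tol = 1e-12, maxit = 5000) {
  Xk <- scale(X, center = TRUE, scale = FALSE)
  Yk <- as.matrix(Y)
  n <- nrow(Xk); p <- ncol(Xk); G <- ncol(Yk)
  W <- matrix(0, p, K); Tm <- matrix(0, n, K)
  P <- matrix(0, p, K); Q <- matrix(0, G, K)
  for (k in seq_len(K)) {
    u <- Yk[, which.max(apply(Yk, 2, var))]
    w <- rep(0, p)
    for (it in seq_len(maxit)) {
      w_new <- drop(crossprod(Xk, u))
      w_new <- w_new / sqrt(sum(w_new^2))
      t_ <- drop(Xk %*% w_new)
      q_ <- drop(crossprod(Yk, t_)) / sum(t_^2)
      u_new <- drop(Yk %*% q_) / sum(q_^2)
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new; u <- u_new
    }
    jmax <- which.max(abs(w))
    if (w[jmax] < 0) w <- -w
    t_ <- drop(Xk %*% w)
    P[, k] <- drop(crossprod(Xk, t_)) / sum(t_^2)
    Q[, k] <- drop(crossprod(Yk, t_)) / sum(t_^2)
    W[, k] <- w; Tm[, k] <- t_
    Xk <- Xk - tcrossprod(t_, P[, k])
    Yk <- Yk - tcrossprod(t_, Q[, k])
  }
  list(weights = W, scores = Tm)
}

# Exact expected observed-OTU richness after rarefying without
# replacement: E = sum_j (1 - choose(total - c_j, depth) /
# choose(total, depth)), the marginal hypergeometric absence law.
expected_richness_hypergeom <- function(counts, depth) {
  total <- sum(counts)
  sum(1 - choose(total - counts, depth) / choose(total, depth))
}

random_clr_instance <- function(n, p, seed) {
  set.seed(seed)
  counts <- matrix(rpois(n * p, lambda = 30) + 1L, n, p,
                   dimnames = list(sprintf("s%02d", seq_len(n)),
                                   sprintf("o%03d", seq_len(p))))
  clrda::clr_transform(clrda::close_composition(
    clrda::count_table(counts), 0))
}
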