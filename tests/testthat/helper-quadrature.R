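# Gauss-Hermite quadrature oracle for one-eta marginal likelihoods.
# Nodes/weights by Golub-Welsch (eigendecomposition of the Jacobi matrix);
# independent of the package's Laplace machinery.

gauss_hermite <- function(n) {
  off <- sqrt(seq_len(n - 1) / 2)
  J <- matrix(0, n, n)
  J[cbind(seq_len(n - 1), seq_len(n - 1) + 1)] <- off
  J[cbind(seq_len(n - 1) + 1, seq_len(n - 1))] <- off
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = eg$values[ord],
       weights = (sqrt(pi) * eg$vectors[1, ]^2)[ord])
}

# -2 log of the exact (to quadrature error) marginal likelihood of one
# subject under the proportional-error model with a single lognormal eta:
#   y_j ~ N(f_j(eta), (sigma f_j(eta))^2),  eta ~ N(0, omega^2)
# pred_fun(eta) must return the prediction vector (computed independently
# of the package, e.g. with the RK45 oracle).
gh_neg2ll_subject <- function(y, pred_fun, sigma, omega, n_nodes = 64) {
  gh <- gauss_hermite(n_nodes)
  log_terms <- vapply(seq_len(n_nodes), function(i) {
    eta <- sqrt(2) * omega * gh$nodes[i]
    f <- pred_fun(eta)
    log(gh$weights[i] / sqrt(pi)) +
      sum(dnorm(y, mean = f, sd = sigma * f, log = TRUE))
  }, numeric(1))
  m <- max(log_terms)
  -2 * (m + log(sum(exp(log_terms - m))))
}
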