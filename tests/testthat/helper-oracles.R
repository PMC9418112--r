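# Independent brute-force oracles used across the tests. These deliberately
# use plain arithmetic (no log-sum-exp, no clamping) on interior parameter
# values so they stay independent of the implementation they check.

random_theta <- function(N, G, K, interior = TRUE) {
  pi <- rexp(G); pi <- pi / sum(pi)
  tau <- rexp(K); tau <- tau / sum(tau)
  a <- if (K > 1) c(sort(runif(K - 1, 0.3, 0.95)), 1) else 1
  lim <- if (interior) c(0.1, 0.9) else c(0, 1)
  phi <- matrix(runif(N * G, lim[1], lim[2]), N, G)
  elca_params(pi = pi, tau = tau, a = a, phi = phi)
}

random_incidence <- function(N, M, p = 0.4) {
  incidence_matrix(matrix(rbinom(N * M, 1, p), N, M))
}

# Probability of one hyperedge column by direct double summation.
brute_column_prob <- function(x, theta) {
  total <- 0
  for (g in seq_len(theta$G)) {
    for (k in seq_len(theta$K)) {
      p <- theta$a[k] * theta$phi[, g]
      total <- total + theta$pi[g] * theta$tau[k] *
        prod(p^x * (1 - p)^(1 - x))
    }
  }
  total
}

brute_loglik <- function(X, theta) {
  sum(X$weights * vapply(seq_len(n_hyperedges(X)), function(j) {
    log(brute_column_prob(X$x[, j], theta))
  }, numeric(1)))
}

# Joint responsibilities of one column by direct arithmetic.
brute_responsibilities <- function(x, theta) {
  num <- matrix(0, theta$G, theta$K)
  for (g in seq_len(theta$G)) {
    for (k in seq_len(theta$K)) {
      p <- theta$a[k] * theta$phi[, g]
      num[g, k] <- theta$pi[g] * theta$tau[k] * prod(p^x * (1 - p)^(1 - x))
    }
  }
  num / sum(num)
}

# LCA observed log-likelihood by direct arithmetic.
brute_lca_loglik <- function(X, params) {
  sum(X$weights * vapply(seq_len(n_hyperedges(X)), function(j) {
    x <- X$x[, j]
    log(sum(vapply(seq_len(params$G), function(g) {
      p <- params$p[, g]
      params$pi[g] * prod(p^x * (1 - p)^(1 - x))
    }, numeric(1))))
  }, numeric(1)))
}
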