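# Probability clamp applied before any log: M*N Bernoulli products underflow
# quickly and phi or a at exactly 0/1 would produce -Inf logs.
PROB_EPS <- 1e-12

clamp_prob <- function(p, eps = PROB_EPS) pmin(pmax(p, eps), 1 - eps)

# N x (G*K) matrix of per-vertex success probabilities, component c = (k-1)*G + g
# holding a[k] * phi[, g]; plus the matching log mixture weights log(pi_g tau_k).
component_probs <- function(theta) {
  G <- theta$G
  K <- theta$K
  p <- theta$phi[, rep(seq_len(G), times = K), drop = FALSE] *
    matrix(rep(theta$a, each = G), theta$N, G * K, byrow = TRUE)
  logw <- log(theta$pi[rep(seq_len(G), times = K)]) +
    log(theta$tau[rep(seq_len(K), each = G)])
  list(p = p, logw = logw)
}

# M x C matrix of conditional Bernoulli log-probabilities log Pr(x_j | comp c)
# for columns of the incidence matrix, given N x C success probabilities.
bernoulli_loglik_matrix <- function(xmat, p) {
  p <- clamp_prob(p)
  crossprod(xmat, log(p)) + crossprod(1 - xmat, log1p(-p))
}

row_logsumexp <- function(L) {
  m0 <- do.call(pmax, as.data.frame(L))
  m0 + log(rowSums(exp(L - m0)))
}

# Per-hyperedge observed log-probabilities under an ELCA or LCA model,
# returned as a length-M vector (weights not applied).
column_log_probs <- function(xmat, params) {
  if (inherits(params, "elca_params")) {
    cp <- component_probs(params)
    p <- cp$p
    logw <- cp$logw
  } else if (inherits(params, "lca_params")) {
    p <- params$p
    logw <- log(params$pi)
  } else {
    stop("params must be elca_params or lca_params")
  }
  L <- bernoulli_loglik_matrix(xmat, p)
  L <- sweep(L, 2L, logw, "+")
  row_logsumexp(L)
}

#' Log-probability of a single hyperedge
#'
#' Evaluates, in log space via log-sum-exp over all `(g, k)` cluster pairs,
#' the marginal probability that the ELCA model generates the hyperedge
#' with membership vector `x`:
#' `sum_g sum_k pi_g tau_k prod_i (a_k phi_ig)^x_i (1 - a_k phi_ig)^(1-x_i)`.
#' Per-Bernoulli probabilities are clamped to `[1e-12, 1 - 1e-12]` before
#' logging, so the result is always finite.
#'
#' @param x 0/1 vector of length `N`.
#' @param theta an [elca_params()] object.
#' @return a scalar `<= 0` (up to clamping error).
#' @export
hyperedge_log_prob <- function(x, theta) {
  stopifnot(inherits(theta, "elca_params"))
  x <- as.double(x)
  if (length(x) != theta$N) stop("x must have length N")
  if (!all(x == 0 | x == 1)) stop("x must be a 0/1 vector")
  as.double(column_log_probs(matrix(x, ncol = 1L), theta))
}

#' Observed-data log-likelihood
#'
#' Sum over hyperedges (respecting multiplicity weights) of the log
#' marginal probability of each column of the incidence matrix under an
#' ELCA model (`elca_loglik`) or a standard LCA model (`lca_loglik`). The
#' value is invariant under column permutations of `X`.
#'
#' @param X an [incidence_matrix()].
#' @param theta an [elca_params()] object.
#' @param params an [lca_params()] object.
#' @return a scalar log-likelihood.
#' @export
elca_loglik <- function(X, theta) {
  stopifnot(inherits(X, "incidence_matrix"), inherits(theta, "elca_params"))
  if (n_vertices(X) != theta$N) stop("X and theta disagree on N")
  sum(X$weights * column_log_probs(X$x, theta))
}

#' @rdname elca_loglik
#' @export
lca_loglik <- function(X, params) {
  stopifnot(inherits(X, "incidence_matrix"), inherits(params, "lca_params"))
  if (n_vertices(X) != params$N) stop("X and params disagree on N")
  sum(X$weights * column_log_probs(X$x, params))
}

#' Complete-data log-likelihood
#'
#' Log-likelihood of the incidence data together with hard cluster
#' assignments: for each hyperedge `j` with primary label `g_j` and size
#' label `k_j`,
#' `log pi_{g_j} + log tau_{k_j} + sum_i x_ij log(a_{k_j} phi_{i g_j}) +
#'  (1 - x_ij) log(1 - a_{k_j} phi_{i g_j})`.
#' Marginalizing (log-sum-exp) over all assignments per hyperedge recovers
#' the observed-data log-likelihood.
#'
#' @param X an [incidence_matrix()].
#' @param z1 `M x G` 0/1 indicator matrix of primary labels (one 1 per row),
#'   or an integer vector of labels in `1..G`.
#' @param z2 `M x K` 0/1 indicator matrix of size labels, or an integer
#'   vector of labels in `1..K`.
#' @param theta an [elca_params()] object.
#' @return a scalar.
#' @export
complete_data_loglik <- function(X, z1, z2, theta) {
  stopifnot(inherits(X, "incidence_matrix"), inherits(theta, "elca_params"))
  m <- n_hyperedges(X)
  g <- indicator_to_labels(z1, theta$G, m, "z1")
  k <- indicator_to_labels(z2, theta$K, m, "z2")
  cp <- component_probs(theta)
  comp <- (k - 1L) * theta$G + g
  L <- bernoulli_loglik_matrix(X$x, cp$p)
  sum(X$weights * (cp$logw[comp] + L[cbind(seq_len(m), comp)]))
}

indicator_to_labels <- function(z, C, m, name) {
  if (is.matrix(z)) {
    if (nrow(z) != m || ncol(z) != C) stop(sprintf("%s has wrong dimensions", name))
    if (!all(z == 0 | z == 1) || any(rowSums(z) != 1)) {
      stop(sprintf("%s rows must each contain exactly one 1", name))
    }
    max.col(z, ties.method = "first")
  } else {
    z <- as.integer(z)
    if (length(z) != m || any(z < 1L) || any(z > C)) {
      stop(sprintf("%s labels must lie in 1..%d and have length M", name, C))
    }
    z
  }
}
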