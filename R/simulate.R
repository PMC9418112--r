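#' Simulate a labeled hypergraph from the ELCA model
#'
#' Draws, for each of `M` hyperedges, a primary label `z1 ~ Categorical(pi)`
#' and an independent size label `z2 ~ Categorical(tau)`, then fills the
#' incidence column with independent Bernoulli draws with success
#' probability `a[z2] * phi[i, z1]`. Labels are drawn before incidences and
#' the incidence draws are laid out column-major, so output is
#' bit-reproducible given `seed`.
#'
#' @param theta an [elca_params()] object.
#' @param M number of hyperedges to generate.
#' @param seed integer seed.
#' @return a list with `X` (an [incidence_matrix()]) and `labels` (a list
#'   with integer vectors `z1` in `1..G` and `z2` in `1..K`).
#' @export
simulate_elca <- function(theta, M, seed = 1L) {
  stopifnot(inherits(theta, "elca_params"), M >= 1)
  M <- as.integer(M)
  with_seed(seed, {
    z1 <- sample.int(theta$G, M, replace = TRUE, prob = theta$pi)
    z2 <- sample.int(theta$K, M, replace = TRUE, prob = theta$tau)
    p <- theta$phi[, z1, drop = FALSE] *
      matrix(theta$a[z2], theta$N, M, byrow = TRUE)
    x <- (matrix(stats::runif(theta$N * M), theta$N, M) < p) * 1
    list(X = incidence_matrix(x, vertex_names = theta$vertex_names),
         labels = list(z1 = z1, z2 = z2))
  })
}

#' Simulate from a standard LCA model
#'
#' @param params an [lca_params()] object.
#' @param M number of hyperedges.
#' @param seed integer seed.
#' @return a list with `X` and `labels` (`z1` only).
#' @export
simulate_lca <- function(params, M, seed = 1L) {
  stopifnot(inherits(params, "lca_params"), M >= 1)
  M <- as.integer(M)
  with_seed(seed, {
    z1 <- sample.int(params$G, M, replace = TRUE, prob = params$pi)
    p <- params$p[, z1, drop = FALSE]
    x <- (matrix(stats::runif(params$N * M), params$N, M) < p) * 1
    list(X = incidence_matrix(x, vertex_names = params$vertex_names),
         labels = list(z1 = z1))
  })
}

#' Exact moments of the hyperedge-size distribution
#'
#' The size of a random hyperedge is, conditionally on its cluster (pair),
#' a Poisson-binomial count with per-vertex probabilities given by the
#' cluster profile; the marginal moments follow from the laws of total
#' expectation and variance. For an ELCA model the components are the
#' `G x K` pairs with weights `pi_g tau_k` and probabilities
#' `a_k * phi[, g]`; for an LCA model the `G` classes with probabilities
#' `p[, g]`. When `p[i, g] = phi[i, g] * sum_k a_k tau_k` (see
#' [matched_lca_params()]) the two models have identical size means while
#' the ELCA variance is at least the LCA variance.
#'
#' @param params an [elca_params()] or [lca_params()] object.
#' @return a list with elements `mean` and `variance`.
#' @export
exact_size_moments <- function(params) {
  cm <- size_components(params)
  s <- colSums(cm$p)
  v <- colSums(cm$p * (1 - cm$p))
  mean_total <- sum(cm$w * s)
  list(mean = mean_total,
       variance = sum(cm$w * v) + sum(cm$w * s^2) - mean_total^2)
}

# Mixture components of the size distribution: weights `w` and an N x C
# matrix of per-vertex probabilities.
size_components <- function(params) {
  if (inherits(params, "elca_params")) {
    cp <- component_probs(params)
    list(w = exp(cp$logw), p = cp$p)
  } else if (inherits(params, "lca_params")) {
    list(w = params$pi, p = params$p)
  } else {
    stop("params must be elca_params or lca_params")
  }
}

#' Exact probability mass function of the hyperedge size
#'
#' Computed by the Poisson-binomial convolution recursion within each
#' mixture component (O(N^2) per component) and mixing with the component
#' weights; deterministic, no sampling.
#'
#' @param params an [elca_params()] or [lca_params()] object.
#' @return numeric vector of length `N + 1` with the probabilities of
#'   sizes `0, 1, ..., N`.
#' @export
hyperedge_size_pmf <- function(params) {
  cm <- size_components(params)
  n <- nrow(cm$p)
  out <- numeric(n + 1L)
  for (cidx in seq_along(cm$w)) {
    out <- out + cm$w[cidx] * poisson_binomial_pmf(cm$p[, cidx])
  }
  out
}

# pmf of a sum of independent Bernoulli(p_i) variables, length N + 1.
poisson_binomial_pmf <- function(p) {
  f <- 1
  for (pi_ in p) {
    f <- c(f * (1 - pi_), 0) + c(0, f * pi_)
  }
  f
}

#' Poisson mixture probability mass function
#'
#' `sum_c w_c exp(-rate_c) rate_c^y / y!`, the limiting size distribution
#' of hyperedges when per-vertex probabilities vanish while per-cluster
#' totals converge.
#'
#' @param weights probability vector of component weights.
#' @param rates positive component rates, same length as `weights`.
#' @param y vector of nonnegative integers.
#' @return probabilities, same length as `y`.
#' @export
poisson_mixture_pmf <- function(weights, rates, y) {
  check_simplex(weights, "weights")
  stopifnot(length(weights) == length(rates), all(rates > 0), all(y >= 0))
  vapply(y, function(yy) sum(weights * stats::dpois(yy, rates)), numeric(1L))
}

#' Total-variation distance of the size distribution to its Poisson limit
#'
#' Rescales the profile matrix of `theta` so that each cluster's total
#' membership probability is held at `Lambda_g = sum_i phi[i, g]` while
#' individual per-vertex probabilities shrink as `Lambda_g / N`, the regime
#' in which the hyperedge-size distribution converges to a mixture of
#' `G x K` Poisson distributions with weights `pi_g tau_k` and rates
#' `a_k Lambda_g`. For each `N` in `n_vertices_sequence` the exact size pmf
#' (Poisson-binomial convolution) is compared in total variation to that
#' limit: `TV = 0.5 * (sum_{y<=N} |f_N(y) - h(y)| + P_h(Y > N))`.
#'
#' @param theta an [elca_params()] object whose profile column sums define
#'   the limiting rates.
#' @param n_vertices_sequence increasing vector of vertex counts.
#' @return numeric vector of total-variation distances, one per `N`.
#' @export
size_tv_to_poisson_limit <- function(theta, n_vertices_sequence) {
  stopifnot(inherits(theta, "elca_params"), all(n_vertices_sequence >= 1))
  lambda_g <- colSums(theta$phi)
  w <- as.vector(outer(theta$pi, theta$tau))
  rates <- as.vector(outer(lambda_g, theta$a))
  keep <- rates > 0
  vapply(n_vertices_sequence, function(n) {
    n <- as.integer(n)
    per_vertex <- lambda_g / n
    if (any(per_vertex > 1)) {
      stop(sprintf("N = %d too small: per-vertex probability exceeds 1", n))
    }
    th_n <- elca_params(pi = theta$pi, tau = theta$tau, a = theta$a,
                        phi = matrix(rep(per_vertex, each = n), n, theta$G))
    f <- hyperedge_size_pmf(th_n)
    y <- 0:n
    h <- if (any(keep)) {
      colSums(w[keep] * outer(rates[keep], y, function(r, yy) stats::dpois(yy, r)))
    } else {
      numeric(n + 1L)
    }
    if (!any(keep)) h[1L] <- h[1L] + sum(w[!keep])  # degenerate Poisson(0)
    else if (any(!keep)) h[1L] <- h[1L] + sum(w[!keep])
    tail_mass <- 1 - sum(h)
    0.5 * (sum(abs(f - h)) + max(tail_mass, 0))
  }, numeric(1L))
}
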