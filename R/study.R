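#' Reference parameter sets for simulation studies
#'
#' Well-separated ELCA parameter sets used throughout the package's
#' simulation studies and tests. Profiles are block-structured: each
#' primary cluster has a high membership probability on its own block of
#' vertices and a low probability elsewhere, which keeps clusters
#' identifiable at moderate `N` and `M`.
#'
#' * `"g2k2"`: `G = 2`, `K = 2`, `pi = (1/2, 1/2)`, `tau = (1/2, 1/2)`,
#'   `a = (0.4, 1)`, profile blocks at 0.8 / 0.2.
#' * `"g3k2"`: `G = 3`, `K = 2`, `pi = (1/3, 1/3, 1/3)`,
#'   `tau = (1/2, 1/2)`, `a = (0.4, 1)`, blocks at 0.8 / 0.15.
#' * `"lca_g2"`: `G = 2`, `K = 1` (a plain LCA), `pi = (1/2, 1/2)`,
#'   blocks at 0.7 / 0.1.
#'
#' @param design one of `"g2k2"`, `"g3k2"`, `"lca_g2"`.
#' @param N number of vertices (split into `G` near-equal blocks).
#' @return an [elca_params()] object.
#' @export
study_params <- function(design = c("g2k2", "g3k2", "lca_g2"), N = 20L) {
  design <- match.arg(design)
  N <- as.integer(N)
  block_phi <- function(G, hi, lo) {
    blocks <- split(seq_len(N), cut(seq_len(N), G, labels = FALSE))
    phi <- matrix(lo, N, G)
    for (g in seq_len(G)) phi[blocks[[g]], g] <- hi
    phi
  }
  switch(design,
    g2k2 = elca_params(pi = c(0.5, 0.5), tau = c(0.5, 0.5), a = c(0.4, 1),
                       phi = block_phi(2L, 0.8, 0.2)),
    g3k2 = elca_params(pi = rep(1 / 3, 3), tau = c(0.5, 0.5), a = c(0.4, 1),
                       phi = block_phi(3L, 0.8, 0.15)),
    lca_g2 = elca_params(pi = c(0.5, 0.5), tau = 1, a = 1,
                         phi = block_phi(2L, 0.7, 0.1)))
}

#' Parameter-recovery simulation study
#'
#' For each replicate and each hyperedge count in `M_values`, simulates a
#' hypergraph from `theta`, refits the model with the true `(G, K)`, aligns
#' the estimated clusters with the simulated labels (primary clusters via
#' the primary-marginal posterior, size clusters via the additional
#' marginal), and records the aligned l2 parameter errors and both
#' misclassification rates.
#'
#' @param theta the generating [elca_params()].
#' @param M_values vector of hyperedge counts.
#' @param n_replicates replicates per `M`.
#' @param control an [elca_control()] for the fits; replicate `r` offsets
#'   the simulation and fitting seeds deterministically.
#' @return a data frame with columns `M`, `replicate`, `l2_phi`, `l2_a`,
#'   `l2_pi`, `l2_tau`, `mis1`, `mis2`, `converged`.
#' @export
recovery_study <- function(theta, M_values, n_replicates = 20L,
                           control = elca_control(n_restarts = 3L)) {
  rows <- vector("list", length(M_values) * n_replicates)
  idx <- 0L
  for (M in M_values) {
    for (r in seq_len(n_replicates)) {
      sim_seed <- control$seed + 1000L * r + M
      sim <- simulate_elca(theta, M, seed = sim_seed)
      ctl <- control
      ctl$seed <- control$seed + 7919L * r
      fit <- elca_fit(sim$X, theta$G, theta$K, control = ctl)
      al1 <- align_labels(sim$labels$z1, posterior_marginals(fit, "primary"))
      al2 <- align_labels(sim$labels$z2, posterior_marginals(fit, "additional"))
      err <- parameter_error(theta, fit$params,
                             perm_primary = al1$permutation,
                             perm_additional = al2$permutation)
      idx <- idx + 1L
      rows[[idx]] <- data.frame(M = M, replicate = r,
                                l2_phi = err$l2_phi, l2_a = err$l2_a,
                                l2_pi = err$l2_pi, l2_tau = err$l2_tau,
                                mis1 = al1$rate, mis2 = al2$rate,
                                converged = fit$converged)
    }
  }
  do.call(rbind, rows)
}

#' BIC selection-rate simulation study
#'
#' Simulates `n_replicates` hypergraphs from `theta`, runs BIC selection
#' over the `(G, K)` grid on each, and tabulates how often each cell is
#' selected.
#'
#' @param theta the generating [elca_params()].
#' @param M hyperedges per replicate.
#' @param G_range,K_range candidate grids.
#' @param n_replicates number of replicates.
#' @param control an [elca_control()] for the fits.
#' @return a data frame with columns `replicate`, `G_selected`,
#'   `K_selected`, plus attribute `"true"` holding `c(G, K)`.
#' @export
bic_selection_study <- function(theta, M, G_range = 1:3, K_range = 1:3,
                                n_replicates = 20L,
                                control = elca_control(n_restarts = 3L)) {
  out <- data.frame(replicate = seq_len(n_replicates),
                    G_selected = NA_integer_, K_selected = NA_integer_)
  for (r in seq_len(n_replicates)) {
    sim <- simulate_elca(theta, M, seed = control$seed + 104729L * r)
    ctl <- control
    ctl$seed <- control$seed + 7919L * r
    grid <- select_model(sim$X, G_range, K_range, control = ctl)
    out$G_selected[r] <- grid$selected$G
    out$K_selected[r] <- grid$selected$K
  }
  attr(out, "true") <- c(G = theta$G, K = theta$K)
  out
}

#' Recovery-rate study for LCA truths fitted with extra size clusters
#'
#' Simulates from an LCA truth (`K = 1`), fits an ELCA with `K_fit` size
#' clusters, and reports the fraction of replicates in which
#' [recovery_check()] declares the truth recovered.
#'
#' @param theta_true generating [elca_params()] with `K = 1`.
#' @param K_fit number of size clusters to fit.
#' @param M hyperedges per replicate.
#' @param n_replicates number of replicates.
#' @param epsilon threshold(s) for [recovery_check()].
#' @param control an [elca_control()] for the fits.
#' @return a named numeric vector of recovery rates, one per `epsilon`.
#' @export
lca_recovery_study <- function(theta_true, K_fit = 2L, M = 500L,
                               n_replicates = 20L, epsilon = c(0.01, 0.05),
                               control = elca_control(n_restarts = 3L)) {
  stopifnot(theta_true$K == 1L)
  hits <- matrix(FALSE, n_replicates, length(epsilon))
  for (r in seq_len(n_replicates)) {
    sim <- simulate_elca(theta_true, M, seed = control$seed + 104729L * r)
    ctl <- control
    ctl$seed <- control$seed + 7919L * r
    fit <- elca_fit(sim$X, theta_true$G, K_fit, control = ctl)
    hits[r, ] <- vapply(epsilon, function(e) recovery_check(fit$params, e),
                        logical(1L))
  }
  stats::setNames(colMeans(hits), paste0("epsilon_", epsilon))
}
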