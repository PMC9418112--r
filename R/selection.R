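#' Bayesian Information Criterion for ELCA / LCA fits
#'
#' `-2 * loglik + n_parameters * log(M)` with the parameter count from
#' [n_parameters()]. `M` is the effective number of hyperedges
#' (`sum(weights)` when duplicates are collapsed). The model with the
#' lowest BIC over a `(G, K)` grid is selected; reliability requires `M`
#' reasonably large relative to `N`.
#'
#' @param loglik observed-data log-likelihood at the estimate.
#' @param G,K,N model dimensions.
#' @param M effective number of hyperedges (`>= 2`).
#' @param model `"elca"` or `"lca"`.
#' @return a scalar.
#' @export
bic <- function(loglik, G, K, N, M, model = c("elca", "lca")) {
  stopifnot(M >= 2)
  -2 * loglik + n_parameters(G, K, N, match.arg(model)) * log(M)
}

#' BIC model selection over a (G, K) grid
#'
#' Fits the ELCA model for every pair in `G_range x K_range` with a shared
#' seeding policy (each cell uses the same base seed from `control`, so
#' grids are deterministic given the seed) and selects the converged cell
#' with the lowest BIC. Ties are broken towards fewer parameters, then
#' smaller `G`. Cells whose best restart did not converge are flagged and
#' excluded from selection unless every cell is flagged.
#'
#' @param X an [incidence_matrix()].
#' @param G_range,K_range vectors of candidate cluster counts.
#' @param control an [elca_control()] list.
#' @param keep_fits keep the fitted objects in the result (default FALSE).
#' @return an object of class `"bic_grid"`: a list with `grid` (data frame
#'   with columns `G`, `K`, `loglik`, `bic`, `converged`), `selected`
#'   (list with `G`, `K`), and optionally `fits`.
#' @export
select_model <- function(X, G_range, K_range, control = elca_control(),
                         keep_fits = FALSE) {
  stopifnot(length(G_range) >= 1, length(K_range) >= 1)
  cells <- expand.grid(G = sort(unique(as.integer(G_range))),
                       K = sort(unique(as.integer(K_range))))
  cells <- cells[order(cells$G, cells$K), , drop = FALSE]
  fits <- vector("list", nrow(cells))
  res <- data.frame(G = cells$G, K = cells$K, loglik = NA_real_,
                    bic = NA_real_, converged = NA)
  for (r in seq_len(nrow(cells))) {
    fit <- tryCatch(elca_fit(X, cells$G[r], cells$K[r], control = control),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      res$converged[r] <- FALSE
      next
    }
    res$loglik[r] <- fit$loglik
    res$bic[r] <- fit$bic
    res$converged[r] <- fit$converged
    if (keep_fits) fits[[r]] <- fit
  }
  pool <- which(res$converged & is.finite(res$bic))
  if (length(pool) == 0L) pool <- which(is.finite(res$bic))
  if (length(pool) == 0L) stop("no model in the grid could be fitted")
  npar <- n_parameters(res$G[pool], res$K[pool], n_vertices(X), "elca")
  ord <- order(res$bic[pool], npar, res$G[pool])
  sel <- pool[ord[1L]]
  structure(list(grid = res,
                 selected = list(G = res$G[sel], K = res$K[sel]),
                 fits = if (keep_fits) fits else NULL),
            class = "bic_grid")
}

#' @export
print.bic_grid <- function(x, ...) {
  cat("BIC model selection grid:\n")
  print(x$grid, row.names = FALSE)
  cat(sprintf("selected: G = %d, K = %d\n", x$selected$G, x$selected$K))
  invisible(x)
}

#' Align estimated clusters with reference labels
#'
#' Hard labels are the per-row argmax of the posterior matrix; the
#' permutation of estimated clusters minimizing total disagreement with the
#' reference labels is found by optimal assignment on the confusion matrix
#' (exhaustive search for `C <= 5`, Hungarian algorithm otherwise). The
#' misclassification rate is the minimized disagreement divided by the
#' number of observations.
#'
#' @param true_labels integer vector with values in `1..C`.
#' @param posterior numeric matrix with one row per observation and `C`
#'   columns of posterior probabilities (a hard labeling can be supplied as
#'   a 0/1 indicator matrix).
#' @return a list with `permutation` (integer vector: estimated cluster `c`
#'   corresponds to reference cluster `permutation[c]`), `rate`, and
#'   `hard_labels` (aligned, i.e. after applying the permutation).
#' @export
align_labels <- function(true_labels, posterior) {
  true_labels <- as.integer(true_labels)
  posterior <- as.matrix(posterior)
  C <- ncol(posterior)
  if (max(true_labels) > C || min(true_labels) < 1L) {
    stop("labels must lie in 1..ncol(posterior)")
  }
  if (length(true_labels) != nrow(posterior)) {
    stop("true_labels and posterior disagree on the number of observations")
  }
  hard <- max.col(posterior, ties.method = "first")
  conf <- matrix(0, C, C)  # conf[r, c] = #{true == r & hard == c}
  for (j in seq_along(hard)) conf[true_labels[j], hard[j]] <- conf[true_labels[j], hard[j]] + 1
  perm <- solve_assignment(-conf)  # maximize matched counts
  matched <- sum(conf[cbind(perm, seq_len(C))])
  list(permutation = perm,
       rate = 1 - matched / length(hard),
       hard_labels = perm[hard])
}

#' Aligned l2 parameter errors
#'
#' Euclidean distances between true and estimated ELCA parameters after
#' relabeling the estimate's clusters: the primary permutation reorders the
#' columns of `phi` and the entries of `pi`, the additional permutation the
#' entries of `a` and `tau`. `phi` is compared as a flattened `N * G`
#' vector. With `normalize = TRUE` each distance is divided by the square
#' root of its number of entries (per-entry root-mean-square error);
#' the default is the raw norm.
#'
#' @param theta_true,theta_hat [elca_params()] objects of equal dimensions.
#' @param perm_primary permutation of `1..G`: estimated cluster `c`
#'   corresponds to true cluster `perm_primary[c]` (see [align_labels()]).
#' @param perm_additional permutation of `1..K`.
#' @param normalize divide each norm by sqrt(number of entries).
#' @return a list with `l2_phi`, `l2_a`, `l2_pi`, `l2_tau`.
#' @export
parameter_error <- function(theta_true, theta_hat,
                            perm_primary = seq_len(theta_true$G),
                            perm_additional = seq_len(theta_true$K),
                            normalize = FALSE) {
  stopifnot(inherits(theta_true, "elca_params"), inherits(theta_hat, "elca_params"),
            theta_true$G == theta_hat$G, theta_true$K == theta_hat$K,
            theta_true$N == theta_hat$N)
  G <- theta_true$G
  K <- theta_true$K
  inv1 <- order(perm_primary)   # column of hat matching true cluster r
  inv2 <- order(perm_additional)
  phi_hat <- theta_hat$phi[, inv1, drop = FALSE]
  pi_hat <- theta_hat$pi[inv1]
  a_hat <- theta_hat$a[inv2]
  tau_hat <- theta_hat$tau[inv2]
  nrm <- function(d, n) if (normalize) sqrt(sum(d^2) / n) else sqrt(sum(d^2))
  list(l2_phi = nrm(theta_true$phi - phi_hat, theta_true$N * G),
       l2_a = nrm(theta_true$a - a_hat, K),
       l2_pi = nrm(theta_true$pi - pi_hat, G),
       l2_tau = nrm(theta_true$tau - tau_hat, K))
}

#' Recovery criterion for an LCA truth fitted with extra size clusters
#'
#' When data generated from a plain LCA (`K = 1`) are fitted with an ELCA
#' model with `K > 1`, the truth is considered recovered if the extra size
#' structure collapses: `max(tau) > 1 - epsilon` (one size cluster takes
#' nearly all the mass) or `min(a) > 1 - epsilon` (all size factors are
#' nearly 1).
#'
#' @param theta_hat an [elca_params()] object.
#' @param epsilon small positive threshold, e.g. 0.01 or 0.05.
#' @return logical flag.
#' @export
recovery_check <- function(theta_hat, epsilon) {
  stopifnot(inherits(theta_hat, "elca_params"), epsilon > 0, epsilon < 1)
  max(theta_hat$tau) > 1 - epsilon || min(theta_hat$a) > 1 - epsilon
}

#' Contingency table of two labelings
#'
#' Entry `(r, c)` counts observations with label `r` in the first labeling
#' and `c` in the second; entries sum to the number of observations.
#'
#' @param labels_a,labels_b integer label vectors of equal length.
#' @param n_a,n_b optional numbers of categories (default the observed max).
#' @return an integer matrix.
#' @export
contingency_table <- function(labels_a, labels_b, n_a = max(labels_a),
                              n_b = max(labels_b)) {
  labels_a <- as.integer(labels_a)
  labels_b <- as.integer(labels_b)
  stopifnot(length(labels_a) == length(labels_b))
  out <- matrix(0L, n_a, n_b)
  for (j in seq_along(labels_a)) {
    out[labels_a[j], labels_b[j]] <- out[labels_a[j], labels_b[j]] + 1L
  }
  out
}
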