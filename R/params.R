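#' ELCA model parameters
#'
#' Container for the parameters of the extended latent class analysis model
#' with `G` primary clusters and `K` size (additional) clusters:
#' mixing weights `pi` (length `G`) and `tau` (length `K`), size factors
#' `a` (length `K`, each in `(0, 1]`), and the `N x G` matrix `phi` of
#' per-vertex membership-profile probabilities. The probability that vertex
#' `i` belongs to a hyperedge from cluster pair `(g, k)` is `a[k] * phi[i, g]`.
#'
#' The representation is canonicalized on construction: `a` is sorted in
#' increasing order (jointly permuting `tau`), and if `a[K] != 1` the
#' likelihood-preserving rescaling `a -> a / a[K]`, `phi -> a[K] * phi` is
#' applied so that `a[K] == 1` exactly. This makes the representative of
#' each equivalence class of parameters unique, which is required for
#' identifiability and convenient for comparison.
#'
#' @param pi numeric probability vector of length `G` (sums to 1 within 1e-10).
#' @param tau numeric probability vector of length `K`.
#' @param a numeric vector of length `K` with entries in `(0, 1]`.
#' @param phi numeric `N x G` matrix with entries in `[0, 1]` such that every
#'   `a[k] * phi[i, g]` lies in `[0, 1]`.
#' @param vertex_names optional character vector of length `N`.
#' @param canonicalize logical; sort/rescale into canonical form (default TRUE).
#' @return an object of class `"elca_params"` with elements `G`, `K`, `N`,
#'   `pi`, `tau`, `a`, `phi`, `vertex_names`.
#' @examples
#' theta <- elca_params(pi = c(0.5, 0.5), tau = c(0.7, 0.3), a = c(0.4, 1),
#'                      phi = matrix(0.5, 4, 2))
#' @export
elca_params <- function(pi, tau, a, phi, vertex_names = NULL,
                        canonicalize = TRUE) {
  pi <- as.double(pi)
  tau <- as.double(tau)
  a <- as.double(a)
  phi <- as.matrix(phi)
  storage.mode(phi) <- "double"
  G <- length(pi)
  K <- length(tau)
  N <- nrow(phi)
  if (G < 1L || K < 1L || N < 1L) stop("G, K and N must all be >= 1")
  if (length(a) != K) stop("a and tau must have the same length K")
  if (ncol(phi) != G) stop("phi must have G columns")
  check_simplex(pi, "pi")
  check_simplex(tau, "tau")
  if (anyNA(a) || any(a <= 0) || any(a > 1)) stop("entries of a must lie in (0, 1]")
  if (anyNA(phi) || any(phi < 0) || any(phi > 1)) {
    stop("entries of phi must lie in [0, 1]")
  }
  if (canonicalize) {
    ord <- order(a)
    a <- a[ord]
    tau <- tau[ord]
    if (a[K] != 1) {
      phi <- phi * a[K]
      a <- a / a[K]
      a[K] <- 1
    }
  } else if (is.unsorted(a) || a[K] != 1) {
    stop("non-canonical parameters: a must be increasing with a[K] == 1")
  }
  if (max(a) * max(phi) > 1 + 1e-12) {
    stop("all products a[k] * phi[i, g] must lie in [0, 1]")
  }
  pi <- pi / sum(pi)
  tau <- tau / sum(tau)
  if (!is.null(vertex_names)) {
    vertex_names <- as.character(vertex_names)
    if (length(vertex_names) != N) stop("vertex_names must have length N")
  }
  dimnames(phi) <- NULL
  structure(list(G = G, K = K, N = N, pi = pi, tau = tau, a = a, phi = phi,
                 vertex_names = vertex_names),
            class = "elca_params")
}

check_simplex <- function(p, name) {
  if (anyNA(p) || any(p < 0)) stop(sprintf("%s must be nonnegative", name))
  if (abs(sum(p) - 1) > 1e-10) {
    stop(sprintf("%s must sum to 1 within 1e-10 (got %.12f)", name, sum(p)))
  }
  invisible(TRUE)
}

#' @export
print.elca_params <- function(x, ...) {
  cat(sprintf("ELCA parameters: N = %d vertices, G = %d primary, K = %d size cluster(s)\n",
              x$N, x$G, x$K))
  cat("pi : ", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  cat("tau: ", paste(sprintf("%.3f", x$tau), collapse = " "), "\n")
  cat("a  : ", paste(sprintf("%.3f", x$a), collapse = " "), "\n")
  invisible(x)
}

#' Standard latent class analysis parameters
#'
#' Container for a `G`-class LCA (independent-Bernoulli mixture) over `N`
#' binary manifest variables: mixing weights `pi` and the `N x G` matrix `p`
#' of conditional membership probabilities.
#'
#' @param pi numeric probability vector of length `G`.
#' @param p numeric `N x G` matrix with entries in `[0, 1]`.
#' @param vertex_names optional character vector of length `N`.
#' @return an object of class `"lca_params"`.
#' @export
lca_params <- function(pi, p, vertex_names = NULL) {
  pi <- as.double(pi)
  p <- as.matrix(p)
  storage.mode(p) <- "double"
  if (length(pi) != ncol(p)) stop("length(pi) must equal ncol(p)")
  check_simplex(pi, "pi")
  if (anyNA(p) || any(p < 0) || any(p > 1)) stop("entries of p must lie in [0, 1]")
  if (!is.null(vertex_names) && length(vertex_names) != nrow(p)) {
    stop("vertex_names must have length N")
  }
  dimnames(p) <- NULL
  structure(list(G = length(pi), N = nrow(p), pi = pi / sum(pi), p = p,
                 vertex_names = if (is.null(vertex_names)) NULL else as.character(vertex_names)),
            class = "lca_params")
}

#' @export
print.lca_params <- function(x, ...) {
  cat(sprintf("LCA parameters: N = %d variables, G = %d classes\n", x$N, x$G))
  cat("pi: ", paste(sprintf("%.3f", x$pi), collapse = " "), "\n")
  invisible(x)
}

#' Expand ELCA parameters to the equivalent standard LCA
#'
#' An ELCA model with `G` primary and `K` size clusters is a constrained LCA
#' with `G * K` classes: the class for pair `(g, k)` has mixing weight
#' `pi[g] * tau[k]` and conditional probabilities `a[k] * phi[, g]`. The
#' observed-data likelihood of the expansion is identical for every data set.
#' Classes are ordered by size cluster from largest factor (`a[K] = 1`)
#' down, primary cluster ascending within, so for `G = K = 2` the class
#' profiles are `phi[,1], phi[,2], a[1]*phi[,1], a[1]*phi[,2]`.
#'
#' @param theta an [elca_params()] object.
#' @return an [lca_params()] object with `G * K` classes.
#' @export
expand_to_lca <- function(theta) {
  stopifnot(inherits(theta, "elca_params"))
  ks <- rev(seq_len(theta$K))
  gs <- seq_len(theta$G)
  idx <- expand.grid(g = gs, k = ks)[, c("k", "g")]
  idx <- idx[order(match(idx$k, ks), idx$g), , drop = FALSE]
  w <- theta$tau[idx$k] * theta$pi[idx$g]
  p <- theta$phi[, idx$g, drop = FALSE] *
    matrix(theta$a[idx$k], theta$N, nrow(idx), byrow = TRUE)
  lca_params(pi = w, p = p, vertex_names = theta$vertex_names)
}

#' Number of free parameters
#'
#' For the ELCA model with `G` primary and `K` size clusters over `N`
#' vertices the count is `G*N + 2*(K - 1) + (G - 1)` (the profiles, the
#' free entries of `a` and `tau`, and the free entries of `pi`). For the
#' unconstrained LCA with `G * K` classes it is `G*K*N + (G*K - 1)`. The
#' two coincide at `K = 1`.
#'
#' @param G,K,N positive integers.
#' @param model `"elca"` or `"lca"` (for `"lca"` the class count is `G * K`).
#' @return a positive integer.
#' @export
n_parameters <- function(G, K, N, model = c("elca", "lca")) {
  model <- match.arg(model)
  stopifnot(G >= 1, K >= 1, N >= 1)
  if (model == "elca") {
    as.integer(G * N + 2 * (K - 1) + (G - 1))
  } else {
    as.integer(G * K * N + (G * K - 1))
  }
}

#' Matched LCA parameters with identical primary profiles
#'
#' The LCA model with `p[i, g] = phi[i, g] * sum_k a[k] * tau[k]` and the
#' same `pi` has the same per-cluster expected membership probabilities as
#' the ELCA model `theta`; hyperedge sizes then have equal means under both
#' models while the ELCA variance is at least as large (see
#' [exact_size_moments()]).
#'
#' @param theta an [elca_params()] object.
#' @return an [lca_params()] object with `G` classes.
#' @export
matched_lca_params <- function(theta) {
  stopifnot(inherits(theta, "elca_params"))
  s <- sum(theta$a * theta$tau)
  lca_params(pi = theta$pi, p = theta$phi * s, vertex_names = theta$vertex_names)
}

#' Read and write ELCA parameters as JSON
#'
#' The document stores `G`, `K`, `pi`, `tau`, `a`, `phi` (row-major list of
#' rows) and optional `vertex_names`, with floats at full precision so the
#' round trip is exact.
#'
#' @param theta an [elca_params()] object.
#' @param path file path.
#' @return `write_elca_params` returns `path` invisibly; `read_elca_params`
#'   returns an [elca_params()] object.
#' @export
write_elca_params <- function(theta, path) {
  stopifnot(inherits(theta, "elca_params"))
  doc <- list(G = theta$G, K = theta$K, pi = theta$pi, tau = theta$tau,
              a = theta$a,
              phi = lapply(seq_len(theta$N), function(i) theta$phi[i, ]))
  if (!is.null(theta$vertex_names)) doc$vertex_names <- theta$vertex_names
  # digits = I(17): 17 significant digits round-trip doubles exactly
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_elca_params
#' @export
read_elca_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  phi <- doc$phi
  if (is.list(phi)) phi <- do.call(rbind, phi)
  elca_params(pi = doc$pi, tau = doc$tau, a = doc$a, phi = phi,
              vertex_names = doc$vertex_names)
}
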