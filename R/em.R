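#' E-step: joint posterior responsibilities
#'
#' Computes, for every hyperedge `j` and cluster pair `(g, k)`, the
#' posterior probability that the hyperedge carries primary label `g` and
#' size label `k` under the current parameters (the ratio of the weighted
#' component probability to the per-hyperedge normalizing constant). The
#' log normalizing constants summed over hyperedges (with multiplicity
#' weights) equal the observed-data log-likelihood, which is returned
#' alongside.
#'
#' @param X an [incidence_matrix()].
#' @param theta an [elca_params()] object.
#' @return a list with `z` (an `M x G x K` array, each `z[j, , ]` summing
#'   to 1) and `loglik` (scalar).
#' @export
e_step <- function(X, theta) {
  stopifnot(inherits(X, "incidence_matrix"), inherits(theta, "elca_params"))
  if (n_vertices(X) != theta$N) stop("X and theta disagree on N")
  cp <- component_probs(theta)
  L <- bernoulli_loglik_matrix(X$x, cp$p)
  L <- sweep(L, 2L, cp$logw, "+")
  lse <- row_logsumexp(L)
  bad <- which(!is.finite(lse))
  if (length(bad) > 0L) {
    stop(sprintf("hyperedge '%s' has zero probability under every (g, k) pair",
                 X$hyperedge_ids[bad[1L]]))
  }
  z <- exp(L - lse)
  list(z = array(z, dim = c(nrow(L), theta$G, theta$K)),
       loglik = sum(X$weights * lse))
}

#' MM update for a single phi entry
#'
#' One minorization-maximization step for a membership-profile probability.
#' The surrogate (the concave `log(1 - a_k phi)` terms for `k < K` replaced
#' by their quadratic minorizers at `phi_old`, curvature `-a_k^2/(1-a_k)^2`)
#' is `Q_lower(phi) = A1 log(phi) + A2 log(1 - phi) + B1 phi +
#' B2 (phi - phi_old)^2`, whose stationary point solves the cubic
#' `phi^3 - (2 B2 - C)/(2 B2) phi^2 - (C - A1 - A2)/(2 B2) phi - A1/(2 B2) = 0`
#' with `C = B1 - 2 B2 phi_old`. Because `A1, A2 >= 0` and `B2 <= 0` the
#' surrogate is concave, so the maximizer over `[floor, 1 - floor]` is
#' unique; all real roots of the cubic inside the interval together with
#' the interval bounds and `phi_old` form the candidate set and the
#' candidate with the largest `Q_lower` is returned, preserving the MM
#' ascent guarantee. All arguments may be vectors (entrywise updates).
#'
#' @param A1 weighted occurrence mass `sum_{j,k} zhat[j,g,k] x[i,j]` (`>= 0`).
#' @param A2 weighted non-occurrence mass in the top size cluster
#'   `sum_j zhat[j,g,K] (1 - x[i,j])` (`>= 0`).
#' @param B1 linear minorizer coefficient (sum over `k < K`, `<= 0`).
#' @param B2 quadratic minorizer coefficient (sum over `k < K`, `<= 0`).
#' @param phi_old current value of the entry.
#' @param floor clamp bound; updates lie in `[floor, 1 - floor]`.
#' @return updated value(s) of phi.
#' @export
mm_phi_update <- function(A1, A2, B1, B2, phi_old, floor = 1e-6) {
  n <- max(length(A1), length(A2), length(B1), length(B2), length(phi_old))
  A1 <- rep_len(A1, n); A2 <- rep_len(A2, n)
  B1 <- rep_len(B1, n); B2 <- rep_len(B2, n)
  phi_old <- rep_len(phi_old, n)
  lo <- floor
  hi <- 1 - floor
  C <- B1 - 2 * B2 * phi_old

  roots <- matrix(NA_real_, n, 3L)
  cub <- which(B2 < 0)
  if (length(cub) > 0L) {
    b2 <- -(2 * B2[cub] - C[cub]) / (2 * B2[cub])
    b1 <- -(C[cub] - A1[cub] - A2[cub]) / (2 * B2[cub])
    b0 <- -A1[cub] / (2 * B2[cub])
    roots[cub, ] <- cubic_roots(b2, b1, b0)
  }
  quad <- which(B2 == 0)
  if (length(quad) > 0L) {
    # stationarity A1/phi - A2/(1-phi) + C = 0, i.e.
    # C phi^2 - (C - A1 - A2) phi - A1 = 0
    cc <- C[quad]
    disc <- (cc - A1[quad] - A2[quad])^2 + 4 * cc * A1[quad]
    has <- cc != 0 & disc >= 0
    sq <- sqrt(pmax(disc, 0))
    r1 <- ifelse(has, ((cc - A1[quad] - A2[quad]) + sq) / (2 * cc), NA_real_)
    r2 <- ifelse(has, ((cc - A1[quad] - A2[quad]) - sq) / (2 * cc), NA_real_)
    lin <- cc == 0 & (A1[quad] + A2[quad]) > 0
    r1[lin] <- A1[quad][lin] / (A1[quad][lin] + A2[quad][lin])
    roots[quad, 1:2] <- cbind(r1, r2)
  }

  cand <- cbind(roots, lo, hi, phi_old)
  cand[!is.na(cand) & (cand < lo | cand > hi)] <- NA_real_
  qval <- matrix(-Inf, n, ncol(cand))
  for (cc in seq_len(ncol(cand))) {
    ok <- !is.na(cand[, cc])
    qval[ok, cc] <- q_lower_phi(cand[ok, cc], A1[ok], A2[ok],
                                B1[ok], B2[ok], phi_old[ok])
  }
  best <- max.col(qval, ties.method = "first")
  out <- cand[cbind(seq_len(n), best)]
  # no admissible candidate can only mean all-NA pathological input
  out[!is.finite(out)] <- phi_old[!is.finite(out)]
  pmin(pmax(out, lo), hi)
}

# Surrogate objective for the phi update; all arguments broadcast to the
# length of `x` (0 * log(0) treated as 0).
q_lower_phi <- function(x, A1, A2, B1, B2, phi_old) {
  n <- length(x)
  A1 <- rep_len(A1, n); A2 <- rep_len(A2, n)
  B1 <- rep_len(B1, n); B2 <- rep_len(B2, n)
  phi_old <- rep_len(phi_old, n)
  ifelse(A1 > 0, A1 * log(x), 0) + ifelse(A2 > 0, A2 * log1p(-x), 0) +
    B1 * x + B2 * (x - phi_old)^2
}

# Real roots of x^3 + b2 x^2 + b1 x + b0 = 0, vectorized; NA-padded columns.
cubic_roots <- function(b2, b1, b0) {
  n <- length(b2)
  out <- matrix(NA_real_, n, 3L)
  p <- b1 - b2^2 / 3
  q <- 2 * b2^3 / 27 - b2 * b1 / 3 + b0
  disc <- (q / 2)^2 + (p / 3)^3
  shift <- -b2 / 3
  one <- which(disc > 0)
  if (length(one) > 0L) {
    s <- sqrt(disc[one])
    cbrt <- function(v) sign(v) * abs(v)^(1 / 3)
    out[one, 1L] <- cbrt(-q[one] / 2 + s) + cbrt(-q[one] / 2 - s) + shift[one]
  }
  three <- which(disc <= 0)
  if (length(three) > 0L) {
    pp <- p[three]
    r <- sqrt(pmax(-pp / 3, 0))
    # triple/degenerate root when p ~ 0
    cosarg <- ifelse(r > 0, 3 * q[three] / (2 * pp * r), 1)
    cosarg <- pmin(pmax(cosarg, -1), 1)
    th <- acos(cosarg)
    for (m in 0:2) {
      out[three, m + 1L] <- 2 * r * cos(th / 3 - 2 * pi * m / 3) + shift[three]
    }
  }
  out
}

#' MM update for a size factor a_k
#'
#' One minorization-maximization step for a size factor with `k < K`
#' (`a[K]` is pinned at 1 by the identifiability constraint). The surrogate
#' is `Q_lower(a) = A log(a) + B a + C (a - a_old)^2` with `A >= 0` and
#' `B, C <= 0` (curvature `-phi^2/(1-phi)^2` from the quadratic minorizer
#' of `log(1 - a phi)` at `a_old`); its stationary point has the closed
#' form `a_hat = sqrt(E + D^2/4) - D/2` with `D = B/(2C) - a_old` and
#' `E = -A/(2C)`. The result is clamped to `[floor, 1 - floor]`; because
#' the surrogate is concave the clamped value still maximizes it over the
#' interval. Degenerate `C = 0` (no non-membership mass) falls back to the
#' maximizer of the remaining terms. Arguments may be vectors.
#'
#' @param A weighted occurrence mass attributed to size cluster `k` (`>= 0`).
#' @param B linear minorizer coefficient (`<= 0`).
#' @param C quadratic minorizer coefficient (`<= 0`).
#' @param a_old current value of the factor.
#' @param floor clamp bound.
#' @return updated value(s) of a.
#' @export
mm_a_update <- function(A, B, C, a_old, floor = 1e-6) {
  n <- max(length(A), length(B), length(C), length(a_old))
  A <- rep_len(A, n); B <- rep_len(B, n)
  C <- rep_len(C, n); a_old <- rep_len(a_old, n)
  out <- numeric(n)
  neg <- C < 0
  if (any(neg)) {
    D <- B[neg] / (2 * C[neg]) - a_old[neg]
    E <- -A[neg] / (2 * C[neg])
    out[neg] <- sqrt(pmax(E + D^2 / 4, 0)) - D / 2
  }
  if (any(!neg)) {
    # C == 0: maximize A log(a) + B a on (0, 1]
    Az <- A[!neg]
    Bz <- B[!neg]
    out[!neg] <- ifelse(Bz < 0 & Az > 0, -Az / Bz,
                        ifelse(Bz < 0 & Az == 0, floor, 1 - floor))
  }
  pmin(pmax(out, floor), 1 - floor)
}

q_lower_a <- function(x, A, B, C, a_old) {
  n <- length(x)
  A <- rep_len(A, n); B <- rep_len(B, n)
  C <- rep_len(C, n); a_old <- rep_len(a_old, n)
  ifelse(A > 0, A * log(x), 0) + B * x + C * (x - a_old)^2
}

#' Conditional maximization sweeps for phi and a
#'
#' `cm_step_phi` performs one MM sweep over every entry of the profile
#' matrix `phi` (all vertices and primary clusters) against fixed
#' responsibilities `z`; `cm_step_a` sweeps the free size factors
#' `a[1], ..., a[K-1]`. Both assemble the sufficient statistics of the
#' respective surrogate from the responsibilities (multiplicity weights
#' respected) and delegate to [mm_phi_update()] / [mm_a_update()].
#'
#' @param X an [incidence_matrix()].
#' @param z an `M x G x K` responsibility array from [e_step()].
#' @param theta current [elca_params()].
#' @param floor clamp bound for updated parameters.
#' @return `cm_step_phi`: an `N x G` matrix; `cm_step_a`: a length-`K`
#'   vector with final element 1.
#' @export
cm_step_phi <- function(X, z, theta, floor = 1e-6) {
  G <- theta$G
  K <- theta$K
  xmat <- X$x
  notx <- 1 - xmat
  zw <- z * X$weights
  phi_new <- theta$phi
  ak <- theta$a
  for (g in seq_len(G)) {
    Zg <- matrix(zw[, g, ], ncol = K)
    A1 <- as.vector(xmat %*% rowSums(Zg))
    A2 <- as.vector(notx %*% Zg[, K])
    if (K > 1L) {
      W <- notx %*% Zg[, -K, drop = FALSE]              # N x (K-1)
      phig <- theta$phi[, g]
      B1 <- numeric(theta$N)
      B2 <- numeric(theta$N)
      for (k in seq_len(K - 1L)) {
        B1 <- B1 + W[, k] * (-ak[k] / (1 - ak[k] * phig))
        B2 <- B2 + W[, k] * (-0.5 * ak[k]^2 / (1 - ak[k])^2)
      }
    } else {
      B1 <- B2 <- numeric(theta$N)
    }
    phi_new[, g] <- mm_phi_update(A1, A2, B1, B2, theta$phi[, g], floor)
  }
  phi_new
}

#' @rdname cm_step_phi
#' @export
cm_step_a <- function(X, z, theta, floor = 1e-6) {
  K <- theta$K
  if (K == 1L) return(theta$a)
  xmat <- X$x
  notx <- 1 - xmat
  zw <- z * X$weights
  sizes <- colSums(xmat)
  phi <- clamp_prob(theta$phi, floor)
  Vc <- crossprod(notx, -0.5 * phi^2 / (1 - phi)^2)     # M x G, k-independent
  a_new <- theta$a
  for (k in seq_len(K - 1L)) {
    Zk <- matrix(zw[, , k], ncol = theta$G)
    A <- sum(rowSums(Zk) * sizes)
    Vb <- crossprod(notx, -phi / (1 - a_new[k] * phi))  # M x G
    B <- sum(Zk * Vb)
    C <- sum(Zk * Vc)
    a_new[k] <- mm_a_update(A, B, C, a_new[k], floor)
  }
  a_new
}

#' Conditional maximization for the mixing weights
#'
#' Lagrange-multiplier updates: `pi_g` is proportional to the total
#' responsibility mass of primary cluster `g` (summed over hyperedges,
#' with multiplicity weights, and size clusters), and `tau_k` analogously
#' with the roles of the two labels exchanged.
#'
#' @param z an `M x G x K` responsibility array.
#' @param weights optional per-hyperedge multiplicities (default all 1).
#' @return a probability vector (length `G` for `cm_step_pi`, `K` for
#'   `cm_step_tau`).
#' @export
cm_step_pi <- function(z, weights = NULL) {
  zw <- if (is.null(weights)) z else z * weights
  p <- apply(zw, 2L, sum)
  p / sum(p)
}

#' @rdname cm_step_pi
#' @export
cm_step_tau <- function(z, weights = NULL) {
  zw <- if (is.null(weights)) z else z * weights
  p <- apply(zw, 3L, sum)
  p / sum(p)
}

#' Fitting control settings
#'
#' @param n_restarts number of random initializations (best final
#'   log-likelihood wins; ties within 1e-9 go to the lowest restart index).
#' @param max_iter maximum number of outer ECM cycles per restart.
#' @param tol relative log-likelihood change declaring convergence.
#' @param mm_iter inner MM sweeps per conditional maximization of phi and a.
#' @param seed base seed; restart `r` uses `seed + r - 1`.
#' @param floor clamp bound keeping parameters away from 0 and 1 (the MM
#'   curvatures involve `(1 - a)^-2` and `(1 - phi)^-2`).
#' @param verbose log per-restart progress to standard error.
#' @return a list of class `"elca_control"`.
#' @export
elca_control <- function(n_restarts = 10L, max_iter = 1000L, tol = 1e-8,
                         mm_iter = 2L, seed = 1L, floor = 1e-6,
                         verbose = FALSE) {
  stopifnot(n_restarts >= 1, max_iter >= 1, tol > 0, mm_iter >= 1, floor > 0)
  structure(list(n_restarts = as.integer(n_restarts),
                 max_iter = as.integer(max_iter), tol = tol,
                 mm_iter = as.integer(mm_iter), seed = as.integer(seed),
                 floor = floor, verbose = isTRUE(verbose)),
            class = "elca_control")
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Random starting parameters
#'
#' Draws `pi` and `tau` from the flat Dirichlet distribution, `phi` entries
#' uniformly on `(0.2, 0.8)`, and the free size factors from `Uniform(0.2, 1)`
#' sorted increasingly with `a[K] = 1`. Deterministic given `seed`.
#'
#' @param X an [incidence_matrix()], or an integer number of vertices.
#' @param G,K numbers of primary and size clusters.
#' @param seed integer seed.
#' @return an [elca_params()] object.
#' @export
elca_init <- function(X, G, K, seed = 1L) {
  N <- if (inherits(X, "incidence_matrix")) n_vertices(X) else as.integer(X)
  with_seed(seed, {
    pi <- rdirichlet_flat(G)
    tau <- rdirichlet_flat(K)
    a <- if (K > 1L) c(sort(stats::runif(K - 1L, 0.2, 1)), 1) else 1
    phi <- matrix(stats::runif(N * G, 0.2, 0.8), N, G)
    elca_params(pi = pi, tau = tau, a = a, phi = phi)
  })
}

rdirichlet_flat <- function(n) {
  g <- stats::rexp(n)
  g / sum(g)
}

#' Fit the ELCA model by ECM with MM inner steps
#'
#' Alternates an E-step (joint responsibilities, Bayes' rule over all
#' `(g, k)` pairs) with conditional maximizations: `mm_iter` MM sweeps over
#' all of `phi`, then over the free size factors `a`, then closed-form
#' updates of `pi` and `tau`, each against the cycle's single E-step.
#' Every conditional step maximizes a minorizer of the expected
#' complete-data log-likelihood, so the observed log-likelihood is
#' non-decreasing across cycles. After each cycle the representation is
#' re-canonicalized (`a` sorted increasingly with `tau` permuted along).
#' Duplicate hyperedges are collapsed internally and handled by weights;
#' returned responsibilities cover the original columns.
#'
#' @param X an [incidence_matrix()].
#' @param G,K numbers of primary and size clusters.
#' @param control an [elca_control()] list.
#' @param init optional [elca_params()] used as the single starting point
#'   (random restarts are skipped).
#' @return an object of class `"elca_fit"`: `params`, `loglik`,
#'   `loglik_trace`, `bic`, `responsibilities` (`M x G x K`), `converged`,
#'   `n_iterations`, `restart_logliks`, `G`, `K`.
#' @examples
#' theta <- study_params("g2k2", N = 10)
#' sim <- simulate_elca(theta, M = 100, seed = 7)
#' fit <- elca_fit(sim$X, G = 2, K = 2, control = elca_control(n_restarts = 2))
#' @export
elca_fit <- function(X, G, K, control = elca_control(), init = NULL) {
  stopifnot(inherits(X, "incidence_matrix"))
  G <- as.integer(G)
  K <- as.integer(K)
  if (is.na(G) || is.na(K) || G < 1L || K < 1L) stop("G and K must be integers >= 1")
  Xd <- deduplicate_hyperedges(X)
  map <- attr(Xd, "column_map")
  m_eff <- sum(Xd$weights)
  if (all(Xd$x == 0)) {
    warning("all hyperedges are empty; phi will be driven to the floor")
  }
  if (G * K > m_eff) {
    warning("G * K exceeds the number of hyperedges; BIC will be unreliable")
  }
  starts <- if (!is.null(init)) {
    stopifnot(inherits(init, "elca_params"))
    if (init$G != G || init$K != K || init$N != n_vertices(X)) {
      stop("init has incompatible dimensions")
    }
    list(init)
  } else {
    lapply(seq_len(control$n_restarts),
           function(r) elca_init(Xd, G, K, seed = control$seed + r - 1L))
  }
  runs <- vector("list", length(starts))
  for (r in seq_along(starts)) {
    runs[[r]] <- run_ecm(Xd, starts[[r]], control)
    if (control$verbose) {
      message(sprintf("restart %d/%d: loglik %.6f after %d iteration(s)%s",
                      r, length(starts), runs[[r]]$loglik, runs[[r]]$n_iter,
                      if (runs[[r]]$converged) "" else " (not converged)"))
    }
  }
  finals <- vapply(runs, `[[`, numeric(1L), "loglik")
  best <- which(finals > max(finals) - 1e-9)[1L]
  run <- runs[[best]]
  fit_bic <- bic(run$loglik, G = G, K = K, N = n_vertices(X), M = m_eff)
  structure(list(params = run$theta, loglik = run$loglik,
                 loglik_trace = run$trace, bic = fit_bic,
                 responsibilities = run$z[map, , , drop = FALSE],
                 converged = run$converged, n_iterations = run$n_iter,
                 restart_logliks = finals, G = G, K = K,
                 hyperedge_ids = X$hyperedge_ids,
                 vertex_names = X$vertex_names),
            class = "elca_fit")
}

run_ecm <- function(X, theta, control) {
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  es <- NULL
  for (it in seq_len(control$max_iter)) {
    es <- e_step(X, theta)
    trace <- c(trace, es$loglik)
    if (it > 1L &&
        abs(es$loglik - ll_prev) / (abs(ll_prev) + 1) < control$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- es$loglik
    for (s in seq_len(control$mm_iter)) {
      theta$phi <- cm_step_phi(X, es$z, theta, floor = control$floor)
    }
    if (theta$K > 1L) {
      for (s in seq_len(control$mm_iter)) {
        theta$a <- cm_step_a(X, es$z, theta, floor = control$floor)
      }
    }
    theta$pi <- floor_simplex(cm_step_pi(es$z, X$weights), control$floor)
    theta$tau <- floor_simplex(cm_step_tau(es$z, X$weights), control$floor)
    ord <- order(theta$a)
    if (is.unsorted(theta$a)) {
      theta$a <- theta$a[ord]
      theta$tau <- theta$tau[ord]
    }
  }
  if (!converged) {
    es <- e_step(X, theta)
    trace <- c(trace, es$loglik)
  }
  list(theta = theta, trace = trace, loglik = trace[length(trace)],
       z = es$z, converged = converged, n_iter = length(trace))
}

floor_simplex <- function(p, floor) {
  p <- pmax(p, floor)
  p / sum(p)
}

#' @export
print.elca_fit <- function(x, ...) {
  cat(sprintf("ELCA fit: G = %d, K = %d\n", x$G, x$K))
  cat(sprintf("log-likelihood %.4f, BIC %.4f, %d iteration(s)%s\n",
              x$loglik, x$bic, x$n_iterations,
              if (x$converged) "" else " (not converged)"))
  print(x$params)
  invisible(x)
}

#' Marginal posterior cluster probabilities of a fit
#'
#' Collapses the joint `M x G x K` responsibilities to the posterior over
#' primary clusters (`margin = "primary"`, summing out `k`) or size
#' clusters (`margin = "additional"`, summing out `g`).
#'
#' @param fit an [elca_fit()] result.
#' @param margin `"primary"` or `"additional"`.
#' @return an `M x G` or `M x K` matrix of posterior probabilities.
#' @export
posterior_marginals <- function(fit, margin = c("primary", "additional")) {
  margin <- match.arg(margin)
  z <- fit$responsibilities
  if (margin == "primary") {
    apply(z, c(1L, 2L), sum)
  } else {
    apply(z, c(1L, 3L), sum)
  }
}

#' Reference EM for the standard LCA model
#'
#' Classical closed-form EM for the `G`-class independent-Bernoulli
#' mixture: responsibilities by Bayes' rule, then `pi` as weighted
#' responsibility means and `p[i, g]` as responsibility-weighted means of
#' the data. Uses the same probability clamp, parameter floor, and
#' convergence rule as [elca_fit()], so an ELCA fit with `K = 1` started
#' from the same initialization reproduces its log-likelihood trace. Kept
#' as a separate closed-form code path (no MM surrogate machinery), which
#' makes it a useful cross-check and a baseline model for comparisons.
#'
#' @param X an [incidence_matrix()].
#' @param G number of classes.
#' @param control an [elca_control()] list (`mm_iter` is ignored).
#' @param init optional [lca_params()] starting point.
#' @return a list: `params` ([lca_params()]), `loglik`, `loglik_trace`,
#'   `bic`, `responsibilities` (`M x G`), `converged`, `n_iterations`.
#' @export
lca_fit_em <- function(X, G, control = elca_control(), init = NULL) {
  stopifnot(inherits(X, "incidence_matrix"))
  Xd <- deduplicate_hyperedges(X)
  map <- attr(Xd, "column_map")
  m_eff <- sum(Xd$weights)
  if (is.null(init)) {
    th <- elca_init(Xd, G, 1L, seed = control$seed)
    init <- lca_params(pi = th$pi, p = th$phi)
  }
  params <- init
  trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  resp <- NULL
  for (it in seq_len(control$max_iter)) {
    L <- bernoulli_loglik_matrix(Xd$x, params$p)
    L <- sweep(L, 2L, log(params$pi), "+")
    lse <- row_logsumexp(L)
    ll <- sum(Xd$weights * lse)
    trace <- c(trace, ll)
    resp <- exp(L - lse)
    if (it > 1L && abs(ll - ll_prev) / (abs(ll_prev) + 1) < control$tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    rw <- resp * Xd$weights
    cs <- colSums(rw)
    p_new <- sweep(Xd$x %*% rw, 2L, cs, "/")
    p_new <- pmin(pmax(p_new, control$floor), 1 - control$floor)
    params <- lca_params(pi = floor_simplex(cs / sum(cs), control$floor),
                         p = p_new)
  }
  if (!converged) {
    L <- bernoulli_loglik_matrix(Xd$x, params$p)
    L <- sweep(L, 2L, log(params$pi), "+")
    lse <- row_logsumexp(L)
    trace <- c(trace, sum(Xd$weights * lse))
    resp <- exp(L - lse)
  }
  list(params = params, loglik = trace[length(trace)], loglik_trace = trace,
       bic = -2 * trace[length(trace)] +
         n_parameters(G, 1L, n_vertices(X), "lca") * log(m_eff),
       responsibilities = resp[map, , drop = FALSE],
       converged = converged, n_iterations = length(trace))
}
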