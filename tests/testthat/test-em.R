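test_that("E-step responsibilities match Bayes' rule", {
  # fully symmetric model: uniform joint posterior
  th_sym <- elca_params(pi = c(0.5, 0.5), tau = c(0.5, 0.5), a = c(1, 1),
                        phi = matrix(0.3, 4, 2), canonicalize = FALSE)
  X <- incidence_matrix(matrix(rbinom(12, 1, 0.5), 4, 3))
  es <- e_step(X, th_sym)
  expect_equal(as.vector(es$z), rep(0.25, 12), tolerance = 1e-12)
  # one-vertex Bayes ratio: 0.45 / (0.45 + 0.05)
  th1 <- elca_params(pi = c(0.5, 0.5), tau = 1, a = 1,
                     phi = matrix(c(0.9, 0.1), 1, 2))
  es1 <- e_step(incidence_matrix(matrix(1, 1, 1)), th1)
  expect_equal(as.vector(es1$z), c(0.9, 0.1), tolerance = 1e-12)
  # random instances against brute-force arithmetic
  set.seed(21)
  for (rep in 1:30) {
    th <- random_theta(sample(2:6, 1), sample(1:3, 1), sample(1:3, 1))
    X <- random_incidence(th$N, sample(1:8, 1))
    es <- e_step(X, th)
    for (j in seq_len(n_hyperedges(X))) {
      expect_equal(matrix(es$z[j, , ], th$G, th$K),
                   brute_responsibilities(X$x[, j], th), tolerance = 1e-12)
    }
    expect_equal(es$loglik, brute_loglik(X, th), tolerance = 1e-10)
    # marginals are valid posteriors
    expect_equal(rowSums(apply(es$z, c(1, 2), sum)),
                 rep(1, n_hyperedges(X)), tolerance = 1e-10)
  }
})

test_that("phi update reduces to the LCA closed form at K = 1 and is floored at A1 = 0", {
  expect_equal(mm_phi_update(2, 3, 0, 0, 0.5), 0.4, tolerance = 1e-12)
  expect_equal(mm_phi_update(0, 3, 0, 0, 0.5), 1e-6)
  # direct maximization of the exact objective agrees at K = 1
  set.seed(22)
  for (rep in 1:20) {
    A1 <- rexp(1) * 4
    A2 <- rexp(1) * 4
    opt <- optimize(function(p) A1 * log(p) + A2 * log(1 - p),
                    c(1e-6, 1 - 1e-6), maximum = TRUE)$maximum
    expect_equal(mm_phi_update(A1, A2, 0, 0, 0.5), A1 / (A1 + A2),
                 tolerance = 1e-10)
    expect_equal(A1 / (A1 + A2), opt, tolerance = 1e-4)
  }
})

test_that("phi update maximizes the minorizer over a fine grid", {
  set.seed(23)
  floor_ <- 1e-6
  grid <- seq(floor_, 1 - floor_, by = 1e-4)
  for (rep in 1:100) {
    A1 <- rexp(1) * 5 * (runif(1) < 0.9)
    A2 <- rexp(1) * 5 * (runif(1) < 0.9)
    B1 <- -rexp(1) * 3
    B2 <- -rexp(1) * 5
    phi_t <- runif(1, 0.05, 0.95)
    out <- mm_phi_update(A1, A2, B1, B2, phi_t, floor_)
    q_out <- hyperlca:::q_lower_phi(out, A1, A2, B1, B2, phi_t)
    q_grid <- max(hyperlca:::q_lower_phi(grid, A1, A2, B1, B2, phi_t))
    expect_gte(q_out, q_grid - 1e-9)
    # ascent relative to the expansion point
    expect_gte(q_out, hyperlca:::q_lower_phi(phi_t, A1, A2, B1, B2, phi_t) - 1e-12)
  }
})

test_that("a update matches its closed form and the numeric maximizer", {
  # worked example: D = 0.5, E = 0.75, a_hat = sqrt(0.8125) - 0.25
  expect_equal(mm_a_update(1.5, -2, -1, 0.5), sqrt(0.8125) - 0.25,
               tolerance = 1e-12)
  # A = 0 with D >= 0 collapses to the floor
  expect_equal(mm_a_update(0, -1, -2, 0.1), 1e-6)
  set.seed(24)
  for (rep in 1:100) {
    A <- rexp(1) * 5 * (runif(1) < 0.9)
    B <- -rexp(1) * 3
    C <- -rexp(1) * 5
    a_t <- runif(1, 0.1, 0.9)
    out <- mm_a_update(A, B, C, a_t)
    D <- B / (2 * C) - a_t
    E <- -A / (2 * C)
    closed <- sqrt(E + D^2 / 4) - D / 2
    expect_equal(out, min(max(closed, 1e-6), 1 - 1e-6), tolerance = 1e-12)
    num <- optimize(function(a) hyperlca:::q_lower_a(a, A, B, C, a_t),
                    c(1e-6, 1 - 1e-6), maximum = TRUE)
    expect_gte(hyperlca:::q_lower_a(out, A, B, C, a_t), num$objective - 1e-7)
    expect_gte(hyperlca:::q_lower_a(out, A, B, C, a_t),
               hyperlca:::q_lower_a(a_t, A, B, C, a_t) - 1e-12)
  }
})

test_that("minorizers lie below the exact conditional objectives and touch at the expansion point", {
  set.seed(25)
  for (rep in 1:20) {
    th <- random_theta(4, 2, 2)
    X <- random_incidence(4, 12)
    es <- e_step(X, th)
    zw <- es$z
    i <- sample(4, 1); g <- sample(2, 1)
    phi_t <- th$phi[i, g]
    K <- th$K
    # exact conditional objective for phi_ig (terms of the expected
    # complete-data log-likelihood involving phi_ig)
    q_exact <- function(p) {
      tot <- 0
      for (j in seq_len(n_hyperedges(X))) {
        for (k in seq_len(K)) {
          tot <- tot + zw[j, g, k] *
            (X$x[i, j] * log(p) + (1 - X$x[i, j]) * log(1 - th$a[k] * p))
        }
      }
      tot
    }
    A1 <- sum(vapply(seq_len(K), function(k) sum(zw[, g, k] * X$x[i, ]), 0))
    A2 <- sum(zw[, g, K] * (1 - X$x[i, ]))
    B1 <- sum(vapply(seq_len(K - 1), function(k) {
      sum(zw[, g, k] * (1 - X$x[i, ])) * (-th$a[k] / (1 - th$a[k] * phi_t))
    }, 0))
    B2 <- sum(vapply(seq_len(K - 1), function(k) {
      sum(zw[, g, k] * (1 - X$x[i, ])) * (-0.5 * th$a[k]^2 / (1 - th$a[k])^2)
    }, 0))
    const <- q_exact(phi_t) -
      hyperlca:::q_lower_phi(phi_t, A1, A2, B1, B2, phi_t)
    for (p in seq(0.05, 0.95, by = 0.09)) {
      expect_lte(hyperlca:::q_lower_phi(p, A1, A2, B1, B2, phi_t) + const,
                 q_exact(p) + 1e-10)
    }
  }
})

test_that("mixing-weight updates are responsibility frequencies and match numeric optimization", {
  m <- 10
  z_unif <- array(1 / 6, dim = c(m, 3, 2))
  expect_equal(cm_step_pi(z_unif), rep(1 / 3, 3), tolerance = 1e-12)
  expect_equal(cm_step_tau(z_unif), rep(1 / 2, 2), tolerance = 1e-12)
  # hard assignments: plain frequencies
  z_hard <- array(0, dim = c(10, 2, 2))
  z_hard[1:8, 1, 1] <- 1
  z_hard[9:10, 2, 2] <- 1
  expect_equal(cm_step_pi(z_hard), c(0.8, 0.2))
  expect_equal(cm_step_tau(z_hard), c(0.8, 0.2))
  # random responsibilities: agreement with constrained numeric maximization
  # of sum_j sum_g sum_k z log pi_g over the simplex (via softmax chart)
  set.seed(26)
  z <- array(rexp(10 * 3 * 2), dim = c(10, 3, 2))
  z <- z / array(rep(apply(z, 1, sum), 6), dim = dim(z))
  mass <- apply(z, 2, sum)
  obj <- function(eta) {
    p <- exp(c(eta, 0)); p <- p / sum(p)
    -sum(mass * log(p))
  }
  opt <- optim(c(0, 0), obj, method = "BFGS")
  p_opt <- exp(c(opt$par, 0)); p_opt <- p_opt / sum(p_opt)
  expect_equal(cm_step_pi(z), p_opt, tolerance = 1e-5)
})

test_that("fitting data from a single Bernoulli profile recovers row means immediately", {
  set.seed(27)
  X <- random_incidence(6, 200, p = 0.35)
  fit <- elca_fit(X, 1, 1, control = elca_control(n_restarts = 1, seed = 3))
  expect_equal(as.vector(fit$params$phi), rowMeans(X$x), tolerance = 1e-9)
  expect_equal(fit$params$pi, 1)
  expect_true(fit$converged)
})

test_that("observed log-likelihood ascends across ECM cycles on random instances", {
  set.seed(28)
  for (rep in 1:25) {
    th <- random_theta(sample(3:8, 1), sample(1:2, 1), sample(1:2, 1))
    X <- simulate_elca(th, sample(20:60, 1), seed = rep)$X
    fit <- elca_fit(X, sample(1:3, 1), sample(1:3, 1),
                    control = elca_control(n_restarts = 1, max_iter = 40,
                                           seed = rep))
    expect_gte(min(diff(fit$loglik_trace)), -1e-8)
  }
})

test_that("K = 1 fits reproduce the closed-form LCA EM trace", {
  set.seed(29)
  for (rep in 1:5) {
    th_true <- study_params("lca_g2", N = 8)
    X <- simulate_elca(th_true, 100, seed = 100 + rep)$X
    init <- elca_init(X, 2, 1, seed = rep)
    ctl <- elca_control(max_iter = 200, tol = 1e-8, seed = rep)
    f_elca <- elca_fit(X, 2, 1, control = ctl, init = init)
    f_lca <- lca_fit_em(X, 2, control = ctl,
                        init = lca_params(init$pi, init$phi))
    expect_equal(length(f_elca$loglik_trace), length(f_lca$loglik_trace))
    expect_equal(f_elca$loglik_trace, f_lca$loglik_trace, tolerance = 1e-9)
  }
})

test_that("initialization is deterministic, canonical, and respects K = 1", {
  i1 <- elca_init(12, 3, 2, seed = 77)
  i2 <- elca_init(12, 3, 2, seed = 77)
  expect_identical(i1, i2)
  expect_equal(i1$a[i1$K], 1)
  expect_false(is.unsorted(i1$a))
  expect_equal(sum(i1$pi), 1, tolerance = 1e-12)
  i3 <- elca_init(5, 2, 1, seed = 1)
  expect_equal(i3$a, 1)
  expect_equal(i3$tau, 1)
  expect_true(all(i3$phi > 0.2 & i3$phi < 0.8))
})

test_that("converged fits are stationary points of the observed log-likelihood", {
  set.seed(30)
  th <- study_params("g2k2", N = 6)
  X <- simulate_elca(th, 150, seed = 9)$X
  fit <- elca_fit(X, 2, 2, control = elca_control(n_restarts = 2, tol = 1e-12,
                                                  max_iter = 3000, seed = 4))
  p <- fit$params
  h <- 1e-6
  # free phi coordinates (interior only)
  for (probe in list(c(1, 1), c(3, 2), c(6, 1))) {
    v <- p$phi[probe[1], probe[2]]
    if (v < 1e-4 || v > 1 - 1e-4) next
    up <- p; up$phi[probe[1], probe[2]] <- v + h
    dn <- p; dn$phi[probe[1], probe[2]] <- v - h
    grad <- (elca_loglik(X, up) - elca_loglik(X, dn)) / (2 * h)
    expect_lt(abs(grad), 1e-3)
  }
  # simplex direction for pi: move mass between the two clusters
  up <- p; up$pi <- p$pi + c(h, -h)
  dn <- p; dn$pi <- p$pi - c(h, -h)
  grad_pi <- (elca_loglik(X, up) - elca_loglik(X, dn)) / (2 * h)
  expect_lt(abs(grad_pi), 1e-3)
})

test_that("degenerate inputs are handled with warnings", {
  set.seed(31)
  X0 <- incidence_matrix(matrix(0, 4, 6))
  expect_warning(fit <- elca_fit(X0, 1, 1,
                                 control = elca_control(n_restarts = 1)),
                 "empty")
  expect_true(all(fit$params$phi <= 1e-5))
  Xs <- random_incidence(3, 4)
  expect_warning(elca_fit(Xs, 3, 2, control = elca_control(n_restarts = 1,
                                                           max_iter = 5)),
                 "BIC")
})
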