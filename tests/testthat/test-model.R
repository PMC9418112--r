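test_that("single-hyperedge log-probability matches direct computation", {
  th <- elca_params(pi = 1, tau = 1, a = 1, phi = matrix(0.5, 1, 1))
  expect_equal(hyperedge_log_prob(1, th), log(0.5), tolerance = 1e-12)
  th2 <- elca_params(pi = c(0.5, 0.5), tau = 1, a = 1,
                     phi = cbind(c(1, 0), c(0, 1)))
  # component 1 generates (1,0) with probability 1, component 2 never does
  expect_equal(hyperedge_log_prob(c(1, 0), th2), log(0.5), tolerance = 1e-9)
  set.seed(5)
  for (rep in 1:20) {
    th3 <- random_theta(3, 2, 2)
    x <- rbinom(3, 1, 0.5)
    expect_equal(hyperedge_log_prob(x, th3), log(brute_column_prob(x, th3)),
                 tolerance = 1e-12)
  }
})

test_that("log-likelihood is additive over columns and permutation invariant", {
  set.seed(6)
  th <- random_theta(4, 2, 2)
  x <- rbinom(4, 1, 0.5)
  X <- incidence_matrix(matrix(x, 4, 5))
  expect_equal(elca_loglik(X, th), 5 * hyperedge_log_prob(x, th),
               tolerance = 1e-10)
  Xr <- random_incidence(4, 20)
  perm <- sample(20)
  Xp <- incidence_matrix(Xr$x[, perm])
  expect_equal(elca_loglik(Xp, th), elca_loglik(Xr, th), tolerance = 1e-10)
})

test_that("ELCA with K = 1 is exactly the standard LCA", {
  set.seed(7)
  th <- random_theta(6, 3, 1)
  X <- random_incidence(6, 30)
  expect_equal(elca_loglik(X, th), lca_loglik(X, lca_params(th$pi, th$phi)),
               tolerance = 1e-12)
})

test_that("G x K expansion preserves the likelihood and orders profiles as documented", {
  # the K = 1 expansion is the identity
  set.seed(8)
  th1 <- random_theta(4, 2, 1)
  ex1 <- expand_to_lca(th1)
  expect_equal(ex1$pi, th1$pi)
  expect_equal(ex1$p, th1$phi)
  # G = 2, K = 2: profiles (phi_1, phi_2, a1 phi_1, a1 phi_2)
  th2 <- random_theta(5, 2, 2)
  ex2 <- expand_to_lca(th2)
  expect_equal(ex2$p,
               cbind(th2$phi[, 1], th2$phi[, 2],
                     th2$a[1] * th2$phi[, 1], th2$a[1] * th2$phi[, 2]),
               tolerance = 1e-14)
  expect_equal(ex2$pi,
               c(th2$tau[2] * th2$pi, th2$tau[1] * th2$pi), tolerance = 1e-14)
  # likelihood equality on 100 random instances (also vs brute force)
  for (rep in 1:100) {
    N <- sample(2:8, 1)
    th <- random_theta(N, sample(1:3, 1), sample(1:3, 1))
    X <- random_incidence(N, sample(1:20, 1))
    ll <- elca_loglik(X, th)
    expect_equal(ll, lca_loglik(X, expand_to_lca(th)), tolerance = 1e-10)
    if (rep <= 10) expect_equal(ll, brute_loglik(X, th), tolerance = 1e-10)
  }
})

test_that("rescaling a and phi jointly leaves the likelihood invariant and canonicalizes", {
  set.seed(9)
  for (rep in 1:20) {
    th <- random_theta(5, 2, 2)
    X <- random_incidence(5, 15)
    C <- runif(1, max(th$phi), 1)  # keeps C * a <= 1 and phi / C <= 1
    scaled <- elca_params(pi = th$pi, tau = th$tau, a = C * th$a,
                          phi = th$phi / C)
    # canonical form restores the representative exactly
    expect_equal(scaled$a, th$a, tolerance = 1e-12)
    expect_equal(scaled$phi, th$phi, tolerance = 1e-12)
    expect_equal(elca_loglik(X, scaled), elca_loglik(X, th), tolerance = 1e-10)
  }
  # unsorted a is sorted jointly with tau
  th <- elca_params(pi = 1, tau = c(0.7, 0.3), a = c(1, 0.5),
                    phi = matrix(0.4, 3, 1))
  expect_equal(th$a, c(0.5, 1))
  expect_equal(th$tau, c(0.3, 0.7))
})

test_that("hyperedge probabilities sum to one over the full outcome space", {
  set.seed(10)
  for (N in c(3, 6, 9)) {
    th <- random_theta(N, 2, 2)
    grid <- as.matrix(expand.grid(rep(list(0:1), N)))
    total <- sum(vapply(seq_len(nrow(grid)), function(r) {
      exp(hyperedge_log_prob(grid[r, ], th))
    }, numeric(1)))
    expect_equal(total, 1, tolerance = 1e-9)
  }
})

test_that("complete-data log-likelihood marginalizes to the observed one", {
  set.seed(12)
  th <- random_theta(4, 2, 3)
  X <- random_incidence(4, 5)
  # single hyperedge, G = K = 1 equals the marginal log-probability
  th11 <- random_theta(4, 1, 1)
  X1 <- incidence_matrix(matrix(X$x[, 1], ncol = 1))
  expect_equal(complete_data_loglik(X1, 1L, 1L, th11),
               hyperedge_log_prob(X$x[, 1], th11), tolerance = 1e-12)
  # enumerate all (z1, z2) assignments per hyperedge: logsumexp equals observed
  m <- n_hyperedges(X)
  combos <- expand.grid(g = seq_len(th$G), k = seq_len(th$K))
  per_edge <- matrix(NA_real_, m, nrow(combos))
  for (cc in seq_len(nrow(combos))) {
    for (j in seq_len(m)) {
      Xj <- incidence_matrix(matrix(X$x[, j], ncol = 1))
      per_edge[j, cc] <- complete_data_loglik(Xj, combos$g[cc], combos$k[cc], th)
    }
  }
  lse <- apply(per_edge, 1, function(v) {
    m0 <- max(v); m0 + log(sum(exp(v - m0)))
  })
  expect_equal(sum(lse), elca_loglik(X, th), tolerance = 1e-10)
  # the maximizing hard assignment dominates every other assignment
  best <- apply(per_edge, 1, max)
  expect_true(all(best + 1e-12 >= per_edge))
  # malformed indicators are rejected
  z1_bad <- matrix(1, m, th$G)
  expect_error(complete_data_loglik(X, z1_bad, rep(1L, m), th), "exactly one")
})

test_that("parameter counts follow the printed formulas", {
  expect_identical(n_parameters(3, 2, 8, "elca"), 28L)
  expect_identical(n_parameters(3, 2, 8, "lca"), 53L)
  expect_identical(n_parameters(1, 1, 10, "elca"), 10L)
  # K = 1: both formulas coincide
  for (G in 1:4) {
    expect_identical(n_parameters(G, 1, 7, "elca"), n_parameters(G, 1, 7, "lca"))
  }
})

test_that("parameters round-trip exactly through JSON", {
  set.seed(13)
  th <- random_theta(6, 3, 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_elca_params(th, path)
  th2 <- read_elca_params(path)
  expect_identical(th2$pi, th$pi)
  expect_identical(th2$tau, th$tau)
  expect_identical(th2$a, th$a)
  expect_identical(th2$phi, th$phi)
})
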