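# hyperlca

Model-based clustering of hyperedges in binary hypergraph data via
**extended latent class analysis (ELCA)**, with an ECM/MM fitting
algorithm, BIC model selection, an exact simulator, evaluation metrics,
and a command-line interface.

## The problem and the model

Many interaction data sets are not pairwise: papers have any number of
coauthors, movie scenes any number of speaking characters, news articles
any number of mentioned countries. Such data form a *hypergraph*: `N`
vertices and `M` hyperedges, each hyperedge an arbitrary subset of the
vertices, recorded as an `N x M` binary incidence matrix `X` with
`x_ij = 1` iff vertex `i` belongs to hyperedge `j` (equivalently, a
two-mode / bipartite network). The scientific question addressed here is
clustering the *hyperedges* — which papers, scenes, or articles are of
the same kind — while properly accounting for the striking variation in
hyperedge *size* that real data show.

The classical tool for multivariate binary data is latent class analysis
(LCA): a `G`-component mixture in which a hyperedge from class `g`
contains vertex `i` independently with probability `p_ig`. LCA needs many
classes to fit hypergraph data well, because size variation and
composition get entangled, and its parameter count `G·N + (G − 1)` grows
quickly with the number of classes.

ELCA factorizes the class profile. Each hyperedge carries **two
independent labels**: a primary label `g ~ Categorical(π)` with vertex
profile `φ_·g`, and a size label `k ~ Categorical(τ)` with a scalar
factor `a_k ∈ (0, 1]`. Conditional on `(g, k)`, vertex `i` joins the
hyperedge independently with probability `a_k · φ_ig`, so the observed
likelihood is

```
L(X; θ) = ∏_j Σ_g Σ_k  π_g τ_k ∏_i (a_k φ_ig)^x_ij (1 − a_k φ_ig)^(1−x_ij)
```

with `θ = (π, τ, a, φ)`. The size factors are ranked increasingly with
`a_K = 1` for identifiability. ELCA is exactly a *constrained* LCA with
`G × K` classes whose profiles are proportional within groups, but with
only `G·N + 2(K−1) + (G−1)` parameters; at `K = 1` it **is** the standard
LCA. Size classes with small `a_k` generate systematically smaller
hyperedges, so the model decouples "what kind of hyperedge" from "how
large", and the size distribution of a random hyperedge has the same mean
as — but larger variance than — the profile-matched LCA, converging to a
`G × K` Poisson mixture as `N` grows.

Estimation is by an EM algorithm whose M-step is a sequence of
conditional maximizations (ECM): closed-form updates for `π` and `τ`, and
minorization–maximization (MM) steps for `φ` (a cubic-equation update)
and `a` (a closed-form quadratic update), each guaranteeing ascent of the
observed log-likelihood. `(G, K)` is chosen by BIC.

## Worked example

```r
library(hyperlca)

theta <- study_params("g2k2", N = 10)        # pi=(.5,.5), tau=(.5,.5), a=(0.4,1)
sim   <- simulate_elca(theta, M = 500, seed = 42)
fit   <- elca_fit(sim$X, G = 2, K = 2,
                  control = elca_control(n_restarts = 5, seed = 1))
print(fit)
#> ELCA fit: G = 2, K = 2
#> log-likelihood -2891.5672, BIC 5926.0705, 32 iteration(s)
#> ELCA parameters: N = 10 vertices, G = 2 primary, K = 2 size cluster(s)
#> pi :  0.540 0.460
#> tau:  0.525 0.475
#> a  :  0.402 1.000
```

The estimate recovers the generating structure: `a ≈ (0.40, 1)` means
roughly half the hyperedges (those with `k = 1`) are drawn with all
membership probabilities scaled down to 40%, i.e. they are systematically
smaller. Aligning the fitted clusters with the simulated labels:

```r
al1 <- align_labels(sim$labels$z1, posterior_marginals(fit, "primary"))
al2 <- align_labels(sim$labels$z2, posterior_marginals(fit, "additional"))
c(mis1 = al1$rate, mis2 = al2$rate)
#>  mis1  mis2
#> 0.086 0.120
```

so 8.6% of hyperedges are assigned to the wrong primary cluster and 12%
to the wrong size cluster (the Bayes-optimal rates are nonzero: the two
layers overlap). BIC selection over a grid lands on the truth:

```r
select_model(sim$X, 1:3, 1:2,
             control = elca_control(n_restarts = 2, max_iter = 300,
                                    tol = 1e-7, seed = 1))
#> BIC model selection grid:
#>  G K    loglik      bic converged
#>  1 1 -3248.801 6559.747      TRUE
#>  1 2 -3184.364 6443.304      TRUE
#>  2 1 -3021.635 6173.777      TRUE
#>  2 2 -2891.568 5926.072      TRUE
#>  3 1 -2906.375 6011.617      TRUE
#>  3 2 -2880.728 5972.753      TRUE
#> selected: G = 2, K = 2
```

Exact size moments illustrate the variance inflation relative to the
profile-matched LCA (`p_ig = φ_ig Σ_k a_k τ_k`):

```r
exact_size_moments(theta)                      # mean 3.5, variance 3.778
exact_size_moments(matched_lca_params(theta))  # mean 3.5, variance 1.834
```

A command-line interface wrapping the same functions (subcommands
`simulate`, `fit`, `select`, `evaluate`, `moments`) is installed at
`inst/cli/hyperlca`; see `?elca_cli`.

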