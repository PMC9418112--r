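---
title: "Extended latent class analysis for hypergraphs: model, estimation, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extended latent class analysis for hypergraphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperlca)
```

## The model

A hypergraph on `N` vertices with `M` hyperedges is stored as the binary
incidence matrix $X = (x_{ij})$, $x_{ij} = 1$ iff vertex $i$ belongs to
hyperedge $j$. Hyperedges are the observations; the package clusters
them. Under the extended latent class analysis (ELCA) model each
hyperedge independently draws a *primary* label
$g \sim \mathrm{Categorical}(\pi)$ and, independently, a *size* label
$k \sim \mathrm{Categorical}(\tau)$; conditional on $(g, k)$ the vertex
memberships are independent Bernoulli draws with success probability
$a_k\,\phi_{ig}$. The observed-data likelihood is
$$
L(X;\theta)=\prod_{j=1}^{M}\sum_{g=1}^{G}\sum_{k=1}^{K}
\pi_g\,\tau_k\prod_{i=1}^{N}(a_k\phi_{ig})^{x_{ij}}(1-a_k\phi_{ig})^{1-x_{ij}},
\qquad \theta=(\pi,\tau,a,\phi).
$$

Assumptions worth making explicit:

* **Conditional independence.** Given its label pair, a hyperedge's
  vertex memberships are independent. Within-hyperedge dependence beyond
  what the two labels induce (e.g. social closure among specific vertex
  pairs) is not modeled.
* **Proportionality.** The profiles of the $G \times K$ implied classes
  are proportional within each primary cluster, with shared constants
  $a_1 \le \dots \le a_K = 1$. This is what buys the reduction from
  $GKN + (GK-1)$ to $GN + 2(K-1) + (G-1)$ parameters, and it is also the
  substantive claim: size variation acts uniformly on all vertices.
* **Exchangeable hyperedges.** Columns of $X$ are i.i.d.; duplicate
  hyperedges are allowed and are collapsed internally into multiplicity
  weights (`deduplicate_hyperedges()`), which leaves every likelihood
  and E-step quantity unchanged.

Without a constraint the model is not identifiable: scaling
$a \to Ca$, $\phi \to \phi/C$ leaves the likelihood untouched. The
package therefore canonicalizes on construction (`elca_params()`): $a$
sorted increasingly, $\tau$ permuted along, and the scale invariance used
to pin $a_K = 1$ exactly. Every fit returns the canonical representative,
which is what makes parameter comparisons and label-aligned errors well
defined. At $K = 1$ the representation is $a = (1)$, $\tau = (1)$, and
the model literally *is* the standard LCA — the same code path, not a
special case.

Two distributional facts about the size $|e|$ of a random hyperedge
guide the simulator's checks. First, against the LCA whose profiles are
matched through $p_{ig} = \phi_{ig}\sum_k a_k\tau_k$
(`matched_lca_params()`), the size means are identical and the ELCA
variance is never smaller — the size mixture adds a layer of spread.
`exact_size_moments()` computes both by the law of total variance,
exactly. Second, in the sparse regime where per-vertex probabilities
scale like $\lambda/N$, the size distribution converges to a mixture of
$G \times K$ Poisson distributions with weights $\pi_g\tau_k$ and rates
$a_k \lim_N \sum_i \phi_{ig}$. `size_tv_to_poisson_limit()` quantifies
the distance exactly: the finite-$N$ size pmf is computed by the
Poisson-binomial convolution recursion per mixture component ($O(N^2)$,
deterministic — chosen over simulation so the check has no Monte Carlo
error) and compared in total variation with the limit.

## Estimation

`elca_fit()` runs an expectation conditional maximization (ECM)
algorithm. The E-step computes joint responsibilities
$\hat z_{jgk} \propto \pi_g\tau_k \prod_i (a_k\phi_{ig})^{x_{ij}}(1-a_k\phi_{ig})^{1-x_{ij}}$,
evaluated in log space with log-sum-exp; the per-hyperedge log
normalizers summed with multiplicity weights are exactly the observed
log-likelihood, which is how the trace is obtained for free. The M-step
is replaced by four conditional maximizations per cycle, in a fixed
order: all of $\phi$, then the free entries of $a$, then $\pi$, then
$\tau$, all against the cycle's single E-step. The order is not
mathematically forced; it is fixed for reproducibility.

$\pi$ and $\tau$ have closed-form updates (responsibility masses,
normalized). $\phi_{ig}$ and $a_k$ do not, because of the
$\log(1 - a_k\phi_{ig})$ terms, so both use minorize–maximize (MM)
steps: the concave logarithm is lower-bounded by its quadratic expansion
at the current value with a curvature bound valid on the whole unit
interval ($-a_k^2/(1-a_k)^2$ for the $\phi$ step, $-\phi^2/(1-\phi)^2$
for the $a$ step). Maximizing the surrogate yields:

* for $\phi_{ig}$ a **cubic** stationarity equation. The surrogate
  $A_1\log\phi + A_2\log(1-\phi) + B_1\phi + B_2(\phi-\phi^{(t)})^2$ is
  concave ($A_1, A_2 \ge 0$, $B_2 \le 0$), so its maximizer on the
  clamped interval is unique; `mm_phi_update()` computes all real roots
  by the closed-form discriminant method, forms the candidate set
  {interior roots, interval bounds, current value}, and returns the
  candidate with the largest surrogate value. This candidate-set rule
  preserves the MM ascent guarantee regardless of which root is the
  maximizer, and degenerates gracefully: at $K = 1$ the $B$ terms vanish
  and the update collapses to the closed-form LCA estimate
  $A_1/(A_1+A_2)$.
* for $a_k$ ($k < K$; $a_K$ is pinned) a closed-form root
  $\hat a_k = (E + D^2/4)^{1/2} - D/2$. Because the surrogate is concave,
  clamping the root into the feasible interval still maximizes it there.

Each conditional maximization runs `mm_iter` MM sweeps (default 2): one
sweep already guarantees ascent; additional sweeps trade time for
per-cycle progress. Every cycle ends by re-sorting $a$ (jointly with
$\tau$) — updates can transiently violate the ordering, which is a
labeling constraint, not a restriction of the likelihood.

Numerical choices, all deliberate:

* Bernoulli probabilities are clamped to $[10^{-12}, 1-10^{-12}]$
  before logging ($M \cdot N$ products underflow quickly), and fitted
  parameters to $[10^{-6}, 1-10^{-6}]$ (`floor` in `elca_control()`):
  the MM curvatures involve $(1-a)^{-2}$ and $(1-\phi)^{-2}$.
  Mixing weights are floored the same way, then renormalized.
* Convergence is declared when the relative log-likelihood change falls
  below `tol` (default $10^{-8}$); the trace is non-decreasing up to
  that tolerance by the ECM + MM construction, and the tests verify the
  ascent property on random instances rather than assuming it.
* Initialization (`elca_init()`): $\pi, \tau$ flat-Dirichlet, $\phi$
  uniform on $(0.2, 0.8)$, free $a$ uniform on $(0.2, 1)$ sorted.
  Restarts (default 10) use consecutive seeds; the best final
  log-likelihood wins, with ties (under $10^{-9}$) broken by the lowest
  restart index. EM on this model has genuine local optima — restart
  counts below 3 visibly understate recovery rates in the studies below.
* Degenerate inputs: an all-zero incidence matrix fits with $\phi$ at
  the floor (with a warning); $G K > M$ warns that BIC is unreliable.

`lca_fit_em()` is a separate, closed-form EM for the plain LCA. It
shares only the low-level Bernoulli log-probability helper with the ELCA
path, which makes it an independent cross-check: started from the same
initialization, an ELCA fit with $K = 1$ must reproduce its
log-likelihood trace to within accumulation error, and the test suite
asserts agreement at $10^{-9}$.

## Model selection and evaluation

`select_model()` fits every cell of a $(G, K)$ grid with a shared
seeding policy and selects the converged cell minimizing
$\mathrm{BIC} = -2\log L + \{GN + 2(K-1) + (G-1)\}\log M$, with $M$ the
effective (weighted) hyperedge count. Ties go to fewer parameters, then
smaller $G$; non-converged cells are flagged and excluded unless all are.

Cluster labels in mixtures are only identified up to permutation, so all
evaluation is alignment-based. `align_labels()` takes hard labels as the
per-row argmax of the posterior and finds the permutation minimizing
disagreement with the reference labels by optimal assignment on the
confusion matrix — exhaustively for up to five clusters, otherwise by an
$O(C^3)$ shortest-augmenting-path (Hungarian) solver included in the
package and tested against the exhaustive path. `parameter_error()`
applies the primary permutation to $\phi$ and $\pi$ and the additional
permutation to $a$ and $\tau$, and reports Euclidean norms of the
flattened differences. Raw norms are the default; since reasonable
readers may expect per-entry scaling, `normalize = TRUE` divides each by
the square root of its entry count — both conventions are exposed rather
than guessing one. `recovery_check()` implements the criterion for
detecting that extra size structure is spurious:
$\max_k \hat\tau_k > 1-\varepsilon$ or $\min_k \hat a_k > 1-\varepsilon$.

## What the simulator emulates — and what it does not

`simulate_elca()` draws labels first ($z^{(1)}$, then $z^{(2)}$), then
fills the incidence matrix column-major, so fixtures are bit-reproducible
given a seed. The bundled study designs (`study_params()`) are the
conditions under which the package's simulation studies and acceptance
checks run, chosen once as representative of well-separated clustering
problems at desk scale:

* `"g2k2"`: $G=2$, $K=2$, $\pi=\tau=(1/2,1/2)$, $a=(0.4,1)$, block
  profiles at $0.8/0.2$ — vertices split into one high-probability block
  per primary cluster.
* `"g3k2"`: $G=3$, $K=2$, equal $\pi$, $a=(0.4,1)$, blocks at
  $0.8/0.15$.
* `"lca_g2"`: a plain LCA truth ($K=1$), blocks at $0.7/0.1$, used for
  the recovery-criterion study.

The study problem sizes are $N \in \{10, 20, 40\}$ and
$M \in \{50, 100, 500, 1000\}$, with 20 replicates per condition and 3–5
restarts per fit; the acceptance script uses the same sizes. These are
deliberate choices keeping a full run in minutes on one core while still
exhibiting the qualitative behaviour of interest (errors shrinking in
$M$, BIC selection sharpening with $N$ and $M$).

Passing these studies shows the estimator works *under the model's own
assumptions with separated clusters*. Real hypergraph data differ in
ways the generator does not emulate: profiles are not block-constant,
cluster separation is weaker, hyperedge sizes can be heavy-tailed beyond
what a two-level $a$ captures, memberships are not conditionally
independent, and hyperedges arrive with temporal or covariate structure
the model ignores. Results on the synthetic designs bound what can be
expected on real data from above.

## Known limitations

* Likelihood surfaces with nearly-degenerate size structure (data truly
  LCA, fitted $K > 1$) have a ridge along the $a$–$\tau$ trade-off;
  convergence there is slow, which is why the recovery study runs with
  the default tolerance $10^{-8}$ and up to 1000 iterations. Loose
  settings visibly understate recovery.
* No standard errors or posterior uncertainty for $\theta$: the package
  reports point estimates, traces, and responsibilities only.
* BIC is used as stated; ICL, AIC, and cross-validated likelihood are
  out of scope, as are vertex-side clustering, weighted incidences, and
  covariate-dependent mixing weights.
* Restarts run sequentially; at desk scale this is fast enough that
  parallelism was not worth the dependency.
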