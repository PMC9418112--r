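#' Deterministic example hypergraphs
#'
#' Named fixtures used in examples and tests; each call with the same name
#' returns identical objects (fixed internal seeds).
#'
#' * `"figure1"`: the 7-vertex, 4-hyperedge coauthorship example
#'   (`e1 = {v1..v4}`, `e2 = {v2, v3}`, `e3 = {v3, v5, v6}`, `e4 = {v4}`);
#'   no generating parameters or labels.
#' * `"lca_g2"`: 500 hyperedges from the `"lca_g2"` [study_params()]
#'   design at `N = 20` (a plain LCA, `K = 1`).
#' * `"elca_g2k2_sep"`: 500 hyperedges from the well-separated `"g2k2"`
#'   design at `N = 20`.
#' * `"elca_g3k2"`: 500 hyperedges from the `"g3k2"` design at `N = 20`.
#' * `"empty_edges"`: a small hand-written hypergraph containing all-zero
#'   hyperedges and an isolated vertex.
#'
#' @param name fixture identifier.
#' @return a list with `X` (an [incidence_matrix()]), `params` (the
#'   generating [elca_params()] or `NULL`), and `labels` (simulated labels
#'   or `NULL`).
#' @export
make_fixture <- function(name) {
  fixtures <- c("figure1", "lca_g2", "elca_g2k2_sep", "elca_g3k2", "empty_edges")
  if (!is.character(name) || length(name) != 1L || !(name %in% fixtures)) {
    stop(sprintf("unknown fixture '%s'; available: %s",
                 as.character(name)[1L], paste(fixtures, collapse = ", ")))
  }
  if (name == "figure1") {
    pairs <- data.frame(
      hyperedge_id = c("e1", "e1", "e1", "e1", "e2", "e2", "e3", "e3", "e3", "e4"),
      vertex_id = c("v1", "v2", "v3", "v4", "v2", "v3", "v3", "v5", "v6", "v4"))
    X <- from_edge_list(pairs, vertex_universe = paste0("v", 1:7),
                        hyperedge_universe = paste0("e", 1:4))
    return(list(X = X, params = NULL, labels = NULL))
  }
  if (name == "empty_edges") {
    x <- cbind(c(1, 1, 0, 0, 0, 0),
               c(0, 0, 0, 0, 0, 0),
               c(0, 1, 1, 1, 0, 0),
               c(0, 0, 0, 0, 0, 0),
               c(1, 0, 0, 1, 1, 0))
    return(list(X = incidence_matrix(x), params = NULL, labels = NULL))
  }
  design <- switch(name, lca_g2 = "lca_g2", elca_g2k2_sep = "g2k2",
                   elca_g3k2 = "g3k2")
  seed <- switch(name, lca_g2 = 421L, elca_g2k2_sep = 422L, elca_g3k2 = 423L)
  theta <- study_params(design, N = 20L)
  sim <- simulate_elca(theta, M = 500L, seed = seed)
  list(X = sim$X, params = theta, labels = sim$labels)
}
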