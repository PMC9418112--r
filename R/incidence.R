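#' Binary incidence matrix of a hypergraph
#'
#' Constructs the vertex-by-hyperedge incidence representation of a
#' hypergraph: an `N x M` matrix `x` with `x[i, j] = 1` iff vertex `i`
#' belongs to hyperedge `j`. Hyperedges are sets of vertices of arbitrary
#' size; repeated hyperedges are allowed and can be stored compactly via
#' integer multiplicities in `weights`. Empty hyperedges (all-zero columns)
#' and isolated vertices (all-zero rows) are legal and retained.
#'
#' @param x a matrix (or object coercible to one) with entries in `{0, 1}`;
#'   rows are vertices, columns are hyperedges.
#' @param vertex_names optional character vector of length `N` with unique
#'   entries; defaults to `v1, ..., vN`.
#' @param hyperedge_ids optional character vector of length `M` with unique
#'   entries; defaults to `e1, ..., eM`.
#' @param weights optional vector of positive integer multiplicities, one
#'   per hyperedge (default all 1). The effective number of hyperedges is
#'   `sum(weights)`.
#' @return an object of class `"incidence_matrix"`: a list with elements
#'   `x`, `vertex_names`, `hyperedge_ids`, `weights`.
#' @examples
#' X <- incidence_matrix(matrix(c(1, 1, 0, 0, 1, 1), nrow = 3))
#' hyperedge_sizes(X)
#' @export
incidence_matrix <- function(x, vertex_names = NULL, hyperedge_ids = NULL,
                             weights = NULL) {
  x <- as.matrix(x)
  if (length(x) == 0L) stop("incidence matrix must have at least one cell")
  if (anyNA(x) || !all(x == 0 | x == 1)) {
    stop("all incidence entries must be 0 or 1")
  }
  storage.mode(x) <- "double"
  n <- nrow(x)
  m <- ncol(x)
  if (is.null(vertex_names)) vertex_names <- paste0("v", seq_len(n))
  if (is.null(hyperedge_ids)) hyperedge_ids <- paste0("e", seq_len(m))
  vertex_names <- as.character(vertex_names)
  hyperedge_ids <- as.character(hyperedge_ids)
  if (length(vertex_names) != n || anyDuplicated(vertex_names)) {
    stop("vertex_names must have length N with unique entries")
  }
  if (length(hyperedge_ids) != m || anyDuplicated(hyperedge_ids)) {
    stop("hyperedge_ids must have length M with unique entries")
  }
  if (is.null(weights)) weights <- rep(1L, m)
  if (length(weights) != m || anyNA(weights) ||
      any(weights < 1) || any(weights != round(weights))) {
    stop("weights must be integers >= 1, one per hyperedge")
  }
  weights <- as.double(weights)
  dimnames(x) <- NULL
  structure(list(x = x, vertex_names = vertex_names,
                 hyperedge_ids = hyperedge_ids, weights = weights),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("Hypergraph incidence matrix: %d vertices x %d hyperedges",
              n_vertices(x), n_hyperedges(x)))
  eff <- sum(x$weights)
  if (eff != n_hyperedges(x)) {
    cat(sprintf(" (%d with multiplicities)", as.integer(eff)))
  }
  sz <- hyperedge_sizes(x)
  cat(sprintf("\nhyperedge sizes: min %d, median %g, max %d\n",
              min(sz), stats::median(sz), max(sz)))
  invisible(x)
}

#' Number of vertices / hyperedges
#'
#' @param X an [incidence_matrix()].
#' @return an integer.
#' @export
n_vertices <- function(X) nrow(X$x)

#' @rdname n_vertices
#' @export
n_hyperedges <- function(X) ncol(X$x)

#' Hyperedge sizes
#'
#' The size (cardinality, number of member vertices) of each hyperedge,
#' i.e. the column sums of the incidence matrix. Multiplicity weights are
#' not applied: one size per stored column.
#'
#' @param X an [incidence_matrix()].
#' @return integer vector of length `M`.
#' @export
hyperedge_sizes <- function(X) {
  stopifnot(inherits(X, "incidence_matrix"))
  as.integer(colSums(X$x))
}

#' Collapse duplicated hyperedges into weighted columns
#'
#' Identical columns of the incidence matrix are merged and their
#' multiplicities accumulated in `weights`. Likelihood and E-step
#' computations on the weighted result equal the unweighted computations on
#' the original matrix, which makes fitting cheaper when hyperedges repeat.
#' The attribute `"column_map"` on the result maps each original column to
#' its representative (first occurrence keeps its hyperedge id).
#'
#' @param X an [incidence_matrix()].
#' @return an [incidence_matrix()] with unique columns, carrying attribute
#'   `"column_map"` (integer vector of length `ncol(X$x)`).
#' @export
deduplicate_hyperedges <- function(X) {
  stopifnot(inherits(X, "incidence_matrix"))
  key <- apply(X$x, 2L, paste, collapse = "")
  first <- !duplicated(key)
  rep_idx <- which(first)
  map <- match(key, key[first])
  w <- as.vector(tapply(X$weights, map, sum))
  out <- incidence_matrix(X$x[, rep_idx, drop = FALSE],
                          vertex_names = X$vertex_names,
                          hyperedge_ids = X$hyperedge_ids[rep_idx],
                          weights = w)
  attr(out, "column_map") <- map
  out
}

#' Build an incidence matrix from a bipartite edge list
#'
#' Each pair `(hyperedge_id, vertex_id)` records that the vertex belongs to
#' the hyperedge (the bipartite / two-mode representation of a hypergraph).
#' Hyperedges are sets, so a duplicated pair is collapsed with a warning
#' rather than rejected. Declaring a `vertex_universe` fixes the vertex set
#' (and row order); a pair naming a vertex outside a declared universe is an
#' error. `hyperedge_universe` likewise allows empty hyperedges.
#'
#' @param pairs a two-column data frame or matrix: hyperedge id, vertex id.
#' @param vertex_universe optional character vector of all vertex names.
#' @param hyperedge_universe optional character vector of all hyperedge ids.
#' @return an [incidence_matrix()].
#' @seealso [to_edge_list()]
#' @export
from_edge_list <- function(pairs, vertex_universe = NULL,
                           hyperedge_universe = NULL) {
  if (is.null(pairs) || NROW(pairs) == 0L) {
    if (is.null(vertex_universe) || is.null(hyperedge_universe)) {
      stop("empty pair list requires both vertex_universe and hyperedge_universe")
    }
    eid <- character(0)
    vid <- character(0)
  } else {
    pairs <- as.data.frame(pairs, stringsAsFactors = FALSE)
    if (ncol(pairs) < 2L) stop("pairs must have two columns: hyperedge id, vertex id")
    eid <- as.character(pairs[[1L]])
    vid <- as.character(pairs[[2L]])
    dup <- duplicated(paste(eid, vid, sep = "\r"))
    if (any(dup)) {
      warning(sprintf("%d duplicated (hyperedge, vertex) pair(s) collapsed", sum(dup)))
      eid <- eid[!dup]
      vid <- vid[!dup]
    }
  }
  if (is.null(vertex_universe)) {
    vertex_universe <- unique(vid)
  } else if (!all(vid %in% vertex_universe)) {
    stop(sprintf("vertex id(s) outside declared universe: %s",
                 paste(setdiff(vid, vertex_universe), collapse = ", ")))
  }
  if (is.null(hyperedge_universe)) {
    hyperedge_universe <- unique(eid)
  } else if (!all(eid %in% hyperedge_universe)) {
    stop(sprintf("hyperedge id(s) outside declared universe: %s",
                 paste(setdiff(eid, hyperedge_universe), collapse = ", ")))
  }
  n <- length(vertex_universe)
  m <- length(hyperedge_universe)
  if (n == 0L || m == 0L) stop("resulting hypergraph has no vertices or no hyperedges")
  x <- matrix(0, n, m)
  x[cbind(match(vid, vertex_universe), match(eid, hyperedge_universe))] <- 1
  incidence_matrix(x, vertex_names = vertex_universe,
                   hyperedge_ids = hyperedge_universe)
}

#' Convert an incidence matrix to a bipartite edge list
#'
#' @param X an [incidence_matrix()].
#' @return a data frame with character columns `hyperedge_id`, `vertex_id`,
#'   ordered by hyperedge then vertex.
#' @seealso [from_edge_list()]
#' @export
to_edge_list <- function(X) {
  stopifnot(inherits(X, "incidence_matrix"))
  idx <- which(X$x == 1, arr.ind = TRUE)
  ord <- order(idx[, 2L], idx[, 1L])
  data.frame(hyperedge_id = X$hyperedge_ids[idx[ord, 2L]],
             vertex_id = X$vertex_names[idx[ord, 1L]],
             stringsAsFactors = FALSE)
}
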