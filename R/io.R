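#' Read and write hypergraph incidence files
#'
#' Three plain-text formats are supported. Files store one hyperedge per
#' record (rows), the transpose of the internal vertex-by-hyperedge
#' orientation; conversion happens at this boundary.
#'
#' * `"tsv"`: a header line `hyperedge_id` followed by the vertex names,
#'   then one row per hyperedge with its id and `N` 0/1 cells.
#' * `"edgelist"`: optional comment headers `# vertices: ...` and
#'   `# hyperedges: ...` declaring the universes (comma-separated), then a
#'   `hyperedge_id<TAB>vertex_id` pair per line. Without a vertex header
#'   the universe is collected from the pairs with a warning.
#' * `"triplet"`: a header line `N<TAB>M`, then lines
#'   `row<TAB>col<TAB>1` with 1-based vertex/hyperedge indices.
#'
#' @param path file path.
#' @param format `"tsv"`, `"edgelist"`, or `"triplet"`.
#' @param X an [incidence_matrix()].
#' @return `read_incidence` returns an [incidence_matrix()];
#'   `write_incidence` returns `path` invisibly.
#' @export
read_incidence <- function(path, format = c("tsv", "edgelist", "triplet")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  switch(format,
         tsv = read_incidence_tsv(path),
         edgelist = read_incidence_edgelist(path),
         triplet = read_incidence_triplet(path))
}

read_incidence_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("tsv incidence file needs a header and at least one row")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  vertex_names <- header[-1L]
  n <- length(vertex_names)
  m <- length(lines) - 1L
  x <- matrix(0, n, m)
  ids <- character(m)
  for (r in seq_len(m)) {
    parts <- strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1L]]
    if (length(parts) != n + 1L) {
      stop(sprintf("line %d: expected %d fields, found %d", r + 1L, n + 1L, length(parts)))
    }
    ids[r] <- parts[1L]
    cells <- suppressWarnings(as.numeric(parts[-1L]))
    if (anyNA(cells) || !all(cells %in% c(0, 1))) {
      stop(sprintf("line %d: non-binary incidence cell", r + 1L))
    }
    x[, r] <- cells
  }
  incidence_matrix(x, vertex_names = vertex_names, hyperedge_ids = ids)
}

read_incidence_edgelist <- function(path) {
  lines <- readLines(path)
  vertex_universe <- NULL
  hyperedge_universe <- NULL
  hdr <- grepl("^#", lines)
  for (h in lines[hdr]) {
    if (grepl("^#\\s*vertices:", h)) {
      vertex_universe <- trimws(strsplit(sub("^#\\s*vertices:", "", h), ",")[[1L]])
    } else if (grepl("^#\\s*hyperedges:", h)) {
      hyperedge_universe <- trimws(strsplit(sub("^#\\s*hyperedges:", "", h), ",")[[1L]])
    }
  }
  body <- lines[!hdr & nzchar(lines)]
  pairs <- NULL
  if (length(body) > 0L) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2L)
    if (length(bad) > 0L) {
      stop(sprintf("line %d: expected two tab-separated fields", which(!hdr & nzchar(lines))[bad[1L]]))
    }
    pairs <- data.frame(hyperedge_id = vapply(parts, `[[`, "", 1L),
                        vertex_id = vapply(parts, `[[`, "", 2L),
                        stringsAsFactors = FALSE)
    if (is.null(vertex_universe)) {
      warning("no vertex universe declared; collecting vertices from pairs")
    }
  }
  from_edge_list(pairs, vertex_universe = vertex_universe,
                 hyperedge_universe = hyperedge_universe)
}

read_incidence_triplet <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  hdr <- suppressWarnings(as.integer(strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]))
  if (length(hdr) < 2L || anyNA(hdr)) stop("triplet header must give N and M")
  n <- hdr[1L]
  m <- hdr[2L]
  x <- matrix(0, n, m)
  for (r in seq_along(lines[-1L])) {
    parts <- suppressWarnings(as.numeric(strsplit(lines[r + 1L], "\t", fixed = TRUE)[[1L]]))
    if (length(parts) != 3L || anyNA(parts)) {
      stop(sprintf("line %d: expected 'row<TAB>col<TAB>1'", r + 1L))
    }
    if (parts[3L] != 1) stop(sprintf("line %d: triplet value must be 1", r + 1L))
    if (parts[1L] < 1 || parts[1L] > n || parts[2L] < 1 || parts[2L] > m) {
      stop(sprintf("line %d: index out of range", r + 1L))
    }
    x[parts[1L], parts[2L]] <- 1
  }
  incidence_matrix(x)
}

#' @rdname read_incidence
#' @export
write_incidence <- function(X, path, format = c("tsv", "edgelist", "triplet")) {
  stopifnot(inherits(X, "incidence_matrix"))
  format <- match.arg(format)
  lines <- switch(format,
    tsv = {
      header <- paste(c("hyperedge_id", X$vertex_names), collapse = "\t")
      rows <- vapply(seq_len(n_hyperedges(X)), function(j) {
        paste(c(X$hyperedge_ids[j], format(X$x[, j], trim = TRUE)), collapse = "\t")
      }, "")
      c(header, rows)
    },
    edgelist = {
      el <- to_edge_list(X)
      c(paste0("# vertices: ", paste(X$vertex_names, collapse = ",")),
        paste0("# hyperedges: ", paste(X$hyperedge_ids, collapse = ",")),
        paste(el$hyperedge_id, el$vertex_id, sep = "\t"))
    },
    triplet = {
      idx <- which(X$x == 1, arr.ind = TRUE)
      idx <- idx[order(idx[, 2L], idx[, 1L]), , drop = FALSE]
      c(paste(n_vertices(X), n_hyperedges(X), sep = "\t"),
        paste(idx[, 1L], idx[, 2L], 1L, sep = "\t"))
    })
  writeLines(lines, path)
  invisible(path)
}

#' Serialize a fit to JSON and posterior probabilities to TSV
#'
#' The JSON document holds the estimated parameters, the log-likelihood
#' trace, the BIC, convergence metadata, and the per-hyperedge marginal
#' posterior probabilities of the primary and additional clusterings. The
#' TSV export lists, per hyperedge, the joint `(g, k)` posteriors followed
#' by the primary and additional marginals (the data behind posterior
#' trace and ternary plots).
#'
#' @param fit an [elca_fit()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "elca_fit"))
  th <- fit$params
  doc <- list(
    G = fit$G, K = fit$K,
    params = list(pi = th$pi, tau = th$tau, a = th$a,
                  phi = lapply(seq_len(th$N), function(i) th$phi[i, ])),
    loglik = fit$loglik, bic = fit$bic, converged = fit$converged,
    n_iterations = fit$n_iterations, loglik_trace = fit$loglik_trace,
    restart_logliks = fit$restart_logliks,
    hyperedge_ids = fit$hyperedge_ids,
    posterior_primary = asplit_rows(posterior_marginals(fit, "primary")),
    posterior_additional = asplit_rows(posterior_marginals(fit, "additional")))
  jsonlite::write_json(doc, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

asplit_rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])

#' @rdname write_fit_json
#' @export
write_posteriors_tsv <- function(fit, path) {
  stopifnot(inherits(fit, "elca_fit"))
  z <- fit$responsibilities
  m <- dim(z)[1L]
  joint <- matrix(z, m)  # columns ordered (g, k) with g fastest
  cols <- expand.grid(g = seq_len(fit$G), k = seq_len(fit$K))
  df <- data.frame(hyperedge_id = fit$hyperedge_ids,
                   joint, posterior_marginals(fit, "primary"),
                   posterior_marginals(fit, "additional"))
  names(df) <- c("hyperedge_id",
                 sprintf("z_g%d_k%d", cols$g, cols$k),
                 sprintf("primary_g%d", seq_len(fit$G)),
                 sprintf("additional_k%d", seq_len(fit$K)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a BIC selection grid as TSV
#'
#' Columns `G`, `K`, `loglik`, `BIC`, `converged`, one row per fitted cell.
#'
#' @param grid a [select_model()] result.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_bic_grid_tsv <- function(grid, path) {
  stopifnot(inherits(grid, "bic_grid"))
  df <- grid$grid
  names(df) <- c("G", "K", "loglik", "BIC", "converged")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulated labels as TSV
#'
#' @param labels list with `z1` and optionally `z2` (from [simulate_elca()]).
#' @param hyperedge_ids character vector of ids.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_labels_tsv <- function(labels, hyperedge_ids, path) {
  df <- data.frame(hyperedge_id = hyperedge_ids, z1 = labels$z1)
  if (!is.null(labels$z2)) df$z2 <- labels$z2
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
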