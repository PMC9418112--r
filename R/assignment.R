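# Minimum-cost assignment of rows to columns of a square cost matrix.
# Returns an integer vector p with p[c] = row assigned to column c.
# Exhaustive search for n <= 5 (the common case when aligning cluster
# labels); O(n^3) shortest-augmenting-path Hungarian algorithm otherwise.
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1)
  if (n <= 5L) {
    perms <- all_permutations(n)
    vals <- apply(perms, 1L, function(p) sum(cost[cbind(p, seq_len(n))]))
    perms[which.min(vals), ]
  } else {
    hungarian_assignment(cost)
  }
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, 0L, n)
  for (pos in seq_len(n)) {
    block <- cbind(sub[, seq_len(pos - 1L), drop = FALSE], n,
                   sub[, seq(pos, n - 1L)[seq_len(n - pos)], drop = FALSE])
    out <- rbind(out, block)
  }
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

# Jonker-style shortest augmenting path with dual potentials; indices are
# offset by one so the virtual column 0 sits at position 1.
hungarian_assignment <- function(cost) {
  n <- nrow(cost)
  u <- numeric(n + 1L)
  v <- numeric(n + 1L)
  p <- integer(n + 1L)            # p[j + 1] = row matched to column j
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1L]) {
          cur <- cost[i0, j] - u[i0 + 0L] - v[j + 1L]
          if (cur < minv[j + 1L]) {
            minv[j + 1L] <- cur
            way[j + 1L] <- j0
          }
          if (minv[j + 1L] < delta) {
            delta <- minv[j + 1L]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1L]) {
          if (p[j + 1L] > 0L) u[p[j + 1L]] <- u[p[j + 1L]] + delta
          v[j + 1L] <- v[j + 1L] - delta
        } else {
          minv[j + 1L] <- minv[j + 1L] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  p[-1L]
}
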