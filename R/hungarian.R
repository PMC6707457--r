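# Optimal linear assignment by the shortest-augmenting-path (Hungarian)
# method with dual potentials, O(n^3). Used by align_factors when the
# number of components exceeds the exhaustive-search range; verified
# against exhaustive permutation search in the test suite.

# cost: square numeric matrix. Returns integer vector a with a[i] the
# column assigned to row i, minimizing sum_i cost[i, a[i]].
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("assignment cost matrix must be square")
  if (n == 1L) return(1L)
  u <- numeric(n + 1L)       # row potentials (index n+1 = virtual row 0)
  v <- numeric(n + 1L)       # column potentials (index n+1 = virtual col 0)
  p <- integer(n + 1L)       # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[n + 1L] <- i
    j0 <- n + 1L
    minv <- rep(Inf, n + 1L)
    used <- rep(FALSE, n + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) {
            minv[j] <- cur
            way[j] <- j0
          }
          if (minv[j] < delta) {
            delta <- minv[j]
            j1 <- j
          }
        }
      }
      for (j in seq_len(n + 1L)) {
        if (used[j]) {
          u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == n + 1L) break
    }
  }
  a <- integer(n)
  a[p[seq_len(n)]] <- seq_len(n)
  a
}
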