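# Minimum-cost bipartite assignment (Hungarian algorithm, shortest
# augmenting path formulation with potentials). Costs must be finite;
# requires nrow(cost) <= ncol(cost). Returns the assigned column for each
# row. Complexity O(n^2 * m) - adequate for the per-frame spot counts of
# sparse single-molecule data.
hungarian_assign <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(integer(0))
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(m + 1)          # index 1 = virtual column
  p <- integer(m + 1)          # p[j] = row matched to column j-1 (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      delta <- Inf; j1 <- 0L
      for (j in seq_len(m) + 1L) {
        if (!used[j]) {
          cur <- cost[i0, j - 1L] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1L)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
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
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m) + 1L) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}
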