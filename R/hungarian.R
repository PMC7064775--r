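# Minimum-cost bipartite assignment (Hungarian algorithm, shortest
# augmenting path formulation, O(n^2 m)). Used to resolve conflicting
# nearest-neighbour claims during frame-to-frame linking; no installed
# package provides weighted bipartite matching, so it lives here and is
# tested against a brute-force permutation oracle.
#
# cost: n x m matrix, n <= m. Returns integer vector a with a[i] = column
# assigned to row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m)
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)      # p[j+1]: row matched to column j (0 = free)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      free <- which(!used[2:(m + 1)])
      cur <- cost[i0, free] - u[i0 + 1] - v[free + 1]
      better <- cur < minv[free + 1]
      idx <- free[better]
      minv[idx + 1] <- cur[better]
      way[idx + 1] <- j0
      k <- which.min(minv[free + 1])
      j1 <- free[k]
      delta <- minv[j1 + 1]
      usedj <- which(used) - 1L
      u[p[usedj + 1] + 1] <- u[p[usedj + 1] + 1] + delta
      v[usedj + 1] <- v[usedj + 1] - delta
      minv[free + 1] <- minv[free + 1] - delta
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) a[p[j + 1]] <- j
  a
}
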