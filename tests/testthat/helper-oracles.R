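# Independent oracles and shared fixtures for the test suite.

# Brute-force anisotropic kernel (direct transcription of the defining
# formulas, no shared code with the package internals beyond base R).
oracle_kernel <- function(Z, eps, alpha) {
  m <- nrow(Z)
  g <- matrix(NA_real_, m, m)
  for (i in 1:m) for (j in 1:m)
    g[i, j] <- exp(-sum((Z[i, ] - Z[j, ])^2) / eps[i, j])
  rho <- rowSums(g)
  K <- matrix(NA_real_, m, m)
  for (i in 1:m) for (j in 1:m)
    K[i, j] <- g[i, j] / (rho[i] * rho[j])^alpha
  K
}

# Brute-force per-point kNN radius (full sort, no partial tricks).
oracle_eta <- function(Z, r) {
  m <- nrow(Z)
  rank <- max(1, ceiling(r * (m - 1)))
  vapply(1:m, function(i) {
    d <- sqrt(colSums((t(Z[-i, , drop = FALSE]) - Z[i, ])^2))
    sort(d)[rank]
  }, numeric(1))
}

# Exact committor of a finite Markov chain: probability of reaching set B
# before set A, solved from the linear system on the interior states.
oracle_committor <- function(P, A, B) {
  k <- nrow(P)
  q <- numeric(k)
  q[B] <- 1
  interior <- setdiff(seq_len(k), c(A, B))
  if (length(interior) > 0) {
    M <- diag(length(interior)) - P[interior, interior, drop = FALSE]
    rhs <- rowSums(P[interior, B, drop = FALSE])
    q[interior] <- solve(M, rhs)
  }
  q
}

# Exhaustive Ward merge on a handful of 1-D points: at each step join the
# pair of clusters with minimal Ward cost (increase in within-cluster SSE).
oracle_ward_1d <- function(x, k) {
  clusters <- as.list(seq_along(x))
  sse <- function(idx) sum((x[idx] - mean(x[idx]))^2)
  while (length(clusters) > k) {
    best <- c(NA, NA)
    best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      cost <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (cost < best_cost) {
        best_cost <- cost
        best <- c(i, j)
      }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(length(x))
  for (s in seq_along(clusters)) labels[clusters[[s]]] <- s
  labels
}

# Exhaustive least-cost path on a small grid: enumerate all simple paths by
# depth-first search (feasible for grids of a dozen populated bins).
oracle_min_path <- function(F, from, to) {
  pop <- which(!is.na(F), arr.ind = TRUE)
  key <- function(ij) paste(ij[1], ij[2])
  pop_keys <- apply(pop, 1, key)
  best <- list(cost = Inf, path = NULL)
  hop <- max(F, na.rm = TRUE) * 1e-9 + 1e-12
  rec <- function(cur, visited, cost, path) {
    if (cost >= best$cost) return()
    if (all(cur == to)) {
      best <<- list(cost = cost, path = path)
      return()
    }
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      nxt <- cur + c(di, dj)
      k <- key(nxt)
      if (!(k %in% pop_keys) || k %in% visited) next
      w <- (F[cur[1], cur[2]] + F[nxt[1], nxt[2]]) / 2 + hop
      rec(nxt, c(visited, k), cost + w, rbind(path, nxt))
    }
  }
  rec(from, key(from), 0, matrix(from, 1))
  best
}

# Small deterministic two-cluster batch used across kernel/learning tests.
two_cluster_batch <- function(m = 200, sd = 0.05, seed = 1) {
  set.seed(seed)
  c(rnorm(m / 2, -1, sd), rnorm(m / 2, 1, sd))
}

# Lifted double-well data set with ground truth, scaled for unit tests.
make_lifted <- function(seed, n_steps = 2e6, T_sub = 5000, n = 10) {
  z <- simulate_langevin(double_well(5), beta = 1, dt = 1e-3,
                         n_steps = n_steps, seed = seed)
  sub <- seq(1, nrow(z), length.out = T_sub)
  lift_trajectory(z[sub, , drop = FALSE], n = n, seed = seed + 1000, dt = 1)
}
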