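# Independent brute-force oracles and tiny graph builders used across the
# suite. Everything here works from the dense adjacency matrix with naive
# summations, deliberately sharing no code path with the package.

random_test_graph <- function(n, p, seed) {
  set.seed(seed)
  A <- matrix(0L, n, n)
  iu <- which(upper.tri(A))
  on <- iu[runif(length(iu)) < p]
  A[on] <- 1L
  A <- A + t(A)
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  list(g = g, A = A, names = igraph::V(g)$name)
}

named_graph <- function(formula_graph, names = NULL) {
  g <- formula_graph
  if (is.null(igraph::V(g)$name)) {
    if (is.null(names)) names <- sprintf("v%02d", seq_len(igraph::vcount(g)))
    igraph::V(g)$name <- names
  }
  g
}

# all-pairs shortest-path distances by Floyd-Warshall
bf_distances <- function(A) {
  n <- nrow(A)
  d <- ifelse(A > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], "+"))
  d
}

# shortest-path counts sigma[s, t] by dynamic programming in distance order
bf_sigma <- function(A, d) {
  n <- nrow(A)
  s <- matrix(0, n, n)
  diag(s) <- 1
  for (i in seq_len(n)) {
    for (j in order(d[i, ])) {
      if (j == i || !is.finite(d[i, j])) next
      pred <- which(A[, j] > 0 & d[i, ] == d[i, j] - 1)
      s[i, j] <- sum(s[i, pred])
    }
  }
  s
}

# Freeman betweenness: sum over unordered pairs s < t (both != v) of the
# fraction of shortest s-t paths passing through v
bf_betweenness <- function(A) {
  n <- nrow(A)
  d <- bf_distances(A)
  sg <- bf_sigma(A, d)
  btw <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (d[s, v] + d[v, t] == d[s, t]) {
          btw[v] <- btw[v] + sg[s, v] * sg[v, t] / sg[s, t]
        }
      }
    }
  }
  btw
}

# within-component closeness (n_c - 1) / sum of distances
bf_closeness <- function(A) {
  d <- bf_distances(A)
  vapply(seq_len(nrow(A)), function(v) {
    reach <- is.finite(d[v, ])
    if (sum(reach) == 1) return(0)
    (sum(reach) - 1) / sum(d[v, reach])
  }, numeric(1))
}

# per-component principal adjacency eigenvector by shifted power iteration
# (all-ones start has positive overlap with the Perron vector)
bf_eigenvector <- function(A, tol = 1e-13, max_iter = 2e5) {
  n <- nrow(A)
  d <- bf_distances(A)
  out <- numeric(n)
  seen <- rep(FALSE, n)
  for (v in seq_len(n)) {
    if (seen[v]) next
    comp <- which(is.finite(d[v, ]))
    seen[comp] <- TRUE
    if (length(comp) == 1) { out[comp] <- 1; next }
    Ac <- A[comp, comp]
    x <- rep(1, length(comp))
    x <- x / sqrt(sum(x^2))
    for (i in seq_len(max_iter)) {
      y <- as.numeric(Ac %*% x) + x
      y <- y / sqrt(sum(y^2))
      if (max(abs(y - x)) < tol) { x <- y; break }
      x <- y
    }
    out[comp] <- x / sqrt(sum(x^2))
  }
  out
}

# modularity by the direct double sum over same-community pairs
bf_modularity <- function(A, mem) {
  m <- sum(A) / 2
  if (m == 0) return(0)
  k <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (mem[i] == mem[j]) q <- q + A[i, j] - k[i] * k[j] / (2 * m)
    }
  }
  unname(q / (2 * m))
}

# CPM Hamiltonian by the direct pairwise sum
bf_cpm <- function(A, mem, gamma) {
  n <- nrow(A)
  h <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mem[i] == mem[j]) h <- h - (A[i, j] - gamma)
    }
  }
  h
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
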