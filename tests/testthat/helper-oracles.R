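# Independent brute-force oracles. These stay deliberately naive: they
# enumerate outcomes or loop over all node triples/pairs, and never call the
# package functions they check.

# P(X >= k) for X ~ Binomial(n, p) by enumerating all 2^n success patterns.
brute_binom_right <- function(k, n, p) {
  total <- 0
  for (code in 0:(2^n - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(n)]
    s <- sum(bits)
    if (s >= k) total <- total + p^s * (1 - p)^(n - s)
  }
  total
}

# P(X >= k) for X ~ Hypergeometric(N, K, n) by enumerating all C(N, n) draws
# from a universe whose first K elements are "successes".
brute_hyper_right <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) >= k)
}

# Literal Holm step-down, written from the definition.
hand_holm <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj_sorted <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    running <- max(running, (m - i + 1) * p[ord[i]])
    adj_sorted[i] <- min(1, running)
  }
  out <- numeric(m)
  out[ord] <- adj_sorted
  out
}

# Cytoscape-convention average clustering from an adjacency matrix.
brute_avg_clustering <- function(adj) {
  n <- nrow(adj)
  coeffs <- numeric(n)
  for (v in seq_len(n)) {
    nb <- which(adj[v, ] > 0)
    d <- length(nb)
    if (d < 2) next
    links <- 0
    for (i in seq_along(nb)) {
      for (j in seq_len(i - 1)) {
        if (adj[nb[i], nb[j]] > 0) links <- links + 1
      }
    }
    coeffs[v] <- links / (d * (d - 1) / 2)
  }
  mean(coeffs)
}

# Mean pairwise shortest-path length by Floyd-Warshall.
brute_avg_shortest_path <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  d[adj > 0] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  mean(d[upper.tri(d)])
}

# Random named G(n, p) graph.
random_graph <- function(n, p, seed) {
  set.seed(seed)
  g <- igraph::sample_gnp(n, p)
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  g
}

graph_from_edges <- function(edges, isolated = character()) {
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  if (length(isolated) > 0) g <- igraph::add_vertices(g, length(isolated), name = isolated)
  g
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Two 5-cliques joined by a single bridge edge.
bridged_cliques <- function() {
  a <- igraph::make_full_graph(5)
  igraph::V(a)$name <- paste0("a", 1:5)
  b <- igraph::make_full_graph(5)
  igraph::V(b)$name <- paste0("b", 1:5)
  g <- igraph::disjoint_union(a, b)
  igraph::add_edges(g, c("a1", "b1"))
}
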