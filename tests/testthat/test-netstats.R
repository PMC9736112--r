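test_that("giant component extraction and ties", {
  g <- graph_from_edges(data.frame(from = c("a", "b", "d"),
                                   to = c("b", "c", "e")))
  giant <- giant_component(g)
  expect_setequal(igraph::V(giant)$name, c("a", "b", "c"))

  full <- graph_from_edges(data.frame(from = "a", to = "b"))
  expect_setequal(igraph::V(giant_component(full))$name, c("a", "b"))

  iso <- igraph::make_empty_graph(3, directed = FALSE)
  igraph::V(iso)$name <- c("c", "a", "b")
  expect_warning(one <- giant_component(iso), "tie")
  expect_equal(igraph::V(one)$name, "a")  # lexicographically smallest set

  expect_error(giant_component(igraph::make_empty_graph(0)), "empty")
  expect_equal(giant_fraction(g), 3 / 5)
})

test_that("average clustering follows the Cytoscape convention", {
  tri <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")))
  expect_equal(avg_clustering(tri), 1)

  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- paste0("s", 1:5)
  expect_equal(avg_clustering(star), 0)

  # square with one diagonal a-c: diagonal endpoints see 2 of 3 neighbour
  # pairs linked, the others are in one triangle: (2/3 + 1 + 2/3 + 1) / 4
  sq <- graph_from_edges(data.frame(from = c("a", "b", "c", "d", "a"),
                                    to = c("b", "c", "d", "a", "c")))
  expect_equal(avg_clustering(sq), 5 / 6)
  expect_equal(avg_clustering(sq),
               brute_avg_clustering(igraph::as_adjacency_matrix(sq, sparse = FALSE)))

  # excluding degree-<2 nodes is available behind the flag
  path2 <- graph_from_edges(data.frame(from = c("a", "b"), to = c("b", "c")))
  expect_equal(avg_clustering(path2), 0)
  expect_equal(avg_clustering(path2, drop_low_degree = TRUE), 0)
})

test_that("average shortest path matches hand values and rejects fragments", {
  tri <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                     to = c("b", "c", "a")))
  expect_equal(avg_shortest_path(tri), 1)
  path <- graph_from_edges(data.frame(from = c("A", "B"), to = c("B", "C")))
  expect_equal(avg_shortest_path(path), 4 / 3)
  frag <- graph_from_edges(data.frame(from = "a", to = "b"), isolated = "z")
  expect_error(avg_shortest_path(frag), "giant component")
})

test_that("clustering and path metrics equal brute force on random graphs", {
  for (i in 1:40) {
    g <- random_graph(n = sample(4:12, 1), p = runif(1, 0.2, 0.8), seed = i)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE)
    expect_equal(avg_clustering(g), brute_avg_clustering(adj),
                 tolerance = 1e-12)
    if (igraph::is_connected(g) && igraph::vcount(g) >= 2) {
      expect_equal(avg_shortest_path(g), brute_avg_shortest_path(adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("metrics are invariant under node relabelling", {
  g <- random_graph(10, 0.4, seed = 99)
  perm <- sample(10)
  g2 <- igraph::permute(g, perm)
  expect_equal(avg_clustering(g), avg_clustering(g2))
  expect_equal(graph_metrics(g)$n_edges, graph_metrics(g2)$n_edges)
})

test_that("degree ranking is descending with ties by node id", {
  star <- igraph::make_star(5, mode = "undirected")
  igraph::V(star)$name <- c("hub", "l1", "l2", "l3", "l4")
  rank <- degree_ranking(star)
  expect_equal(rank$node[1], "hub")
  expect_equal(rank$degree[1], 4)

  tri <- graph_from_edges(data.frame(from = c("c", "a", "b"),
                                     to = c("a", "b", "c")))
  expect_equal(degree_ranking(tri)$node, c("a", "b", "c"))
})

test_that("MCL separates disjoint triangles and bridged cliques", {
  two_tri <- graph_from_edges(data.frame(
    from = c("a1", "a2", "a3", "b1", "b2", "b3"),
    to = c("a2", "a3", "a1", "b2", "b3", "b1")))
  cl <- mcl(two_tri)
  expect_equal(cl$n_clusters, 2)
  expect_equal(sort(tabulate(cl$membership$cluster)), c(3, 3))
  m <- cl$membership
  expect_equal(length(unique(m$cluster[startsWith(m$node, "a")])), 1)

  cl5 <- mcl(bridged_cliques(), inflation = 2.5)
  expect_equal(cl5$n_clusters, 2)
  expect_equal(sort(tabulate(cl5$membership$cluster)), c(5, 5))
  m5 <- cl5$membership
  expect_equal(length(unique(m5$cluster[startsWith(m5$node, "a")])), 1)
  expect_equal(length(unique(m5$cluster[startsWith(m5$node, "b")])), 1)
})

test_that("MCL output is a partition and never merges components", {
  for (seed in 1:5) {
    g <- random_graph(n = 20, p = 0.15, seed = seed)
    cl <- mcl(g)
    expect_setequal(cl$membership$node, igraph::V(g)$name)
    expect_equal(anyDuplicated(cl$membership$node), 0)
    comp <- igraph::components(g)$membership
    cluster_of <- cl$membership$cluster[match(igraph::V(g)$name,
                                              cl$membership$node)]
    # two nodes in one MCL cluster must share a connected component
    for (k in unique(cluster_of)) {
      expect_equal(length(unique(comp[cluster_of == k])), 1)
    }
  }
})

test_that("MCL is deterministic and relabelling-invariant", {
  g <- random_graph(15, 0.3, seed = 42)
  a <- mcl(g)
  b <- mcl(g)
  expect_identical(a$membership, b$membership)
  g2 <- igraph::permute(g, sample(15))
  c2 <- mcl(g2)
  joined <- dplyr::inner_join(a$membership, c2$membership, by = "node",
                              suffix = c("_a", "_b"))
  expect_equal(ari(joined$cluster_a, joined$cluster_b), 1)
})

test_that("MCL recovers planted coexpression modules", {
  sim <- simulate_module_matrix(n_modules = 4, module_size = 15, n_noise = 30,
                                n_samples = 100, seed = 17)
  g <- build_graph(pairwise_pearson(sim$mat), 0.6)
  cl <- mcl(g, inflation = 2.5)
  joined <- dplyr::left_join(cl$membership, sim$truth,
                             by = c(node = "gene"))
  modular <- !is.na(joined$module)
  expect_gte(ari(joined$cluster[modular], joined$module[modular]), 0.9)
})

test_that("graph metrics assemble into one consistent row", {
  g <- graph_from_edges(data.frame(from = c("a", "b", "c"),
                                   to = c("b", "c", "a")),
                        isolated = c("x", "y"))
  m <- graph_metrics(g)
  expect_equal(m$n_nodes, 5)
  expect_equal(m$n_edges, 3)
  expect_equal(m$giant_fraction, 3 / 5)
  expect_equal(m$avg_shortest_path, 1)
  expect_equal(m$avg_clustering, 3 / 5)  # two isolated nodes contribute 0
})
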