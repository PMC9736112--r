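#' Extract the giant component of a graph
#'
#' Returns the subgraph induced by the largest connected component. A size
#' tie is broken towards the lexicographically smallest node-name set, with a
#' warning.
#'
#' @param g An igraph graph.
#' @return The giant component as an igraph graph.
#' @export
giant_component <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  comp <- igraph::components(g)
  biggest <- which(comp$csize == max(comp$csize))
  if (length(biggest) > 1) {
    warning("giant component tie (", length(biggest),
            " components of size ", max(comp$csize),
            "); smallest node set chosen", call. = FALSE)
    sets <- lapply(biggest, function(b) {
      sort(igraph::V(g)$name[comp$membership == b])
    })
    keys <- vapply(sets, paste, "", collapse = "\r")
    biggest <- biggest[order(keys)][1]
  }
  igraph::induced_subgraph(g, igraph::V(g)[comp$membership == biggest])
}

#' Fraction of nodes in the giant component
#'
#' @param g An igraph graph.
#' @return `|giant| / |nodes|`.
#' @export
giant_fraction <- function(g) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  max(igraph::components(g)$csize) / igraph::vcount(g)
}

#' Average (local) clustering coefficient
#'
#' Mean over all nodes of the local clustering coefficient: triangles through
#' the node divided by `deg * (deg - 1) / 2`. Following the Cytoscape
#' NetworkAnalyzer convention, nodes of degree < 2 contribute 0 to the mean;
#' set `drop_low_degree = TRUE` to exclude them instead.
#'
#' @param g An igraph graph with at least one node.
#' @param drop_low_degree Exclude degree-<2 nodes from the mean (default
#'   `FALSE`).
#' @return Value in `[0, 1]`.
#' @export
avg_clustering <- function(g, drop_low_degree = FALSE) {
  if (igraph::vcount(g) == 0) stop("empty graph", call. = FALSE)
  local <- igraph::transitivity(g, type = "local", isolates = "NaN")
  if (drop_low_degree) {
    local <- local[!is.nan(local)]
    if (length(local) == 0) return(0)
  } else {
    local[is.nan(local)] <- 0
  }
  mean(local)
}

#' Average shortest path length
#'
#' Mean unweighted BFS distance over all unordered node pairs of a connected
#' graph. Call on the [giant_component()] for a fragmented network.
#'
#' @param g A connected igraph graph.
#' @return Mean pairwise distance (1 for a complete graph).
#' @export
avg_shortest_path <- function(g) {
  if (igraph::vcount(g) < 2) stop("need at least 2 nodes", call. = FALSE)
  if (!igraph::is_connected(g)) {
    stop("graph is disconnected; extract the giant component first",
         call. = FALSE)
  }
  igraph::mean_distance(g, directed = FALSE)
}

#' Rank nodes by degree
#'
#' @param g An igraph graph.
#' @return Tibble (`node`, `degree`) in descending degree order, ties broken
#'   by node name.
#' @export
degree_ranking <- function(g) {
  deg <- igraph::degree(g)
  tibble::tibble(node = names(deg), degree = as.integer(deg)) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node)
}

#' Standard metrics of a coexpression network
#'
#' @param g An igraph graph.
#' @param drop_low_degree Passed to [avg_clustering()].
#' @return One-row tibble: `n_nodes`, `n_edges`, `avg_clustering`,
#'   `avg_shortest_path` (computed on the giant component), `giant_fraction`.
#' @export
graph_metrics <- function(g, drop_low_degree = FALSE) {
  giant <- giant_component(g)
  tibble::tibble(
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    avg_clustering = avg_clustering(g, drop_low_degree),
    avg_shortest_path = if (igraph::vcount(giant) >= 2) {
      avg_shortest_path(giant)
    } else {
      NA_real_
    },
    giant_fraction = igraph::vcount(giant) / igraph::vcount(g)
  )
}

#' Markov Cluster Algorithm (MCL)
#'
#' Deterministic dense-matrix MCL on the (binary) adjacency matrix. The
#' column-stochastic transition matrix (self-loops of weight 1 added by
#' default) is alternately expanded (matrix power) and inflated (entrywise
#' power followed by column renormalisation, with small entries pruned) until
#' the change between iterations falls below `tol`. Clusters are read off the
#' attractor structure of the limit matrix; any overlap between attractor
#' systems is resolved towards the larger cluster with a warning. The
#' inflation exponent is the "granularity" parameter: larger values give
#' finer clusterings.
#'
#' @param g An igraph graph (non-empty).
#' @param inflation Inflation exponent (> 1; default 2.5).
#' @param expansion Expansion power (integer >= 2; default 2).
#' @param pruning_threshold Entries below this are zeroed each iteration
#'   (default 1e-5).
#' @param max_iterations Iteration cap (default 100).
#' @param tol Convergence tolerance on the max absolute change (default 1e-6).
#' @param self_loops Add unit self-loops before normalisation (default TRUE).
#' @param weighted Use the `weight` edge attribute if present (default FALSE:
#'   binary adjacency).
#' @return Object of class `mcl_clustering`: a list with `membership` (tibble
#'   `node`, `cluster`; clusters numbered 1.. in decreasing size), `n_clusters`,
#'   `converged`, `n_iterations`. Supports [generics::tidy()] and
#'   [generics::glance()].
#' @export
mcl <- function(g, inflation = 2.5, expansion = 2, pruning_threshold = 1e-5,
                max_iterations = 100, tol = 1e-6, self_loops = TRUE,
                weighted = FALSE) {
  stopifnot(inflation > 1, expansion >= 2)
  n <- igraph::vcount(g)
  if (n == 0) stop("empty graph", call. = FALSE)
  nodes <- igraph::V(g)$name
  if (is.null(nodes)) nodes <- as.character(seq_len(n))
  a <- igraph::as_adjacency_matrix(
    g, sparse = FALSE,
    attr = if (weighted && "weight" %in% igraph::edge_attr_names(g)) "weight" else NULL
  )
  if (self_loops) diag(a) <- pmax(diag(a), 1)
  m <- col_normalise(a)

  converged <- FALSE
  iter <- 0L
  while (iter < max_iterations) {
    iter <- iter + 1L
    prev <- m
    for (e in seq_len(expansion - 1)) m <- m %*% prev  # matrix power
    m[m < pruning_threshold] <- 0
    m <- col_normalise(m^inflation)
    m[m < pruning_threshold] <- 0
    m <- col_normalise(m)
    if (max(abs(m - prev)) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge in ", max_iterations,
            " iterations; returning current clustering", call. = FALSE)
  }

  membership <- mcl_interpret(m, nodes, pruning_threshold)
  structure(
    list(membership = membership,
         n_clusters = max(membership$cluster),
         converged = converged,
         n_iterations = iter),
    class = "mcl_clustering"
  )
}

col_normalise <- function(m) {
  s <- colSums(m)
  s[s == 0] <- 1
  sweep(m, 2, s, "/")
}

# Read clusters from the limit matrix: attractors are rows with a positive
# diagonal; each attractor row spans the columns it attracts. Attractor rows
# sharing members belong to one attractor system and are merged; remaining
# overlaps (rare, non-converged input) go to the larger cluster.
mcl_interpret <- function(m, nodes, eps) {
  n <- length(nodes)
  attractors <- which(diag(m) > eps)
  clusters <- list()
  if (length(attractors) > 0) {
    support <- lapply(attractors, function(i) which(m[i, ] > eps))
    # merge attractor rows with overlapping support (one attractor system)
    assigned <- rep(0L, length(support))
    for (i in seq_along(support)) {
      if (assigned[i] != 0L) next
      members <- support[[i]]
      assigned[i] <- length(clusters) + 1L
      repeat {
        grew <- FALSE
        for (j in seq_along(support)) {
          if (assigned[j] == 0L && length(intersect(support[[j]], members)) > 0) {
            members <- union(members, support[[j]])
            assigned[j] <- assigned[i]
            grew <- TRUE
          }
        }
        if (!grew) break
      }
      clusters[[assigned[i]]] <- sort(members)
    }
  }
  # resolve residual overlaps towards the larger cluster
  seen <- integer(0)
  sizes <- lengths(clusters)
  for (k in order(sizes, decreasing = TRUE)) {
    dup <- intersect(clusters[[k]], seen)
    if (length(dup) > 0) {
      warning("overlapping MCL clusters; ", length(dup),
              " node(s) kept in the larger cluster", call. = FALSE)
      clusters[[k]] <- setdiff(clusters[[k]], dup)
    }
    seen <- c(seen, clusters[[k]])
  }
  clusters <- clusters[lengths(clusters) > 0]
  # unattracted nodes become singletons
  left <- setdiff(seq_len(n), unlist(clusters))
  clusters <- c(clusters, as.list(left))
  # order by size (desc), ties by smallest member index for determinism
  ord <- order(-lengths(clusters),
               vapply(clusters, min, numeric(1)))
  clusters <- clusters[ord]
  membership <- integer(n)
  for (k in seq_along(clusters)) membership[clusters[[k]]] <- k
  tibble::tibble(node = nodes, cluster = membership)
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat("<mcl_clustering> ", x$n_clusters, " clusters over ",
      nrow(x$membership), " nodes (",
      if (x$converged) paste0("converged in ", x$n_iterations, " iterations")
      else "not converged", ")\n", sep = "")
  sizes <- sort(table(x$membership$cluster), decreasing = TRUE)
  cat("cluster sizes:", paste(utils::head(as.integer(sizes), 10), collapse = ", "),
      if (length(sizes) > 10) "..." else "", "\n")
  invisible(x)
}

#' Nodes of a given MCL cluster
#'
#' @param clustering An `mcl_clustering`.
#' @param cluster Cluster id (default 1, the largest).
#' @return Character vector of node names.
#' @export
mcl_cluster_nodes <- function(clustering, cluster = 1) {
  clustering$membership$node[clustering$membership$cluster == cluster]
}
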