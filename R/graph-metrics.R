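# Global and nodal topology of binary graphs.
#
# All metrics follow the unweighted conventions used in connectome
# analysis: clustering with 0 for degree < 2 nodes, characteristic path
# length averaged over finite-distance pairs, efficiency with the
# 1/infinity = 0 convention, Brandes betweenness with fractional counting
# normalized by (n-1)(n-2)/2.

as_bg <- function(g) {
  if (inherits(g, "binary_graph")) g else binary_graph(g)
}

#' Clustering coefficient
#'
#' Per node: the fraction of the node's neighbor pairs that are connected
#' (0 for nodes of degree < 2); the network value `cp` is the mean over
#' all nodes.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @return A list with elements `cp` (scalar) and `node_values`.
#' @export
clustering_coefficient <- function(g) {
  g <- as_bg(g)
  vals <- igraph::transitivity(g$graph, type = "local", isolates = "zero")
  list(cp = mean(vals), node_values = vals)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all ordered node pairs at finite
#' distance.  Disconnected pairs are excluded from the mean; their count
#' is reported alongside so sparse-threshold disconnection is visible.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @return A list with elements `lp` and `disconnected_pairs` (ordered
#'   pairs at infinite distance).
#' @export
characteristic_path_length <- function(g) {
  g <- as_bg(g)
  if (g$n_edges == 0) stop_validation("characteristic path length is undefined for an edgeless graph")
  d <- igraph::distances(g$graph)
  off <- d[row(d) != col(d)]
  finite <- is.finite(off)
  list(lp = mean(off[finite]), disconnected_pairs = sum(!finite))
}

efficiency_from_distances <- function(d) {
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(d) - 1)
}

#' Global and nodal efficiency
#'
#' Nodal efficiency of node i is the mean inverse shortest-path distance
#' from i to every other node (with 1/infinity = 0 for unreachable
#' pairs); global efficiency is the mean nodal efficiency.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @return `global_efficiency()` returns a scalar in `[0, 1]`;
#'   `nodal_efficiency()` a per-node vector.
#' @export
global_efficiency <- function(g) {
  mean(nodal_efficiency(g))
}

#' @rdname global_efficiency
#' @export
nodal_efficiency <- function(g) {
  g <- as_bg(g)
  efficiency_from_distances(igraph::distances(g$graph))
}

#' Local efficiency
#'
#' Per node: the global efficiency of the subgraph induced by the node's
#' neighbors (0 when the node has fewer than 2 neighbors); the network
#' value is the mean over all nodes.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @return A list with elements `eloc` and `node_values`.
#' @export
local_efficiency <- function(g) {
  g <- as_bg(g)
  adj <- g$adj
  vals <- vapply(seq_len(g$n_nodes), function(i) {
    nbrs <- which(adj[i, ])
    if (length(nbrs) < 2) return(0)
    sub <- adj[nbrs, nbrs, drop = FALSE]
    gs <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    mean(efficiency_from_distances(igraph::distances(gs)))
  }, numeric(1))
  list(eloc = mean(vals), node_values = vals)
}

#' Nodal degree and betweenness
#'
#' Degree is the number of directly connected neighbors.  Betweenness is
#' Brandes shortest-path betweenness with fractional counting over
#' equal-length shortest paths, normalized by `(n-1)(n-2)/2` so values are
#' comparable across network sizes.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @return A per-node numeric vector.
#' @export
nodal_degree <- function(g) {
  g <- as_bg(g)
  as.numeric(igraph::degree(g$graph))
}

#' @rdname nodal_degree
#' @export
nodal_betweenness <- function(g) {
  g <- as_bg(g)
  n <- g$n_nodes
  if (n < 3) stop_validation("betweenness is undefined for fewer than 3 nodes")
  as.numeric(igraph::betweenness(g$graph, directed = FALSE)) /
    ((n - 1) * (n - 2) / 2)
}

#' Degree-preserving random rewiring (Maslov-Sneppen null model)
#'
#' Applies double-edge swaps that preserve every node's degree exactly:
#' two edges (a,b) and (c,d) are replaced by (a,d) and (c,b) unless the
#' swap would create a self-loop or multi-edge.  Used to build the null
#' ensemble for [normalized_small_world()].
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @param n_swaps Number of *accepted* swaps to perform (default 10 times
#'   the edge count).
#' @param seed RNG seed.
#' @param max_tries Proposal budget; if it is exhausted first (e.g. on a
#'   star graph, where no swap is acceptable) the partially rewired graph
#'   is returned with a warning.
#' @return A [binary_graph()] with the same degree sequence.
#' @export
random_rewire <- function(g, n_swaps = NULL, seed = 1L, max_tries = NULL) {
  g <- as_bg(g)
  n_swaps <- n_swaps %||% (10 * g$n_edges)
  max_tries <- max_tries %||% (50 * max(n_swaps, 1))
  if (g$n_edges < 2) {
    warn("fewer than 2 edges; graph returned unchanged")
    return(g)
  }
  edges <- which(upper.tri(g$adj) & g$adj, arr.ind = TRUE)
  rewired <- with_seed(seed, {
    rewire_edgelist_cpp(edges, g$n_nodes, as.integer(n_swaps),
                        as.integer(min(max_tries, .Machine$integer.max)))
  })
  accepted <- attr(rewired, "accepted")
  if (accepted < n_swaps) {
    warn(sprintf("only %d of %d requested swaps were accepted", accepted, n_swaps))
  }
  out <- from_edge_matrix(rewired, g$n_nodes, sparsity = g$sparsity)
  attr(out, "accepted_swaps") <- accepted
  out
}

#' Small-world normalization against degree-preserving nulls
#'
#' Computes gamma = Cp / mean(Cp of rewired nulls), lambda = Lp /
#' mean(Lp of nulls) and sigma = gamma / lambda.  A network is
#' small-world when gamma > 1 and lambda is approximately 1
#' simultaneously (so sigma > 1).  Null seeds are derived from `seed` by
#' counter, so the ensemble is reproducible.
#'
#' @param g A [binary_graph()] (or adjacency matrix).
#' @param n_null Number of null networks (default 100).
#' @param seed Master RNG seed.
#' @param n_swaps Accepted swaps per null (default 10 x edges).
#' @return A list with `gamma`, `lambda`, `sigma`, `cp`, `lp`,
#'   `null_cp_mean`, `null_lp_mean`.
#' @export
normalized_small_world <- function(g, n_null = 100, seed = 1L, n_swaps = NULL) {
  g <- as_bg(g)
  if (!is_count(n_null)) stop_config("`n_null` must be a positive integer")
  cp <- clustering_coefficient(g)$cp
  lp <- characteristic_path_length(g)$lp
  null_cp <- numeric(n_null)
  null_lp <- numeric(n_null)
  for (b in seq_len(n_null)) {
    gb <- random_rewire(g, n_swaps = n_swaps, seed = derive_seed(seed, b))
    null_cp[b] <- clustering_coefficient(gb)$cp
    null_lp[b] <- characteristic_path_length(gb)$lp
  }
  if (mean(null_cp) == 0) {
    stop_validation("null ensemble has zero mean clustering; graph too sparse to normalize")
  }
  gamma <- cp / mean(null_cp)
  lambda <- lp / mean(null_lp)
  list(gamma = gamma, lambda = lambda, sigma = gamma / lambda,
       cp = cp, lp = lp,
       null_cp_mean = mean(null_cp), null_lp_mean = mean(null_lp))
}

#' Area under a metric curve over the sparsity grid
#'
#' Trapezoidal integral of a per-threshold metric curve along the
#' sparsity axis -- the threshold-free summary used for all group
#' statistics.
#'
#' @param values Metric values, one per grid point.
#' @param grid Sparsity grid (same length as `values`).
#' @return The trapezoidal integral (scalar).
#' @export
auc_over_sparsity <- function(values, grid) {
  if (length(values) != length(grid)) {
    stop_validation(sprintf("curve has %d values but the grid has %d points",
                            length(values), length(grid)))
  }
  bad <- which(!is.finite(values))
  if (length(bad) > 0) {
    stop_validation(sprintf("non-finite metric value at grid point s = %g",
                            grid[bad[1]]))
  }
  pracma::trapz(grid, values)
}
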