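# Named small graphs used across the topology tests.

adj_from_edges <- function(edges, n) {
  adj <- matrix(0L, n, n)
  for (e in edges) {
    adj[e[1], e[2]] <- 1L
    adj[e[2], e[1]] <- 1L
  }
  adj
}

complete_adj <- function(n) {
  adj <- matrix(1L, n, n)
  diag(adj) <- 0L
  adj
}

cycle_adj <- function(n) {
  adj_from_edges(c(lapply(seq_len(n - 1), function(i) c(i, i + 1)),
                   list(c(n, 1))), n)
}

path_adj <- function(n) {
  adj_from_edges(lapply(seq_len(n - 1), function(i) c(i, i + 1)), n)
}

star_adj <- function(n) {
  adj_from_edges(lapply(2:n, function(i) c(1, i)), n)
}

# K4 minus the (1,2) edge.
k4_minus_edge <- function() {
  adj_from_edges(list(c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4)), 4)
}

# Kite: K4 on nodes 1-4 with a tail 4-5.
kite_adj <- function() {
  adj_from_edges(list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4),
                      c(3, 4), c(4, 5)), 5)
}

# Quick small-cohort config for end-to-end tests.
toy_cohort_config <- function(n_patients = 6, n_controls = 6, n_nodes = 40,
                              n_timepoints = 120, seed = 11L, ...) {
  cohort_config(n_patients = n_patients, n_controls = n_controls,
                n_nodes = n_nodes, n_timepoints = n_timepoints,
                community_sizes = rep(n_nodes / 4, 4), seed = seed, ...)
}

expect_metrics_match_oracle <- function(adj, tol = 1e-10) {
  g <- binary_graph(adj)
  cc <- clustering_coefficient(g)
  oc <- oracle_clustering(adj)
  expect_equal(cc$cp, oc$cp, tolerance = tol)
  expect_equal(cc$node_values, oc$node_values, tolerance = tol)
  lp <- characteristic_path_length(g)
  ol <- oracle_lp(adj)
  expect_equal(lp$lp, ol$lp, tolerance = tol)
  expect_identical(lp$disconnected_pairs, ol$disconnected_pairs)
  expect_equal(nodal_efficiency(g), oracle_nodal_efficiency(adj), tolerance = tol)
  expect_equal(global_efficiency(g), oracle_eg(adj), tolerance = tol)
  el <- local_efficiency(g)
  oe <- oracle_eloc(adj)
  expect_equal(el$eloc, oe$eloc, tolerance = tol)
  expect_equal(el$node_values, oe$node_values, tolerance = tol)
  expect_equal(nodal_degree(g), colSums(adj), tolerance = tol,
               ignore_attr = TRUE)
  if (nrow(adj) >= 3) {
    expect_equal(nodal_betweenness(g), oracle_betweenness(adj), tolerance = tol)
  }
}
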