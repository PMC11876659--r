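test_that("binarize_at_sparsity keeps the k strongest edges with deterministic ties", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- 0.9
  w[1, 3] <- 0.8
  w[2, 3] <- 0.5
  w[1, 4] <- 0.4
  w[2, 4] <- 0.2
  w[3, 4] <- 0.1
  w <- w + t(w)
  g <- binarize_at_sparsity(w, 0.5)
  expect_equal(g$n_edges, 3)
  expect_true(all(g$adj[cbind(c(1, 1, 2), c(2, 3, 3))]))
  expect_false(g$adj[1, 4])

  # ties at the cut: lower (i, j) pair wins
  w2 <- matrix(0, 4, 4)
  w2[1, 2] <- 0.9
  w2[1, 3] <- 0.5
  w2[2, 4] <- 0.5
  w2 <- w2 + t(w2)
  g2 <- binarize_at_sparsity(w2, 2 / 6)
  expect_true(g2$adj[1, 2])
  expect_true(g2$adj[1, 3])
  expect_false(g2$adj[2, 4])

  # full graph when k equals the number of pairs
  w3 <- matrix(runif(25), 5, 5)
  w3 <- (w3 + t(w3)) / 2
  diag(w3) <- 0
  g3 <- binarize_at_sparsity(w3, 10 / 10 - 1e-9)
  expect_equal(g3$n_edges, 10)

  expect_error(binarize_at_sparsity(w, 0.01), class = "connectopath_config_error")
  expect_warning(binarize_at_sparsity(w2, 0.9), "non-zero weights")
})

test_that("edge count is exact at every grid point on random weight matrices", {
  grid <- sparsity_grid()
  withr::with_seed(42, {
    for (rep in 1:3) {
      n <- sample(20:40, 1)
      w <- matrix(rnorm(n^2), n, n)
      w <- (w + t(w)) / 2
      diag(w) <- 0
      w <- abs(w)  # all positive so no shortfall warnings
      for (s in sample(grid, 6)) {
        g <- binarize_at_sparsity(w, s)
        expect_equal(g$n_edges, round(s * n * (n - 1) / 2 + 1e-9))
      }
    }
  })
})

test_that("clustering, path length and efficiency match closed forms on named graphs", {
  expect_equal(clustering_coefficient(complete_adj(3))$cp, 1)
  expect_equal(clustering_coefficient(path_adj(3))$cp, 0)

  k4e <- clustering_coefficient(k4_minus_edge())
  expect_equal(k4e$node_values, c(1, 1, 2 / 3, 2 / 3))
  expect_equal(k4e$cp, 5 / 6)

  expect_equal(characteristic_path_length(complete_adj(5))$lp, 1)
  expect_equal(characteristic_path_length(cycle_adj(4))$lp, 4 / 3)

  two_k2 <- adj_from_edges(list(c(1, 2), c(3, 4)), 4)
  lp <- characteristic_path_length(two_k2)
  expect_equal(lp$lp, 1)
  expect_equal(lp$disconnected_pairs, 8)
  expect_error(characteristic_path_length(matrix(0, 3, 3)),
               class = "connectopath_validation_error")

  expect_equal(global_efficiency(complete_adj(4)), 1)
  expect_equal(nodal_efficiency(complete_adj(4)), rep(1, 4))
  expect_equal(global_efficiency(cycle_adj(4)), 5 / 6)

  # K3 plus two isolated nodes: unreachable pairs contribute 0
  k3_iso <- adj_from_edges(list(c(1, 2), c(1, 3), c(2, 3)), 5)
  expect_equal(global_efficiency(k3_iso), mean(c(rep(2 / 4, 3), 0, 0)))

  expect_equal(local_efficiency(complete_adj(4))$eloc, 1)
  expect_equal(local_efficiency(star_adj(5))$eloc, 0)
  expect_equal(local_efficiency(k4_minus_edge())$eloc,
               oracle_eloc(k4_minus_edge())$eloc)
})

test_that("degree and betweenness follow their definitions", {
  p3 <- path_adj(3)
  expect_equal(nodal_betweenness(p3), c(0, 1, 0))
  expect_equal(nodal_betweenness(complete_adj(5)), rep(0, 5))
  expect_equal(nodal_degree(star_adj(6)), c(5, rep(1, 5)))
  expect_error(nodal_betweenness(matrix(0, 2, 2)),
               class = "connectopath_validation_error")

  kite <- kite_adj()
  expect_equal(nodal_betweenness(kite), oracle_betweenness_enum(kite))
})

test_that("path-counting and path-enumeration betweenness oracles agree", {
  # cross-validates the two independent oracle routes on all 4- and
  # 5-node labeled graphs
  for (n in 4:5) {
    n_pairs <- n * (n - 1) / 2
    for (mask in 0:(2^n_pairs - 1)) {
      adj <- adj_from_mask(mask, n)
      if (sum(adj) == 0) next
      expect_equal(oracle_betweenness(adj), oracle_betweenness_enum(adj),
                   tolerance = 1e-12)
    }
  }
})

test_that("metric invariants hold on random graphs", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(5:12, 1)
      adj <- random_adjacency(n, p = runif(1, 0.25, 0.7))
      if (sum(adj) == 0) next
      g <- binary_graph(adj)
      expect_equal(mean(nodal_efficiency(g)), global_efficiency(g))
      expect_equal(sum(nodal_degree(g)), 2 * g$n_edges)
      if (n >= 3) {
        nb <- nodal_betweenness(g)
        expect_true(all(nb >= 0))
        expect_true(all(nb[nodal_degree(g) <= 1] == 0))
      }
    }
  })
})

test_that("metrics are invariant under node relabeling", {
  withr::with_seed(13, {
    for (rep in 1:5) {
      n <- 9
      adj <- random_adjacency(n, 0.4)
      if (sum(adj) == 0) next
      perm <- sample(n)
      padj <- adj[perm, perm]
      expect_equal(clustering_coefficient(adj)$cp, clustering_coefficient(padj)$cp)
      expect_equal(characteristic_path_length(adj)$lp,
                   characteristic_path_length(padj)$lp)
      expect_equal(global_efficiency(adj), global_efficiency(padj))
      expect_equal(local_efficiency(adj)$eloc, local_efficiency(padj)$eloc)
      expect_equal(sort(nodal_betweenness(adj)), sort(nodal_betweenness(padj)))
      expect_equal(sort(nodal_degree(adj)), sort(nodal_degree(padj)))
    }
  })
})

test_that("random rewiring preserves degrees, is seed-deterministic, and randomizes structure", {
  withr::with_seed(3, {
    adj <- random_adjacency(20, 0.3)
  })
  g <- binary_graph(adj)
  r1 <- random_rewire(g, seed = 5)
  r2 <- random_rewire(g, seed = 5)
  r3 <- random_rewire(g, seed = 6)
  expect_identical(r1$adj, r2$adj)
  expect_false(identical(r1$adj, r3$adj))
  expect_equal(nodal_degree(r1), nodal_degree(g))
  expect_equal(r1$n_edges, g$n_edges)
  expect_false(any(diag(r1$adj)))

  # star graph admits no swap: returned unchanged with a warning
  star <- binary_graph(star_adj(6))
  expect_warning(rs <- random_rewire(star, n_swaps = 10, max_tries = 1000,
                                     seed = 1), "accepted")
  expect_identical(rs$adj, star$adj)

  # C8 rewired with many swaps leaves the lattice: clustering of the
  # ensemble drops to that of random degree-2 graphs and the edge set moves
  c8 <- binary_graph(cycle_adj(8))
  changed <- vapply(1:20, function(s) {
    rw <- random_rewire(c8, n_swaps = 80, seed = s)
    !identical(rw$adj, c8$adj)
  }, logical(1))
  expect_true(mean(changed) > 0.9)
})

test_that("small-world normalization is self-consistent and sigma = gamma/lambda", {
  withr::with_seed(21, {
    adj <- random_adjacency(30, 0.25)
  })
  g <- binary_graph(adj)
  sw <- normalized_small_world(g, n_null = 30, seed = 9)
  expect_equal(sw$sigma, sw$gamma / sw$lambda)
  # an ER-like graph is its own null: gamma and lambda near 1
  expect_lt(abs(sw$gamma - 1), 0.25)
  expect_lt(abs(sw$lambda - 1), 0.1)

  # modular small-world template: strong excess clustering
  tmpl <- make_structural_template(60, rep(15, 4), 0.1, seed = 2)
  gt <- binarize_at_sparsity(tmpl, 0.15)
  swt <- normalized_small_world(gt, n_null = 20, seed = 4)
  expect_gt(swt$gamma, 1)
})

test_that("AUC integration matches closed-form trapezoids and validates input", {
  grid <- sparsity_grid()
  expect_length(grid, 25)
  expect_equal(auc_over_sparsity(rep(1, 25), grid), 0.24)
  expect_equal(auc_over_sparsity(rep(2, 25), grid), 0.48)
  ramp <- seq(0, 1, length.out = 25)
  expect_equal(auc_over_sparsity(ramp, grid), 0.12)
  bad <- rep(1, 25)
  bad[7] <- NaN
  expect_error(auc_over_sparsity(bad, grid), "0.16")
  expect_error(auc_over_sparsity(rep(1, 10), grid),
               class = "connectopath_validation_error")
})

test_that("connectome_metrics produces consistent curves and AUC tables", {
  tmpl <- make_structural_template(30, c(8, 8, 7, 7), 0.1, seed = 5)
  grid <- sparsity_grid(0.12, 0.2, 0.02)
  curves <- connectome_metrics(tmpl, grid = grid,
                               metrics = c("cp", "lp", "eg", "nd", "ne"),
                               subject_id = "s1", modality = "SC")
  expect_setequal(unique(curves$metric), c("cp", "lp", "eg", "nd", "ne"))
  expect_equal(sum(curves$scope == "global"), 3 * length(grid))
  expect_equal(sum(curves$metric == "nd"), 30 * length(grid))
  # mean nodal efficiency equals global efficiency at each threshold
  by_s <- split(curves, curves$sparsity)
  for (chunk in by_s) {
    expect_equal(mean(chunk$value[chunk$metric == "ne"]),
                 chunk$value[chunk$metric == "eg" & chunk$scope == "global"])
  }
  auc <- metric_auc(curves)
  expect_equal(nrow(auc), 3 + 2 * 30)
  eg_curve <- curves[curves$metric == "eg", ]
  expect_equal(auc$auc[auc$metric == "eg"],
               auc_over_sparsity(eg_curve$value[order(eg_curve$sparsity)], grid))
})
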