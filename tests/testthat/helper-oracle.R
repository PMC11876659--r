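# Brute-force graph-metric oracle, independent of the package's igraph
# path: Floyd-Warshall distances, exhaustive triangle counting, and
# shortest-path counting from the distance matrix (plus a DFS
# path-enumeration variant for tiny graphs).  Only usable for small n.

oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

oracle_clustering <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nbrs <- which(adj[i, ] > 0)
    k <- length(nbrs)
    if (k < 2) return(0)
    tri <- sum(adj[nbrs, nbrs]) / 2
    tri / (k * (k - 1) / 2)
  }, numeric(1))
  list(cp = mean(vals), node_values = vals)
}

oracle_lp <- function(adj) {
  d <- oracle_distances(adj)
  off <- d[row(d) != col(d)]
  list(lp = mean(off[is.finite(off)]), disconnected_pairs = sum(!is.finite(off)))
}

oracle_nodal_efficiency <- function(adj) {
  d <- oracle_distances(adj)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

oracle_eg <- function(adj) mean(oracle_nodal_efficiency(adj))

oracle_eloc <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nbrs <- which(adj[i, ] > 0)
    if (length(nbrs) < 2) return(0)
    oracle_eg(adj[nbrs, nbrs, drop = FALSE])
  }, numeric(1))
  list(eloc = mean(vals), node_values = vals)
}

# Betweenness by counting shortest paths from the Floyd-Warshall distance
# matrix: sigma[s,t] accumulated by path length, through-node counts from
# the composition identity sigma_sv * sigma_vt when d(s,v)+d(v,t)=d(s,t).
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  sigma[d == 1] <- 1
  finite_d <- d[is.finite(d)]
  maxd <- max(finite_d)
  if (maxd >= 2) {
    for (len in 2:maxd) {
      idx <- which(d == len, arr.ind = TRUE)
      for (r in seq_len(nrow(idx))) {
        s <- idx[r, 1]
        t <- idx[r, 2]
        w <- which(adj[, t] > 0 & d[s, ] == len - 1)
        sigma[s, t] <- sum(sigma[s, w])
      }
    }
  }
  nb <- numeric(n)
  for (v in seq_len(n)) {
    tot <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || !is.finite(d[s, t])) next
        if (is.finite(d[s, v]) && is.finite(d[v, t]) &&
            d[s, v] + d[v, t] == d[s, t]) {
          tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
        }
      }
    }
    nb[v] <- tot
  }
  nb / ((n - 1) * (n - 2) / 2)
}

# DFS enumeration of every simple path between every pair; the slow but
# definitionally transparent variant, used to cross-validate
# oracle_betweenness on very small graphs.
oracle_betweenness_enum <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(s, t) {
    paths <- list()
    dfs <- function(path) {
      v <- path[length(path)]
      if (v == t) {
        paths[[length(paths) + 1]] <<- path
        return(invisible())
      }
      for (w in which(adj[v, ] > 0)) {
        if (!(w %in% path)) dfs(c(path, w))
      }
    }
    dfs(s)
    paths
  }
  nb <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      shortest <- paths[lens == min(lens)]
      cnt <- numeric(n)
      for (p in shortest) {
        mid <- p[-c(1, length(p))]
        cnt[mid] <- cnt[mid] + 1
      }
      nb <- nb + cnt / length(shortest)
    }
  }
  nb / ((n - 1) * (n - 2) / 2)
}

# Adjacency matrix from an integer edge-subset mask over the upper
# triangle (used to enumerate all labeled graphs on n nodes).
adj_from_mask <- function(mask, n) {
  n_pairs <- n * (n - 1) / 2
  bits <- as.integer(intToBits(mask))[seq_len(n_pairs)]
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- bits
  adj + t(adj)
}

is_connected_adj <- function(adj) {
  all(is.finite(oracle_distances(adj)))
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(0L, n, n)
  adj[upper.tri(adj)] <- as.integer(runif(n * (n - 1) / 2) < p)
  adj + t(adj)
}
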