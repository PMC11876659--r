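#' Sparsity grid for network thresholding
#'
#' The default grid, 0.10 to 0.34 in steps of 0.01 (25 points), spans the
#' range over which thresholded brain networks are typically both sparse
#' and fully estimable; integrating metrics over it (see
#' [auc_over_sparsity()]) avoids committing to any single threshold.
#'
#' @param s_min,s_max Grid endpoints, `0 < s_min < s_max < 1`.
#' @param step Grid step.
#' @return A numeric vector of sparsity values.
#' @export
sparsity_grid <- function(s_min = 0.10, s_max = 0.34, step = 0.01) {
  if (!(s_min > 0 && s_min < s_max && s_max < 1)) {
    stop_config("need 0 < s_min < s_max < 1")
  }
  n_steps <- floor((s_max - s_min) / step + 1e-9)
  grid <- s_min + step * (0:n_steps)
  if (length(grid) < 2) stop_config("sparsity grid must have at least 2 points")
  grid
}

#' Binary graph at a fixed sparsity
#'
#' `binary_graph()` wraps an adjacency matrix as the package's unit of
#' metric computation; [binarize_at_sparsity()] is the usual constructor.
#'
#' @param adj Symmetric 0/1 (or logical) adjacency matrix with zero
#'   diagonal.
#' @param sparsity Sparsity level the graph was thresholded at (`NA` for
#'   hand-built graphs).
#' @return An object of class `binary_graph`: a list with elements
#'   `adj` (logical matrix), `graph` (igraph), `n_nodes`, `n_edges`,
#'   `sparsity`.
#' @export
binary_graph <- function(adj, sparsity = NA_real_) {
  adj <- as.matrix(adj)
  if (nrow(adj) != ncol(adj)) stop_validation("adjacency matrix must be square")
  adj <- adj != 0
  if (any(diag(adj))) stop_validation("self-loops are not allowed")
  if (any(adj != t(adj))) stop_validation("adjacency matrix must be symmetric")
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(adj = adj, graph = g, n_nodes = nrow(adj),
                 n_edges = sum(adj) / 2, sparsity = sparsity),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("<binary_graph> %d nodes, %d edges (sparsity %s)\n",
              x$n_nodes, x$n_edges,
              if (is.na(x$sparsity)) "NA" else format(x$sparsity)))
  invisible(x)
}

from_edge_matrix <- function(edges, n_nodes, sparsity = NA_real_) {
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[edges] <- TRUE
  adj[edges[, c(2, 1), drop = FALSE]] <- TRUE
  binary_graph(adj, sparsity = sparsity)
}

#' Binarize a weighted connectivity matrix at a sparsity level
#'
#' Keeps exactly `k = round(s * n(n-1)/2)` strongest upper-triangle
#' weights as edges of an undirected unweighted graph (rounding half away
#' from zero).  Ties at the cut boundary are broken deterministically by
#' ascending `(i, j)` index pair.  Negative functional-connectivity
#' weights are either set to zero (default) or replaced by their absolute
#' value before ranking.
#'
#' @param w A [connectivity_matrix()] or symmetric zero-diagonal numeric
#'   matrix.
#' @param s Target sparsity in (0, 1).
#' @param negative_weights `"zero"` (drop negative edges) or
#'   `"absolute"` (rank by magnitude).
#' @return A [binary_graph()].  If fewer than `k` weights are non-zero,
#'   all non-zero edges are kept and a warning reports the shortfall.
#' @export
binarize_at_sparsity <- function(w, s, negative_weights = c("zero", "absolute")) {
  negative_weights <- match.arg(negative_weights)
  w <- as.matrix(unclass(w))
  n <- nrow(w)
  if (asymmetry(w) > 1e-10) stop_validation("weight matrix must be symmetric")
  n_pairs <- n * (n - 1) / 2
  k <- round_half_away(s * n_pairs)
  if (k < 1) {
    stop_config(sprintf("sparsity %g yields an empty graph (k = 0) for n = %d", s, n))
  }
  ut <- which(upper.tri(w), arr.ind = TRUE)
  weights <- w[ut]
  if (negative_weights == "zero") {
    weights[weights < 0] <- 0
  } else {
    weights <- abs(weights)
  }
  n_nonzero <- sum(weights > 0)
  if (k > n_nonzero) {
    warn(sprintf(
      "requested %d edges at sparsity %g but only %d non-zero weights; keeping all %d",
      k, s, n_nonzero, n_nonzero))
    k <- n_nonzero
  }
  ord <- order(-weights, ut[, 1], ut[, 2])
  chosen <- ord[seq_len(k)]
  from_edge_matrix(ut[chosen, , drop = FALSE], n, sparsity = s)
}
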