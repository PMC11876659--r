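GLOBAL_METRICS <- c("cp", "lp", "gamma", "lambda", "sigma", "eg", "eloc")
NODAL_METRICS <- c("nd", "nb", "ne")

#' Per-threshold topology of one weighted connectome
#'
#' Binarizes a weighted connectivity matrix at every sparsity-grid point
#' and computes the requested global (`cp`, `lp`, `gamma`, `lambda`,
#' `sigma`, `eg`, `eloc`) and nodal (`nd`, `nb`, `ne`) metrics.  The
#' small-world trio requires a degree-preserving null ensemble per graph
#' (`n_null` rewired networks), which dominates the run time; restrict
#' `metrics` when they are not needed.
#'
#' @param w A [connectivity_matrix()] or symmetric weight matrix.
#' @param grid Sparsity grid from [sparsity_grid()].
#' @param metrics Character vector of metric names.
#' @param n_null Null networks per graph for gamma/lambda/sigma.
#' @param seed RNG seed for the null ensembles.
#' @param negative_weights Passed to [binarize_at_sparsity()].
#' @param subject_id,modality,band Identifiers copied into the output;
#'   defaults are taken from `w`'s attributes.
#' @return A long tibble with columns `subject_id`, `modality`, `band`,
#'   `metric`, `scope` (`"global"` or `"nodal"`), `node` (`NA` for global
#'   metrics), `sparsity`, `value`.
#' @export
connectome_metrics <- function(w, grid = sparsity_grid(),
                               metrics = c(GLOBAL_METRICS, NODAL_METRICS),
                               n_null = 100, seed = 1L,
                               negative_weights = c("zero", "absolute"),
                               subject_id = NULL, modality = NULL,
                               band = NULL) {
  negative_weights <- match.arg(negative_weights)
  metrics <- match.arg(metrics, c(GLOBAL_METRICS, NODAL_METRICS),
                       several.ok = TRUE)
  subject_id <- subject_id %||% attr(w, "subject_id") %||% "subject"
  modality <- modality %||% attr(w, "modality") %||% "FC"
  band <- band %||% attr(w, "band") %||% "none"

  want_sw <- any(c("gamma", "lambda", "sigma") %in% metrics)
  rows <- purrr::map(seq_along(grid), function(gi) {
    s <- grid[gi]
    g <- binarize_at_sparsity(w, s, negative_weights = negative_weights)
    vals <- list()
    if ("cp" %in% metrics && !want_sw) vals$cp <- clustering_coefficient(g)$cp
    if (("lp" %in% metrics) && !want_sw) vals$lp <- characteristic_path_length(g)$lp
    if (want_sw) {
      sw <- normalized_small_world(g, n_null = n_null,
                                   seed = derive_seed(seed, 1000 * gi))
      vals$cp <- sw$cp
      vals$lp <- sw$lp
      vals$gamma <- sw$gamma
      vals$lambda <- sw$lambda
      vals$sigma <- sw$sigma
    }
    if (any(c("eg", "ne") %in% metrics)) {
      ne <- nodal_efficiency(g)
      vals$eg <- mean(ne)
    }
    if ("eloc" %in% metrics) vals$eloc <- local_efficiency(g)$eloc

    out <- tibble::tibble(metric = names(vals),
                          scope = "global",
                          node = NA_integer_,
                          sparsity = s,
                          value = unlist(vals, use.names = FALSE))
    out <- dplyr::filter(out, .data$metric %in% metrics)

    nodal <- list()
    if ("nd" %in% metrics) nodal$nd <- nodal_degree(g)
    if ("nb" %in% metrics) nodal$nb <- nodal_betweenness(g)
    if ("ne" %in% metrics) nodal$ne <- ne
    if (length(nodal) > 0) {
      n <- g$n_nodes
      nodal_tbl <- tibble::tibble(
        metric = rep(names(nodal), each = n),
        scope = "nodal",
        node = rep(seq_len(n), times = length(nodal)),
        sparsity = s,
        value = unlist(nodal, use.names = FALSE))
      out <- dplyr::bind_rows(out, nodal_tbl)
    }
    out
  })
  dplyr::bind_rows(rows) |>
    dplyr::mutate(subject_id = subject_id, modality = modality, band = band,
                  .before = 1)
}

#' Integrate metric curves to AUC values
#'
#' Collapses the per-threshold curves produced by [connectome_metrics()]
#' to one trapezoidal area-under-curve value per subject, modality, band,
#' metric and node.
#'
#' @param curves Long tibble from [connectome_metrics()] (any number of
#'   subjects bound together).
#' @return A tibble with columns `subject_id`, `modality`, `band`,
#'   `metric`, `scope`, `node`, `auc`.
#' @export
metric_auc <- function(curves) {
  curves |>
    dplyr::group_by(.data$subject_id, .data$modality, .data$band,
                    .data$metric, .data$scope, .data$node) |>
    dplyr::arrange(.data$sparsity, .by_group = TRUE) |>
    dplyr::summarise(auc = auc_over_sparsity(.data$value, .data$sparsity),
                     .groups = "drop")
}

#' Topology of a set of subject connectomes
#'
#' Maps [connectome_metrics()] over a named list of weighted matrices
#' (one per subject) and returns both the per-threshold curves and their
#' AUC table.  Per-subject null-ensemble seeds are derived from `seed` by
#' counter.
#'
#' @param matrices Named list of [connectivity_matrix()] objects (names =
#'   subject ids, used when a matrix carries no `subject_id` attribute).
#' @inheritParams connectome_metrics
#' @return A list with elements `curves` and `auc` (tibbles).
#' @export
cohort_metrics <- function(matrices, grid = sparsity_grid(),
                           metrics = c(GLOBAL_METRICS, NODAL_METRICS),
                           n_null = 100, seed = 1L,
                           negative_weights = "zero") {
  ids <- names(matrices) %||% as.character(seq_along(matrices))
  curves <- purrr::imap(matrices, function(w, nm) {
    i <- match(nm, ids)
    connectome_metrics(w, grid = grid, metrics = metrics, n_null = n_null,
                       seed = derive_seed(seed, 100000 + i),
                       negative_weights = negative_weights,
                       subject_id = attr(w, "subject_id") %||% nm)
  }) |>
    dplyr::bind_rows()
  list(curves = curves, auc = metric_auc(curves))
}
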