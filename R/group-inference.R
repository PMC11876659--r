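#' Residualize a response on covariates
#'
#' Ordinary-least-squares residuals of `y` on an intercept plus the given
#' covariates -- the covariate-adjustment step shared by the permutation
#' test and the partial correlations.
#'
#' @param y Numeric vector.
#' @param covariates Numeric matrix or data frame with one row per element
#'   of `y`, or `NULL` for intercept-only adjustment (mean-centering).
#' @return The residual vector.
#' @export
adjust_covariates <- function(y, covariates = NULL) {
  if (is.null(covariates)) return(y - mean(y))
  x <- as.matrix(covariates)
  storage.mode(x) <- "double"
  if (nrow(x) != length(y)) stop_validation("covariate rows must align with `y`")
  design <- cbind(`(Intercept)` = 1, x)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    dropped <- colnames(design)[qr_d$pivot[(qr_d$rank + 1):ncol(design)]]
    stop_validation(paste0("covariate design is rank-deficient; collinear columns: ",
                           paste(dropped, collapse = ", ")))
  }
  as.numeric(qr.resid(qr_d, y))
}

#' Covariate-adjusted permutation test for a two-group difference
#'
#' The test statistic is the difference of group means (first level minus
#' second level) of covariate-adjusted residuals (Freedman-Lane style:
#' responses are residualized on the covariates once, then group labels
#' are permuted, which is exchangeable under the null with fixed
#' covariates).  The two-tailed p-value is
#' `(1 + #permutations with |T| >= |T_obs|) / (n_perm + 1)`, so the
#' smallest achievable p is `1 / (n_perm + 1)`.
#'
#' @param values Numeric vector of responses (e.g. metric AUC values).
#' @param group Factor or character vector of group labels with exactly
#'   two levels.
#' @param covariates Optional covariate matrix/data frame (see
#'   [adjust_covariates()]).
#' @param n_perm Number of permutations (default 10000).
#' @param seed RNG seed.
#' @param levels Two group labels, difference taken as
#'   `levels[1] - levels[2]`; defaults to the factor levels or sorted
#'   unique labels.
#' @return A list of class `permutation_test` with `observed_stat`,
#'   `p_value`, `n_permutations`, `seed`.
#' @export
permutation_test <- function(values, group, covariates = NULL,
                             n_perm = 10000, seed = 1L, levels = NULL) {
  if (is.null(levels)) {
    levels <- if (is.factor(group)) base::levels(group) else sort(unique(group))
  }
  group <- as.character(group)
  if (length(levels) != 2 || !all(group %in% levels)) {
    stop_validation("`group` must contain exactly the two labels in `levels`")
  }
  g1 <- group == levels[1]
  n1 <- sum(g1)
  n2 <- sum(!g1)
  if (n1 < 2 || n2 < 2) stop_validation("each group needs at least 2 subjects")
  r <- adjust_covariates(values, covariates)
  observed <- mean(r[g1]) - mean(r[!g1])
  n <- length(r)
  total <- sum(r)
  perm_stats <- with_seed(seed, {
    idx <- vapply(seq_len(n_perm), function(i) sample.int(n, n1), integer(n1))
    sums <- colSums(matrix(r[idx], nrow = n1))
    sums / n1 - (total - sums) / n2
  })
  p <- (1 + sum(abs(perm_stats) >= abs(observed))) / (n_perm + 1)
  structure(list(observed_stat = observed, p_value = p,
                 n_permutations = n_perm, seed = seed,
                 levels = levels),
            class = "permutation_test")
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("Permutation test (%s - %s): stat = %.4g, p = %.4g (%d permutations)\n",
              x$levels[1], x$levels[2], x$observed_stat, x$p_value,
              x$n_permutations))
  invisible(x)
}

check_pvalues <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) {
    stop_validation("p-values must lie in (0, 1]")
  }
  invisible(p)
}

#' Multiple-comparison correction
#'
#' `bh_fdr()` applies the Benjamini-Hochberg step-up false-discovery-rate
#' procedure (monotonicity enforced by a cumulative minimum from the
#' largest rank); `bonferroni()` returns `min(1, m * p)`.
#'
#' @param p Vector of p-values in (0, 1].
#' @return Adjusted values (q-values for `bh_fdr()`).
#' @export
bh_fdr <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "BH")
}

#' @rdname bh_fdr
#' @export
bonferroni <- function(p) {
  check_pvalues(p)
  p.adjust(p, method = "bonferroni")
}

#' Partial correlation with covariates
#'
#' Pearson correlation of the two covariate-residualized vectors, with a
#' two-tailed p-value from the t distribution on `n - k - 2` degrees of
#' freedom (k = number of covariates).  With no covariates this is the
#' plain Pearson correlation test.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional covariate matrix/data frame.
#' @return A list with `r`, `p`, `df`, `n`.
#' @export
partial_correlation <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop_validation("`x` and `y` must have equal length")
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  if (n <= k + 3) {
    stop_validation(sprintf("need n > k + 3 observations (n = %d, k = %d)", n, k))
  }
  rx <- adjust_covariates(x, covariates)
  ry <- adjust_covariates(y, covariates)
  r <- cor(rx, ry)
  df <- n - k - 2
  t_stat <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(t_stat), df)
  list(r = r, p = p, df = df, n = n)
}

sex_to_numeric <- function(sex) {
  out <- dplyr::case_when(
    sex %in% c("M", "m", "1", 1) ~ 1,
    sex %in% c("F", "f", "0", 0) ~ 0,
    .default = NA_real_
  )
  if (anyNA(out)) stop_validation("sex values must be in {M, F, 0, 1}")
  out
}

covariate_matrix <- function(manifest, covariates) {
  if (length(covariates) == 0) return(NULL)
  missing_cols <- setdiff(covariates, names(manifest))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("manifest lacks covariate columns: ",
                           paste(missing_cols, collapse = ", ")))
  }
  cov <- manifest[covariates]
  if ("sex" %in% covariates) cov$sex <- sex_to_numeric(cov$sex)
  as.matrix(cov)
}

#' Compare metric AUC values between groups
#'
#' Runs the covariate-adjusted permutation test for every metric (and
#' node, for nodal metrics) in an AUC table, then corrects for multiple
#' comparisons within families defined by `family_vars` (default:
#' modality x band x scope, so global metrics of one network form one
#' family and each nodal-metric map another).
#'
#' @param auc AUC tibble from [metric_auc()] / [cohort_metrics()].
#' @param manifest Cohort manifest with `subject_id`, `group` (labels
#'   `"patient"` and `"control"`), and any covariate columns.
#' @param covariates Manifest columns to adjust for (default age and sex).
#' @param n_perm Permutations per test.
#' @param correction `"bonferroni"` or `"bh"`.
#' @param alpha Significance threshold applied to the adjusted values.
#' @param family_vars Columns defining a correction family.
#' @param seed Master seed (per-test seeds derived by counter).
#' @return A tibble with one row per test: identifiers, `observed_stat`
#'   (patient minus control adjusted means), `p`, `adjusted`,
#'   `significant`.
#' @export
compare_groups <- function(auc, manifest, covariates = c("age", "sex"),
                           n_perm = 10000,
                           correction = c("bonferroni", "bh"),
                           alpha = 0.05,
                           family_vars = c("modality", "band", "scope"),
                           seed = 1L) {
  correction <- match.arg(correction)
  manifest <- dplyr::select(manifest, dplyr::all_of(
    unique(c("subject_id", "group", covariates))))
  data <- dplyr::inner_join(auc, manifest, by = "subject_id") |>
    dplyr::arrange(.data$modality, .data$band, .data$metric, .data$scope,
                   .data$node)
  keys <- dplyr::distinct(data, .data$modality, .data$band, .data$metric,
                          .data$scope, .data$node)
  results <- purrr::pmap(
    list(keys$modality, keys$band, keys$metric, keys$scope, keys$node,
         seq_len(nrow(keys))),
    function(mod, bnd, met, scp, nod, i) {
      rows <- data[data$modality == mod & data$band == bnd &
                     data$metric == met & data$scope == scp &
                     (is.na(nod) | data$node %in% nod), ]
      if (is.na(nod)) rows <- rows[is.na(rows$node), ]
      cov <- covariate_matrix(rows, covariates)
      pt_res <- permutation_test(rows$auc, rows$group, covariates = cov,
                                 n_perm = n_perm,
                                 seed = derive_seed(seed, i),
                                 levels = c("patient", "control"))
      tibble::tibble(modality = mod, band = bnd, metric = met, scope = scp,
                     node = nod, observed_stat = pt_res$observed_stat,
                     p = pt_res$p_value)
    }) |>
    dplyr::bind_rows()
  adjust_fun <- if (correction == "bonferroni") bonferroni else bh_fdr
  results |>
    dplyr::group_by(dplyr::across(dplyr::all_of(family_vars))) |>
    dplyr::mutate(adjusted = adjust_fun(.data$p)) |>
    dplyr::ungroup() |>
    dplyr::mutate(correction = correction,
                  significant = .data$adjusted < alpha)
}

#' Partial correlations between metric AUC values and clinical variables
#'
#' For each metric in `auc` (optionally restricted to an "altered" subset)
#' and each clinical variable, computes the covariate-adjusted partial
#' correlation within one group (by default the patients, where the
#' clinical scales are informative), with FDR or Bonferroni correction
#' across the whole correlation family.
#'
#' @param auc AUC tibble.
#' @param manifest Cohort manifest including the clinical columns.
#' @param clinical_vars Clinical column names to correlate against.
#' @param metrics Optional tibble of metric keys (columns among
#'   `modality`, `band`, `metric`, `scope`, `node`) to restrict to.
#' @param covariates Covariate columns (default age, sex).
#' @param correction `"bh"` or `"bonferroni"`.
#' @param alpha Threshold on the adjusted values.
#' @param group Group to correlate within (default `"patient"`).
#' @return A tibble with identifiers, `clinical_var`, `r`, `p`, `q`,
#'   `significant`.
#' @export
correlate_clinical <- function(auc, manifest, clinical_vars,
                               metrics = NULL,
                               covariates = c("age", "sex"),
                               correction = c("bh", "bonferroni"),
                               alpha = 0.05, group = "patient") {
  correction <- match.arg(correction)
  if (!is.null(metrics)) {
    auc <- dplyr::semi_join(auc, metrics,
                            by = intersect(names(metrics), names(auc)))
  }
  subj <- dplyr::filter(manifest, .data$group == !!group)
  data <- dplyr::inner_join(auc, subj, by = "subject_id")
  keys <- dplyr::distinct(data, .data$modality, .data$band, .data$metric,
                          .data$scope, .data$node)
  results <- purrr::pmap(
    list(keys$modality, keys$band, keys$metric, keys$scope, keys$node),
    function(mod, bnd, met, scp, nod) {
      rows <- data[data$modality == mod & data$band == bnd &
                     data$metric == met & data$scope == scp, ]
      rows <- if (is.na(nod)) rows[is.na(rows$node), ] else rows[rows$node %in% nod, ]
      cov <- covariate_matrix(rows, covariates)
      purrr::map(clinical_vars, function(cv) {
        pc <- partial_correlation(rows$auc, rows[[cv]], cov)
        tibble::tibble(modality = mod, band = bnd, metric = met,
                       scope = scp, node = nod, clinical_var = cv,
                       r = pc$r, p = pc$p)
      }) |> dplyr::bind_rows()
    }) |>
    dplyr::bind_rows()
  adjust_fun <- if (correction == "bonferroni") bonferroni else bh_fdr
  dplyr::mutate(results, q = adjust_fun(.data$p),
                significant = .data$q < alpha)
}
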