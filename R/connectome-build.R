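#' Frequency bands for resting-state fMRI analysis
#'
#' `frequency_band()` builds a validated band; `fmri_bands()` returns the
#' three bands used throughout the package: the conventional full band
#' (0.01-0.1 Hz) and the slow-4 (0.027-0.073 Hz) and slow-5
#' (0.01-0.027 Hz) sub-bands.
#'
#' @param low_hz,high_hz Band edges in Hz, `0 <= low_hz < high_hz`.
#' @param name Band label.
#' @return A `frequency_band` object (named list).
#' @export
frequency_band <- function(low_hz, high_hz, name) {
  if (!is_scalar_num(low_hz) || low_hz < 0) stop_config("`low_hz` must be >= 0")
  if (!is_scalar_num(high_hz) || high_hz <= low_hz) {
    stop_config("`high_hz` must exceed `low_hz`")
  }
  structure(list(low_hz = low_hz, high_hz = high_hz, name = name),
            class = "frequency_band")
}

#' @rdname frequency_band
#' @export
fmri_bands <- function() {
  list(
    full = frequency_band(0.01, 0.1, "full"),
    slow4 = frequency_band(0.027, 0.073, "slow4"),
    slow5 = frequency_band(0.01, 0.027, "slow5")
  )
}

# Remove a least-squares linear trend from each column.
detrend_columns <- function(x) {
  t_idx <- seq_len(nrow(x))
  fit <- stats::lm.fit(cbind(1, t_idx), x)
  matrix(fit$residuals, nrow = nrow(x), dimnames = dimnames(x))
}

#' Ideal (rectangular) bandpass filter for node time series
#'
#' Demeans each column, zeroes every discrete-Fourier coefficient whose
#' frequency falls outside the band, and inverse-transforms.  The boundary
#' convention is that a coefficient exactly at a band edge belongs to the
#' band *below* it: frequency f is retained when
#' `low_hz < f <= high_hz`.  This makes the adjacent slow-5 and slow-4
#' bands, which abut at 0.027 Hz, exactly disjoint and exhaustive.  The
#' filter is exactly idempotent.
#'
#' @param x T x N numeric matrix of node time series (columns = nodes).
#' @param band A [frequency_band()].
#' @param tr_seconds Repetition time in seconds; the sampling interval.
#' @param detrend If `TRUE`, remove a linear trend from each column before
#'   filtering (off by default so the operator is a pure band selection).
#' @return A filtered matrix of the same shape, with attribute `"band"`
#'   set to the band name.
#' @export
bandpass_filter <- function(x, band, tr_seconds, detrend = FALSE) {
  stopifnot(is.matrix(x), inherits(band, "frequency_band"))
  nyquist <- 1 / (2 * tr_seconds)
  if (band$high_hz > nyquist + 1e-12) {
    stop_config(sprintf(
      "band '%s' (%g-%g Hz) exceeds the Nyquist frequency %g Hz at TR = %g s",
      band$name, band$low_hz, band$high_hz, nyquist, tr_seconds))
  }
  n_t <- nrow(x)
  x <- scale(x, center = TRUE, scale = FALSE)
  if (detrend) x <- detrend_columns(x)
  coeffs <- mvfft(x)
  k <- 0:(n_t - 1)
  freq <- pmin(k, n_t - k) / (n_t * tr_seconds)
  keep <- freq > band$low_hz & freq <= band$high_hz
  out <- Re(mvfft(coeffs * keep, inverse = TRUE)) / n_t
  dimnames(out) <- dimnames(x)
  attr(out, "band") <- band$name
  out
}

#' Connectivity matrix container
#'
#' A symmetric N x N weighted matrix with zero diagonal, tagged with its
#' modality (`"FC"` for functional, `"SC"` for structural), frequency band
#' and subject.  Functional entries must lie in `[-1, 1]`, structural
#' (fractional anisotropy) entries in `[0, 1]`; symmetry is enforced to
#' within 1e-10.
#'
#' @param values Numeric N x N matrix.
#' @param modality `"FC"` or `"SC"`.
#' @param band Band label (`"full"`, `"slow4"`, `"slow5"` or `"none"`).
#' @param subject_id Optional subject identifier.
#' @return A `connectivity_matrix` (a matrix with attributes).
#' @export
connectivity_matrix <- function(values, modality = c("FC", "SC"),
                                band = "none", subject_id = NULL) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || nrow(values) != ncol(values)) {
    stop_validation("connectivity values must be a square matrix")
  }
  if (asymmetry(values) > 1e-10) {
    stop_validation("connectivity matrix is not symmetric (tolerance 1e-10)")
  }
  if (any(abs(diag(values)) > 1e-10)) {
    stop_validation("connectivity matrix must have a zero diagonal")
  }
  rng <- if (modality == "FC") c(-1, 1) else c(0, 1)
  if (min(values) < rng[1] - 1e-10 || max(values) > rng[2] + 1e-10) {
    stop_validation(sprintf("%s entries must lie in [%g, %g]",
                            modality, rng[1], rng[2]))
  }
  structure(values, class = c("connectivity_matrix", "matrix", "array"),
            modality = modality, band = band %||% "none",
            subject_id = subject_id)
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat(sprintf("<connectivity_matrix> %s (band: %s) %d x %d%s\n",
              attr(x, "modality"), attr(x, "band"), nrow(x), ncol(x),
              if (!is.null(attr(x, "subject_id")))
                paste0(" subject: ", attr(x, "subject_id")) else ""))
  invisible(x)
}

#' Functional connectivity matrix from node time series
#'
#' Pearson correlation between every pair of node time series; the
#' diagonal is forced to zero.  Constant (zero-variance) columns signal a
#' degenerate region: their correlations are set to 0 and a warning is
#' raised.
#'
#' @param x T x N numeric matrix (T >= 3).  A `"band"` attribute (as left
#'   by [bandpass_filter()]) is propagated.
#' @param band Band label; defaults to the `"band"` attribute of `x`.
#' @param subject_id Optional subject identifier.
#' @return A [connectivity_matrix()] with modality `"FC"`.
#' @export
fc_matrix <- function(x, band = NULL, subject_id = NULL) {
  stopifnot(is.matrix(x))
  if (nrow(x) < 3) stop_validation("need at least 3 time points for Pearson correlation")
  band <- band %||% attr(x, "band") %||% "none"
  sds <- apply(x, 2, sd)
  constant <- sds == 0 | !is.finite(sds)
  r <- suppressWarnings(cor(x))
  if (any(constant)) {
    warn(sprintf("%d constant node time series; their correlations are set to 0 (nodes: %s)",
                 sum(constant), paste(which(constant), collapse = ", ")))
    r[constant, ] <- 0
    r[, constant] <- 0
  }
  r <- (r + t(r)) / 2
  r <- pmin(pmax(r, -1), 1)
  diag(r) <- 0
  connectivity_matrix(r, modality = "FC", band = band, subject_id = subject_id)
}

#' Read and write delimited matrices
#'
#' Matrices are stored as tab-delimited text with no header, one row per
#' line -- the interchange format for per-subject time series and
#' connectivity matrices.
#'
#' @param x Numeric matrix.
#' @param path File path.
#' @return `read_matrix_tsv()` returns a numeric matrix.
#' @export
write_matrix_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "connectopath_io_error")
  }
  df <- readr::read_tsv(path, col_names = FALSE, show_col_types = FALSE,
                        progress = FALSE)
  m <- as.matrix(df)
  dimnames(m) <- NULL
  if (!is.numeric(m)) stop_validation(paste0("non-numeric values in ", path))
  m
}

#' Load and validate a structural (FA) connectivity matrix
#'
#' Reads a tab-delimited square matrix of region-pair mean fractional
#' anisotropy values, checks the dimension, symmetry (tolerance 1e-6,
#' after which the matrix is exactly symmetrized as `(W + t(W)) / 2`) and
#' the FA range `[0, 1]`, and zeroes the diagonal.
#'
#' @param path Path to the matrix file.
#' @param expected_n Expected number of nodes, or `NULL` to accept any.
#' @param subject_id Optional subject identifier.
#' @return A [connectivity_matrix()] with modality `"SC"`.
#' @export
load_sc_matrix <- function(path, expected_n = NULL, subject_id = NULL) {
  w <- read_matrix_tsv(path)
  if (nrow(w) != ncol(w)) {
    stop_validation(sprintf("%s: matrix is %d x %d, not square",
                            path, nrow(w), ncol(w)))
  }
  if (!is.null(expected_n) && nrow(w) != expected_n) {
    stop_validation(sprintf("%s: expected %d nodes, found %d",
                            path, expected_n, nrow(w)))
  }
  if (anyNA(w)) stop_validation(paste0(path, ": missing values in FA matrix"))
  asym <- abs(w - t(w))
  if (max(asym) > 1e-6) {
    idx <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop_validation(sprintf(
      "%s: asymmetry %.3g at (%d, %d) exceeds tolerance 1e-6",
      path, max(asym), idx[1], idx[2]))
  }
  w <- (w + t(w)) / 2
  diag(w) <- 0
  out_of_range <- which(w < 0 | w > 1, arr.ind = TRUE)
  if (nrow(out_of_range) > 0) {
    stop_validation(sprintf(
      "%s: FA value %.3g at (%d, %d) outside [0, 1]",
      path, w[out_of_range[1, , drop = FALSE]],
      out_of_range[1, 1], out_of_range[1, 2]))
  }
  connectivity_matrix(w, modality = "SC", subject_id = subject_id)
}
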