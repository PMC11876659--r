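#' Configuration for a synthetic two-group connectome cohort
#'
#' Describes a simulated case-control study: a modular small-world
#' structural template shared by all subjects, per-subject fractional
#' anisotropy (FA) matrices and node time series sampled around it, and
#' clinical scores generated from a known linear mediation structure.  The
#' patient group's template additionally receives long-range
#' cross-community "shortcut" edges, which shorten the characteristic path
#' length and raise global efficiency relative to controls -- a planted,
#' recoverable group effect.
#'
#' @param n_patients,n_controls Group sizes (defaults 32 and 31).
#' @param n_nodes Number of network nodes (default 116, the size of the
#'   AAL116 parcellation).
#' @param n_timepoints Number of fMRI volumes per subject (default 230,
#'   roughly an eight-minute run at TR = 2 s).
#' @param tr_seconds Repetition time in seconds (default 2).
#' @param community_sizes Integer vector of community sizes summing to
#'   `n_nodes`; `NULL` splits the nodes into 8 near-equal communities.
#' @param rewiring_prob Probability that a within-community edge of the
#'   template is rewired to a random cross-community pair
#'   (Watts-Strogatz-style), in `[0, 1]`.
#' @param group_shortcut_fraction Extra cross-community edges added to the
#'   patient template, as a fraction of the number of within-community
#'   edges.  Zero removes the planted group effect.
#' @param fa_noise_sd Standard deviation of the symmetric Gaussian noise
#'   added to the template to obtain each subject's FA matrix.
#' @param mediation_params List with elements `a`, `b`, `c_prime`,
#'   `noise_sd_m`, `noise_sd_y`: coefficients of the planted linear
#'   mediation model M = a X + eM, Y = c' X + b M + eY.  Defaults plant no
#'   mediation (a = b = 0).
#' @param seed Master seed for all randomness in the generator.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @seealso [generate_cohort()], [make_structural_template()]
#' @export
cohort_config <- function(n_patients = 32L,
                          n_controls = 31L,
                          n_nodes = 116L,
                          n_timepoints = 230L,
                          tr_seconds = 2,
                          community_sizes = NULL,
                          rewiring_prob = 0.1,
                          group_shortcut_fraction = 0.05,
                          fa_noise_sd = 0.05,
                          mediation_params = list(a = 0, b = 0, c_prime = 0,
                                                  noise_sd_m = 1, noise_sd_y = 1),
                          seed = 1L) {
  if (is.null(community_sizes)) {
    n_comm <- min(8L, n_nodes)
    base <- n_nodes %/% n_comm
    community_sizes <- rep(base, n_comm)
    extra <- n_nodes - sum(community_sizes)
    if (extra > 0) {
      community_sizes[seq_len(extra)] <- community_sizes[seq_len(extra)] + 1L
    }
  }
  cfg <- list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_nodes = as.integer(n_nodes),
    n_timepoints = as.integer(n_timepoints),
    tr_seconds = tr_seconds,
    community_sizes = as.integer(community_sizes),
    rewiring_prob = rewiring_prob,
    group_shortcut_fraction = group_shortcut_fraction,
    fa_noise_sd = fa_noise_sd,
    mediation_params = mediation_params,
    seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_patients", "n_controls", "n_nodes", "n_timepoints")) {
    if (!is_count(cfg[[f]])) stop_config(paste0("`", f, "` must be a positive integer"))
  }
  if (!is_scalar_num(cfg$tr_seconds) || cfg$tr_seconds <= 0) {
    stop_config("`tr_seconds` must be a positive number")
  }
  if (sum(cfg$community_sizes) != cfg$n_nodes) {
    stop_config(sprintf(
      "`community_sizes` must sum to n_nodes: sum is %d, n_nodes is %d",
      sum(cfg$community_sizes), cfg$n_nodes))
  }
  if (any(cfg$community_sizes < 1)) stop_config("all community sizes must be positive")
  if (!is_scalar_num(cfg$rewiring_prob) ||
      cfg$rewiring_prob < 0 || cfg$rewiring_prob > 1) {
    stop_config("`rewiring_prob` must be in [0, 1]")
  }
  if (!is_scalar_num(cfg$group_shortcut_fraction) || cfg$group_shortcut_fraction < 0) {
    stop_config("`group_shortcut_fraction` must be >= 0")
  }
  if (!is_scalar_num(cfg$fa_noise_sd) || cfg$fa_noise_sd < 0) {
    stop_config("`fa_noise_sd` must be >= 0")
  }
  mp <- cfg$mediation_params
  need <- c("a", "b", "c_prime", "noise_sd_m", "noise_sd_y")
  if (!all(need %in% names(mp))) {
    stop_config(paste0("`mediation_params` must contain: ",
                       paste(need, collapse = ", ")))
  }
  if (mp$noise_sd_m < 0 || mp$noise_sd_y < 0) {
    stop_config("mediation noise standard deviations must be >= 0")
  }
  invisible(cfg)
}

#' Read or write a cohort configuration as YAML
#'
#' @param path Path to a YAML file.
#' @return `read_cohort_config()` returns a [cohort_config()] object.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @param config A [cohort_config()] object.
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

community_membership <- function(community_sizes) {
  rep(seq_along(community_sizes), community_sizes)
}

#' Modular small-world structural template
#'
#' Builds a symmetric, zero-diagonal weight matrix that is dense within
#' communities and sparse between them: every within-community node pair
#' receives a weight drawn uniformly from `[0.5, 0.9]`, and a fraction
#' `rewiring_prob` of those edges is then rewired to uniformly chosen
#' cross-community pairs (Watts-Strogatz-style), creating the long-range
#' shortcuts that give the template its small-world character after
#' thresholding.
#'
#' @param n_nodes Number of nodes.
#' @param community_sizes Integer vector summing to `n_nodes`.
#' @param rewiring_prob Rewiring probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return An `n_nodes` x `n_nodes` numeric matrix with a
#'   `"membership"` attribute giving each node's community.
#' @export
make_structural_template <- function(n_nodes, community_sizes, rewiring_prob,
                                     seed = 1L) {
  cfg <- list(n_nodes = as.integer(n_nodes), n_patients = 1L, n_controls = 1L,
              n_timepoints = 3L, tr_seconds = 2,
              community_sizes = as.integer(community_sizes),
              rewiring_prob = rewiring_prob, group_shortcut_fraction = 0,
              fa_noise_sd = 0,
              mediation_params = list(a = 0, b = 0, c_prime = 0,
                                      noise_sd_m = 1, noise_sd_y = 1))
  validate_cohort_config(cfg)
  membership <- community_membership(community_sizes)
  w <- matrix(0, n_nodes, n_nodes)
  ut <- which(upper.tri(w), arr.ind = TRUE)
  same <- membership[ut[, 1]] == membership[ut[, 2]]
  with_seed(seed, {
    n_within <- sum(same)
    weights <- runif(n_within, 0.5, 0.9)
    rewire <- runif(n_within) < rewiring_prob
    cross_idx <- which(!same)
    keep_rows <- ut[same, , drop = FALSE][!rewire, , drop = FALSE]
    keep_w <- weights[!rewire]
    n_moved <- sum(rewire)
    if (n_moved > 0) {
      target <- sample(cross_idx, n_moved, replace = FALSE)
      moved_rows <- ut[target, , drop = FALSE]
      w[moved_rows] <- weights[rewire]
    }
    w[keep_rows] <- keep_w
  })
  w <- w + t(w)
  attr(w, "membership") <- membership
  w
}

# Add high-weight cross-community shortcut edges to a template.  This is the
# planted patient-group effect: extra long-range connections lower the
# characteristic path length and raise global efficiency of the binarized
# networks.
add_group_shortcuts <- function(template, fraction, seed = 1L) {
  if (fraction <= 0) return(template)
  membership <- attr(template, "membership")
  if (is.null(membership)) stop_config("template lacks a `membership` attribute")
  ut <- which(upper.tri(template), arr.ind = TRUE)
  same <- membership[ut[, 1]] == membership[ut[, 2]]
  n_extra <- round_half_away(fraction * sum(same))
  candidates <- which(!same & template[ut] == 0)
  if (length(candidates) < n_extra) n_extra <- length(candidates)
  out <- template
  with_seed(seed, {
    chosen <- sample(candidates, n_extra, replace = FALSE)
    rows <- ut[chosen, , drop = FALSE]
    ws <- runif(n_extra, 0.6, 0.9)
    out[rows] <- ws
    out[rows[, c(2, 1), drop = FALSE]] <- ws
  })
  attr(out, "membership") <- membership
  out
}

#' Sample a subject structural (FA) connectivity matrix
#'
#' Adds symmetric Gaussian noise to a template weight matrix and clips the
#' result to the fractional-anisotropy range `[0, 1]`, keeping the diagonal
#' at zero.
#'
#' @param template Symmetric, zero-diagonal weight matrix.
#' @param fa_noise_sd Noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @param subject_id Optional subject identifier.
#' @return A [connectivity_matrix()] with modality `"SC"`.
#' @export
sample_subject_sc <- function(template, fa_noise_sd, seed = 1L,
                              subject_id = NULL) {
  if (!is_scalar_num(fa_noise_sd) || fa_noise_sd < 0) {
    stop_config("`fa_noise_sd` must be >= 0")
  }
  n <- nrow(template)
  w <- unclass(template)
  attr(w, "membership") <- NULL
  if (fa_noise_sd > 0) {
    noise <- matrix(0, n, n)
    with_seed(seed, {
      noise[upper.tri(noise)] <- rnorm(n * (n - 1) / 2, sd = fa_noise_sd)
    })
    noise <- noise + t(noise)
    w <- w + noise
  }
  w <- pmin(pmax(w, 0), 1)
  diag(w) <- 0
  connectivity_matrix(w, modality = "SC", subject_id = subject_id)
}

# Load the diagonal of a template until the matrix is positive-definite, so
# it can serve as a multivariate-normal covariance.
loaded_covariance <- function(template, tol = 1e-8) {
  s <- unclass(template)
  attr(s, "membership") <- NULL
  diag(s) <- diag(s) + 1
  repeat {
    ev <- min(eigen(s, symmetric = TRUE, only.values = TRUE)$values)
    if (ev > tol) break
    diag(s) <- diag(s) + (tol - ev) + 0.05
  }
  s
}

#' Sample a subject node time-series matrix
#'
#' Draws `n_timepoints` independent observations from a zero-mean
#' multivariate normal whose covariance is the template with its diagonal
#' loaded until positive-definite.  Node pairs with large template weights
#' therefore show large sample Pearson correlations.
#'
#' @param template Symmetric weight matrix (zero diagonal allowed; the
#'   diagonal is loaded internally).
#' @param n_timepoints Number of time points T (>= 3).
#' @param seed RNG seed.
#' @return A T x N numeric matrix.
#' @export
sample_subject_timeseries <- function(template, n_timepoints, seed = 1L) {
  if (!is_count(n_timepoints) || n_timepoints < 3) {
    stop_config("`n_timepoints` must be an integer >= 3 (Pearson correlation is degenerate below)")
  }
  if (asymmetry(unclass(template)) > 1e-10) {
    stop_config("`template` must be symmetric")
  }
  sigma <- loaded_covariance(template)
  with_seed(seed, {
    MASS::mvrnorm(n = n_timepoints, mu = rep(0, nrow(sigma)), Sigma = sigma)
  })
}

#' Generate clinical mediator and outcome values from a linear mediation model
#'
#' Implements the generating side of the Baron-Kenny model:
#' `M = a * X + eM`, `Y = c' * X + b * M + eY`, with independent Gaussian
#' noise.  With zero noise the relations are exact and the total effect of
#' X on Y equals `c' + a * b`.
#'
#' @param x_value Numeric vector of independent-variable values.
#' @param mediation_params List with `a`, `b`, `c_prime`, `noise_sd_m`,
#'   `noise_sd_y`.
#' @param seed RNG seed.
#' @return A tibble with columns `m` and `y`, one row per element of
#'   `x_value`.
#' @export
sample_clinical <- function(x_value, mediation_params, seed = 1L) {
  mp <- mediation_params
  if (mp$noise_sd_m < 0 || mp$noise_sd_y < 0) {
    stop_config("mediation noise standard deviations must be >= 0")
  }
  n <- length(x_value)
  with_seed(seed, {
    m <- mp$a * x_value + rnorm(n, sd = mp$noise_sd_m)
    y <- mp$c_prime * x_value + mp$b * m + rnorm(n, sd = mp$noise_sd_y)
  })
  tibble::tibble(m = m, y = y)
}

rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  out <- rnorm(n, mean, sd)
  bad <- which(out < lower | out > upper)
  guard <- 0
  while (length(bad) > 0 && guard < 1000) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- which(out < lower | out > upper)
    guard <- guard + 1
  }
  pmin(pmax(out, lower), upper)
}

# Clinical score distributions.  Patients follow the case-series means and
# spreads of a chronic low back-related leg pain cohort (VAS ~5.8, BI ~88,
# JOA ~14, Fugl-Meyer ~20, duration ~33 months, two-point discrimination
# ~25 mm hands / ~30 mm feet); controls sit at the healthy end of each
# instrument.  All scores are clipped to instrument bounds.
sample_clinical_scores <- function(n, group) {
  if (group == "patient") {
    tibble::tibble(
      vas = rtrunc_norm(n, 5.78, 0.95, 0, 10),
      bi = rtrunc_norm(n, 87.66, 11.98, 0, 100),
      joa = rtrunc_norm(n, 13.94, 5.07, -6, 29),
      fugl_meyer = rtrunc_norm(n, 19.62, 2.38, 0, 34),
      duration_months = rtrunc_norm(n, 33.31, 46.12, 3, Inf),
      pd2_rh = rtrunc_norm(n, 25.53, 5.73, 0, Inf),
      pd2_lh = rtrunc_norm(n, 25.81, 5.79, 0, Inf),
      pd2_rf = rtrunc_norm(n, 29.97, 7.87, 0, Inf),
      pd2_lf = rtrunc_norm(n, 30.25, 5.91, 0, Inf)
    )
  } else {
    tibble::tibble(
      vas = rtrunc_norm(n, 0.3, 0.3, 0, 10),
      bi = rtrunc_norm(n, 99, 1.5, 0, 100),
      joa = rtrunc_norm(n, 27, 1.5, -6, 29),
      fugl_meyer = rtrunc_norm(n, 22, 1.5, 0, 34),
      duration_months = rep(0, n),
      pd2_rh = rtrunc_norm(n, 18, 4, 0, Inf),
      pd2_lh = rtrunc_norm(n, 18, 4, 0, Inf),
      pd2_rf = rtrunc_norm(n, 22, 5, 0, Inf),
      pd2_lf = rtrunc_norm(n, 22, 5, 0, Inf)
    )
  }
}

#' Generate a synthetic two-group cohort on disk
#'
#' Writes one tab-delimited time-series file (`<id>_ts.tsv`) and one FA
#' matrix file (`<id>_sc.tsv`) per subject, plus a `manifest.csv` with
#' group labels, covariates and clinical scores.  Patients and controls
#' share a modular small-world template; the patient template additionally
#' carries cross-community shortcut edges (see [cohort_config()]).  When
#' the configured mediation coefficients are non-zero, the planted (X, M,
#' Y) triplet is carried by the `vas`, `fugl_meyer` and `pd2_rf` columns
#' (standardized X, with M and Y perturbations added before clipping); all
#' other clinical scores are independent noise within instrument bounds.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest as a tibble (invisibly written to
#'   `manifest.csv`), with attributes `ground_truth` (templates, planted
#'   effect directions, mediation parameters) and `out_dir`.
#' @export
generate_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "cohort_config"))
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    abort(paste0("cannot write to output directory: ", out_dir),
          class = "connectopath_io_error")
  }
  seed <- config$seed
  template_control <- make_structural_template(
    config$n_nodes, config$community_sizes, config$rewiring_prob,
    seed = derive_seed(seed, 1))
  template_patient <- add_group_shortcuts(
    template_control, config$group_shortcut_fraction,
    seed = derive_seed(seed, 2))

  n_total <- config$n_patients + config$n_controls
  group <- c(rep("patient", config$n_patients),
             rep("control", config$n_controls))
  subject_id <- sprintf("sub%03d", seq_len(n_total))
  sex <- c(rep_len(c("M", "F"), config$n_patients),
           rep_len(c("M", "F"), config$n_controls))
  age <- with_seed(derive_seed(seed, 3),
                   rtrunc_norm(n_total, 52, 7, 35, 65))

  scores <- with_seed(derive_seed(seed, 4), {
    dplyr::bind_rows(
      sample_clinical_scores(config$n_patients, "patient"),
      sample_clinical_scores(config$n_controls, "control")
    )
  })

  mp <- config$mediation_params
  if (mp$a != 0 || mp$b != 0 || mp$c_prime != 0) {
    x_latent <- as.numeric(scale(scores$vas))
    my <- sample_clinical(x_latent, mp, seed = derive_seed(seed, 5))
    scores$fugl_meyer <- pmin(pmax(scores$fugl_meyer + my$m, 0), 34)
    scores$pd2_rf <- pmax(scores$pd2_rf + my$y, 0)
  }

  for (i in seq_len(n_total)) {
    tmpl <- if (group[i] == "patient") template_patient else template_control
    sc <- sample_subject_sc(tmpl, config$fa_noise_sd,
                            seed = derive_seed(seed, 1000 + i),
                            subject_id = subject_id[i])
    ts <- sample_subject_timeseries(tmpl, config$n_timepoints,
                                    seed = derive_seed(seed, 5000 + i))
    write_matrix_tsv(unclass(sc), file.path(out_dir, paste0(subject_id[i], "_sc.tsv")))
    write_matrix_tsv(ts, file.path(out_dir, paste0(subject_id[i], "_ts.tsv")))
  }

  manifest <- dplyr::bind_cols(
    tibble::tibble(subject_id = subject_id, group = group,
                   age = round(age, 1), sex = sex),
    dplyr::mutate(scores, dplyr::across(dplyr::everything(), ~ round(.x, 2)))
  )
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))

  attr(manifest, "ground_truth") <- list(
    template_patient = template_patient,
    template_control = template_control,
    planted_effects = c(eg = "increase", lp = "decrease"),
    mediation_params = mp
  )
  attr(manifest, "out_dir") <- out_dir
  manifest
}
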