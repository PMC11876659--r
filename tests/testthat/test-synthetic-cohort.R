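test_that("cohort_config validates its fields", {
  expect_s3_class(cohort_config(), "cohort_config")
  expect_error(cohort_config(n_nodes = 10, community_sizes = c(4, 4)),
               class = "connectopath_config_error")
  expect_error(cohort_config(rewiring_prob = 1.5),
               class = "connectopath_config_error")
  expect_error(cohort_config(fa_noise_sd = -0.1),
               class = "connectopath_config_error")
  cfg <- cohort_config(n_nodes = 116)
  expect_equal(sum(cfg$community_sizes), 116)
  expect_length(cfg$community_sizes, 8)
})

test_that("structural template is symmetric, modular, and seed-deterministic", {
  t0 <- make_structural_template(30, c(10, 10, 10), 0, seed = 4)
  membership <- rep(1:3, each = 10)
  expect_equal(t0, t(t0), ignore_attr = TRUE)
  expect_equal(diag(t0), rep(0, 30))
  cross <- outer(membership, membership, "!=")
  expect_equal(sum(t0[cross]), 0)  # no rewiring: block-diagonal
  within <- upper.tri(t0) & !cross
  expect_true(all(t0[within] >= 0.5 & t0[within] <= 0.9))

  t1 <- make_structural_template(30, c(10, 10, 10), 0.2, seed = 4)
  t2 <- make_structural_template(30, c(10, 10, 10), 0.2, seed = 4)
  expect_identical(t1, t2)
  expect_gt(sum(t1[cross]), 0)  # rewired weight crossed communities
  # rewiring moves edges, it does not add them
  expect_equal(sum(t1[upper.tri(t1)] > 0), sum(t0[upper.tri(t0)] > 0))

  expect_error(make_structural_template(30, c(10, 10), 0.1),
               class = "connectopath_config_error")
})

test_that("subject FA matrices are clipped, symmetric perturbations of the template", {
  tmpl <- make_structural_template(20, c(10, 10), 0.1, seed = 6)
  exact <- sample_subject_sc(tmpl, 0, seed = 1)
  expect_equal(unclass(exact), unclass(tmpl), ignore_attr = TRUE)

  noisy <- sample_subject_sc(tmpl, 0.05, seed = 2)
  expect_s3_class(noisy, "connectivity_matrix")
  expect_true(min(noisy) >= 0 && max(noisy) <= 1)
  expect_equal(unclass(noisy), t(unclass(noisy)), ignore_attr = TRUE)
  expect_error(sample_subject_sc(tmpl, -1), class = "connectopath_config_error")

  # law of large numbers on entries far from the clipping bounds
  sd <- 0.05
  draws <- lapply(1:100, function(i) unclass(sample_subject_sc(tmpl, sd, seed = i)))
  avg <- Reduce(`+`, draws) / length(draws)
  interior <- upper.tri(tmpl) & tmpl > 4 * sd & tmpl < 1 - 4 * sd
  se <- sd / sqrt(length(draws))
  expect_true(all(abs(avg[interior] - tmpl[interior]) < 3.5 * se + 1e-12))
})

test_that("time series reflect the template covariance", {
  # identity template: off-diagonal sample correlations vanish at large T
  eye <- diag(10)
  ts_big <- sample_subject_timeseries(eye, 5000, seed = 3)
  r <- cor(ts_big)
  expect_lt(max(abs(r[upper.tri(r)])), 0.1)

  expect_identical(sample_subject_timeseries(eye, 50, seed = 9),
                   sample_subject_timeseries(eye, 50, seed = 9))
  expect_error(sample_subject_timeseries(eye, 2),
               class = "connectopath_config_error")

  # strongly coupled pair shows up in the sample correlation at T = 230
  tmpl <- matrix(0, 4, 4)
  tmpl[1, 2] <- tmpl[2, 1] <- 0.9
  ts <- sample_subject_timeseries(tmpl, 230, seed = 5)
  expect_gt(cor(ts[, 1], ts[, 2]), 0.5)
})

test_that("clinical generator follows the linear mediation equations", {
  mp <- list(a = 0.5, b = 0.4, c_prime = 0.1, noise_sd_m = 0, noise_sd_y = 0)
  out <- sample_clinical(2, mp, seed = 1)
  expect_equal(out$m, 1.0)
  expect_equal(out$y, 0.1 * 2 + 0.4 * 1.0)

  mp0 <- list(a = 0, b = 0.4, c_prime = 0, noise_sd_m = 0, noise_sd_y = 0)
  out0 <- sample_clinical(c(-3, 0, 5), mp0, seed = 1)
  expect_equal(out0$m, c(0, 0, 0))

  expect_identical(sample_clinical(1:5, mp, seed = 2),
                   sample_clinical(1:5, mp, seed = 2))
})

test_that("generate_cohort writes a complete, reproducible study directory", {
  cfg <- toy_cohort_config(n_patients = 4, n_controls = 3, n_nodes = 20,
                           n_timepoints = 30, seed = 42)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_cohort(cfg, d1)
  m2 <- generate_cohort(cfg, d2)

  expect_equal(nrow(m1), 7)
  expect_equal(sum(m1$group == "patient"), 4)
  expect_setequal(
    list.files(d1, pattern = "_ts.tsv$"),
    paste0(m1$subject_id, "_ts.tsv"))
  # byte-identical rerun under the same config and seed
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  expect_identical(readLines(file.path(d1, "sub001_sc.tsv")),
                   readLines(file.path(d2, "sub001_sc.tsv")))

  # instrument bounds
  expect_true(all(m1$vas >= 0 & m1$vas <= 10))
  expect_true(all(m1$bi >= 0 & m1$bi <= 100))
  expect_true(all(m1$joa >= -6 & m1$joa <= 29))
  expect_true(all(m1$age >= 35 & m1$age <= 65))
  pd_cols <- c("pd2_rh", "pd2_lh", "pd2_rf", "pd2_lf")
  expect_true(all(as.matrix(m1[pd_cols]) >= 0))

  # files round-trip through the loaders
  sc <- load_sc_matrix(file.path(d1, "sub001_sc.tsv"), expected_n = 20)
  expect_s3_class(sc, "connectivity_matrix")
  ts <- read_matrix_tsv(file.path(d1, "sub001_ts.tsv"))
  expect_equal(dim(ts), c(30, 20))

  gt <- attr(m1, "ground_truth")
  expect_true(all(c("template_patient", "template_control") %in% names(gt)))
  # planted patient effect: extra cross-community shortcuts only
  extra <- gt$template_patient - gt$template_control
  expect_true(all(extra >= 0))
  expect_gt(sum(extra > 0), 0)
})

test_that("default cohort matches the study design sizes", {
  cfg <- cohort_config()
  expect_equal(cfg$n_patients, 32L)
  expect_equal(cfg$n_controls, 31L)
  expect_equal(cfg$n_nodes, 116L)
  d <- withr::local_tempdir()
  small <- cohort_config(n_patients = 32, n_controls = 31, n_nodes = 12,
                         n_timepoints = 20, community_sizes = c(6, 6))
  m <- generate_cohort(small, d)
  expect_equal(nrow(m), 63)
})

test_that("cohort config round-trips through YAML", {
  cfg <- toy_cohort_config(seed = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_config(cfg, path)
  back <- read_cohort_config(path)
  expect_equal(unclass(back), unclass(cfg))
})

test_that("planted group effect in global efficiency is recoverable by the permutation test", {
  # cohorts with and without the planted shortcut effect, SC arm, Eg AUC
  grid <- sparsity_grid(0.12, 0.3, 0.03)
  run_one <- function(seed, shortcut) {
    cfg <- cohort_config(n_patients = 16, n_controls = 16, n_nodes = 36,
                         n_timepoints = 20, community_sizes = rep(9, 4),
                         group_shortcut_fraction = shortcut, seed = seed)
    d <- withr::local_tempdir()
    m <- generate_cohort(cfg, d)
    mats <- lapply(m$subject_id, function(id)
      load_sc_matrix(file.path(d, paste0(id, "_sc.tsv")), subject_id = id))
    names(mats) <- m$subject_id
    met <- cohort_metrics(mats, grid = grid, metrics = "eg")
    auc <- met$auc
    stats <- compare_groups(auc, m, n_perm = 500, seed = seed + 1)
    stats$significant[stats$metric == "eg"]
  }
  planted <- vapply(1:10, function(s) run_one(100 + s, 0.08), logical(1))
  null_eff <- vapply(1:10, function(s) run_one(200 + s, 0), logical(1))
  expect_gte(mean(planted), 0.9)
  expect_lte(mean(null_eff), 0.1)
})
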