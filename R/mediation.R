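#' Indirect effect of a mediation model
#'
#' The product `a * b` of the X-to-M and M-to-Y (given X) coefficients.
#'
#' @param a,b Regression coefficients.
#' @return `a * b`.
#' @export
indirect_effect <- function(a, b) {
  stopifnot(is.finite(a), is.finite(b))
  a * b
}

#' Mediation decision from a bootstrap confidence interval
#'
#' The indirect effect is declared significant exactly when the
#' confidence interval excludes zero.
#'
#' @param ci_low,ci_high Interval bounds, `ci_low <= ci_high`.
#' @return `"significant"` or `"non-significant"`.
#' @export
conclude <- function(ci_low, ci_high) {
  if (ci_low > ci_high) stop_validation("`ci_low` must not exceed `ci_high`")
  if (ci_low > 0 || ci_high < 0) "significant" else "non-significant"
}

coef_and_p <- function(fit, term) {
  s <- summary(fit)$coefficients
  c(estimate = unname(s[term, "Estimate"]), p = unname(s[term, "Pr(>|t|)"]))
}

#' Sequential regressions of a Baron-Kenny mediation model
#'
#' The three ordinary-least-squares fits of the mediation triplet:
#' `Y ~ X + covariates` (total effect c), `M ~ X + covariates`
#' (coefficient a) and `Y ~ X + M + covariates` (direct effect c' and
#' coefficient b), with two-tailed t-test p-values for each named
#' coefficient.  This is the point-estimation core of [mediate()],
#' usable on its own (e.g. for small worked examples).
#'
#' @inheritParams mediate
#' @return A list with `c`, `p_c`, `a`, `p_a`, `c_prime`, `p_cprime`,
#'   `b`, `p_b`, `ab`, `n`, plus the prepared data frame and covariate
#'   term names (used internally by [mediate()]).
#' @export
sequential_regression <- function(data, x, m, y, covariates = NULL) {
  cols <- c(x, m, y, covariates)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    stop_validation(paste0("data lacks columns: ",
                           paste(missing_cols, collapse = ", ")))
  }
  df <- data.frame(x = data[[x]], m = data[[m]], y = data[[y]])
  cov_mat <- NULL
  if (!is.null(covariates)) {
    cov_mat <- covariate_matrix(data, covariates)
    df <- cbind(df, as.data.frame(cov_mat))
  }
  df <- df[stats::complete.cases(df), , drop = FALSE]
  cov_terms <- if (is.null(covariates)) NULL else colnames(cov_mat)
  form <- function(lhs, rhs) stats::reformulate(c(rhs, cov_terms), response = lhs)
  fit_c <- lm(form("y", "x"), data = df)
  fit_a <- lm(form("m", "x"), data = df)
  fit_full <- lm(form("y", c("x", "m")), data = df)
  for (f in list(fit_c, fit_a, fit_full)) {
    if (anyNA(coef(f))) {
      stop_validation(paste0("rank-deficient design; aliased terms: ",
                             paste(names(coef(f))[is.na(coef(f))],
                                   collapse = ", ")))
    }
  }
  cc <- coef_and_p(fit_c, "x")
  aa <- coef_and_p(fit_a, "x")
  cp <- coef_and_p(fit_full, "x")
  bb <- coef_and_p(fit_full, "m")
  list(c = unname(cc["estimate"]), p_c = unname(cc["p"]),
       a = unname(aa["estimate"]), p_a = unname(aa["p"]),
       c_prime = unname(cp["estimate"]), p_cprime = unname(cp["p"]),
       b = unname(bb["estimate"]), p_b = unname(bb["p"]),
       ab = indirect_effect(unname(aa["estimate"]), unname(bb["estimate"])),
       n = nrow(df), data = df, cov_terms = cov_terms)
}

# One bootstrap (or jackknife) refit of a and b using pre-built design
# matrices.  Returns NA when either design is rank-deficient on the
# resample.
fit_ab <- function(idx, d_m, m_vals, d_y, y_vals) {
  fm <- stats::lm.fit(d_m[idx, , drop = FALSE], m_vals[idx])
  fy <- stats::lm.fit(d_y[idx, , drop = FALSE], y_vals[idx])
  if (fm$rank < ncol(d_m) || fy$rank < ncol(d_y)) return(NA_real_)
  unname(fm$coefficients["x"] * fy$coefficients["m"])
}

#' Baron-Kenny mediation with bootstrap confidence interval
#'
#' Fits the three sequential regressions
#' `Y ~ X + covariates` (total effect c), `M ~ X + covariates`
#' (coefficient a) and `Y ~ X + M + covariates` (direct effect c' and
#' coefficient b), each with two-tailed t-test p-values, then bootstraps
#' the indirect effect `a * b` by resampling subjects with replacement
#' and refitting a and b per resample.  Because the three regressions
#' share the same covariate set, the decomposition `c = c' + a * b` holds
#' exactly on the point estimates.  The mediation is declared significant
#' exactly when the bootstrap confidence interval for `a * b` excludes
#' zero.  Resamples with a rank-deficient design are redrawn (their count
#' is recorded) so the number of bootstrap replicates stays fixed.
#'
#' @param data Data frame with one row per subject.
#' @param x,m,y Column names of the independent variable, mediator and
#'   outcome.
#' @param covariates Optional covariate column names included in all
#'   three regressions.
#' @param n_boot Bootstrap resamples (default 5000).
#' @param seed RNG seed.
#' @param ci `"percentile"` (default; plain 2.5/97.5 percentiles) or
#'   `"bca"` (bias-corrected and accelerated, with jackknife
#'   acceleration).
#' @param conf_level Confidence level (default 0.95).
#' @return An object of class `mediation_fit`; see [tidy.mediation_fit()]
#'   and [glance.mediation_fit()].
#' @export
mediate <- function(data, x, m, y, covariates = NULL, n_boot = 5000,
                    seed = 1L, ci = c("percentile", "bca"),
                    conf_level = 0.95) {
  ci <- match.arg(ci)
  fit0 <- sequential_regression(data, x, m, y, covariates)
  df <- fit0$data
  cov_terms <- fit0$cov_terms
  n <- fit0$n
  if (n < 10) stop_validation("mediation requires at least 10 complete cases")
  ab <- fit0$ab

  d_m <- cbind(`(Intercept)` = 1, x = df$x,
               if (!is.null(cov_terms)) as.matrix(df[cov_terms]))
  d_y <- cbind(`(Intercept)` = 1, x = df$x, m = df$m,
               if (!is.null(cov_terms)) as.matrix(df[cov_terms]))
  redrawn <- 0L
  ab_boot <- with_seed(seed, {
    out <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      val <- NA_real_
      while (is.na(val)) {
        idx <- sample.int(n, n, replace = TRUE)
        val <- fit_ab(idx, d_m, df$m, d_y, df$y)
        if (is.na(val)) redrawn <- redrawn + 1L
      }
      out[b] <- val
    }
    out
  })
  alpha <- 1 - conf_level
  if (ci == "percentile") {
    bounds <- quantile(ab_boot, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                       type = 7)
  } else {
    z0 <- qnorm(mean(ab_boot < ab) + 0.5 * mean(ab_boot == ab))
    jack <- vapply(seq_len(n), function(i) {
      fit_ab(setdiff(seq_len(n), i), d_m, df$m, d_y, df$y)
    }, numeric(1))
    jm <- mean(jack, na.rm = TRUE)
    num <- sum((jm - jack)^3, na.rm = TRUE)
    den <- 6 * sum((jm - jack)^2, na.rm = TRUE)^1.5
    acc <- if (den == 0) 0 else num / den
    zq <- qnorm(c(alpha / 2, 1 - alpha / 2))
    probs <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
    bounds <- quantile(ab_boot, probs, names = FALSE, type = 7)
  }

  structure(list(
    x = x, m = m, y = y, covariates = covariates, n = n,
    c = fit0$c, p_c = fit0$p_c,
    c_prime = fit0$c_prime, p_cprime = fit0$p_cprime,
    a = fit0$a, p_a = fit0$p_a,
    b = fit0$b, p_b = fit0$p_b,
    ab = unname(ab),
    ci_low = bounds[1], ci_high = bounds[2],
    ci_type = ci, conf_level = conf_level,
    n_boot = n_boot, seed = seed, redrawn_resamples = redrawn,
    ab_boot = ab_boot,
    conclusion = conclude(bounds[1], bounds[2])
  ), class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, ...) {
  cat(sprintf("Mediation: %s -> %s -> %s (n = %d)\n", x$x, x$m, x$y, x$n))
  cat(sprintf("  total effect      c  = %8.3f (p = %.3f)\n", x$c, x$p_c))
  cat(sprintf("  direct effect     c' = %8.3f (p = %.3f)\n", x$c_prime, x$p_cprime))
  cat(sprintf("  X -> M            a  = %8.3f (p = %.3f)\n", x$a, x$p_a))
  cat(sprintf("  M -> Y | X        b  = %8.3f (p = %.3f)\n", x$b, x$p_b))
  cat(sprintf("  indirect effect  ab  = %8.3f, %d%% boot CI [%.3f, %.3f] (%s)\n",
              x$ab, round(100 * x$conf_level), x$ci_low, x$ci_high,
              x$ci_type))
  cat(sprintf("  conclusion: %s mediating effect\n",
              if (x$conclusion == "significant") "a" else "no"))
  invisible(x)
}

#' Tidy a mediation fit
#'
#' One row per model quantity (`c`, `c_prime`, `a`, `b`, `ab`), with
#' p-values for the regression coefficients and the bootstrap interval
#' for the indirect effect.
#'
#' @param x A [mediate()] fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate`, `p.value`,
#'   `conf.low`, `conf.high`.
#' @method tidy mediation_fit
#' @export
tidy.mediation_fit <- function(x, ...) {
  tibble::tibble(
    term = c("c", "c_prime", "a", "b", "ab"),
    estimate = c(x$c, x$c_prime, x$a, x$b, x$ab),
    p.value = c(x$p_c, x$p_cprime, x$p_a, x$p_b, NA_real_),
    conf.low = c(rep(NA_real_, 4), x$ci_low),
    conf.high = c(rep(NA_real_, 4), x$ci_high)
  )
}

#' Glance at a mediation fit
#'
#' @param x A [mediate()] fit.
#' @param ... Unused.
#' @return A one-row tibble mirroring the columns of a mediation summary
#'   table: variables, coefficient estimates and p-values, the indirect
#'   effect with its bootstrap interval, and the conclusion.
#' @method glance mediation_fit
#' @export
glance.mediation_fit <- function(x, ...) {
  fit <- x
  tibble::tibble(
    x = fit$x, m = fit$m, y = fit$y, n = fit$n,
    c = fit$c, p_c = fit$p_c, c_prime = fit$c_prime, p_cprime = fit$p_cprime,
    a = fit$a, p_a = fit$p_a, b = fit$b, p_b = fit$p_b,
    ab = fit$ab, ci_low = fit$ci_low, ci_high = fit$ci_high,
    n_boot = fit$n_boot, conclusion = fit$conclusion
  )
}

#' Plot the bootstrap distribution of the indirect effect
#'
#' Histogram of the bootstrap `a * b` replicates with the point estimate
#' and confidence bounds; zero outside the interval means a significant
#' mediation.
#'
#' @param object A [mediate()] fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_fit
#' @export
autoplot.mediation_fit <- function(object, ...) {
  df <- tibble::tibble(ab = object$ab_boot)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ab)) +
    ggplot2::geom_histogram(bins = 60, fill = "grey70", color = "grey40") +
    ggplot2::geom_vline(xintercept = object$ab, linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = c(object$ci_low, object$ci_high),
                        linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, color = "red", linetype = "dotted") +
    ggplot2::labs(
      x = "bootstrap indirect effect (a × b)", y = "count",
      title = sprintf("%s → %s → %s: %s", object$x, object$m,
                      object$y, object$conclusion)) +
    ggplot2::theme_minimal()
}
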