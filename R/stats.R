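#' Correlate two variables with Pearson, Spearman or skipped models
#'
#' The skipped model is a robust correlation: bivariate outliers are
#' detected relative to a minimum-covariance-determinant (MCD) center by the
#' projection method (see [skipped_outliers()]) and removed, then the rank
#' (Spearman) correlation — or Pearson, if requested — is computed on the
#' remaining points. For all models the 95% confidence interval is a seeded
#' percentile bootstrap and the achieved power of the correlation test is
#' evaluated by the Fisher-z approximation at the observed r and n.
#'
#' @param data Optional data frame; when supplied, `x` and `y` are column
#'   names (tidy-select style strings) in it. Otherwise pass numeric vectors.
#' @param x,y Numeric vectors, or column names when `data` is given.
#' @param model `"pearson"`, `"spearman"` or `"skipped"`.
#' @param skipped_base Correlation computed on the cleaned set for the
#'   skipped model: `"spearman"` (default) or `"pearson"`.
#' @param n_boot Bootstrap resamples for the CI (default 2000).
#' @param seed Integer seed for the bootstrap (and the MCD subsampling).
#' @param alpha Significance level for the power computation.
#'
#' @return An object of class `beta_cor`: a list with `model`, `r`, `ci95`,
#'   `p_value`, `power`, `n`, `n_outliers`, `outlier_indices`, `n_boot`.
#'   For Pearson/Spearman `n_outliers` is 0. [tidy()] returns the one-row
#'   tibble form; [glance()] the fit metadata.
#' @examples
#' set.seed(1)
#' x <- rnorm(40); y <- 0.6 * x + rnorm(40)
#' correlate(x = x, y = y, model = "skipped")
#' @export
correlate <- function(data = NULL, x, y, model = c("pearson", "spearman", "skipped"),
                      skipped_base = c("spearman", "pearson"),
                      n_boot = 2000, seed = 1L, alpha = 0.05) {
  model <- match.arg(model)
  skipped_base <- match.arg(skipped_base)
  if (!is.null(data)) {
    x <- data[[x]]
    y <- data[[y]]
  }
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 4) abort("Correlation needs at least 4 complete observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation is undefined for a constant input vector.")
  }

  outliers <- integer()
  if (model == "skipped") {
    outliers <- skipped_outliers(x = x, y = y, seed = seed)
    kept <- setdiff(seq_len(n), outliers)
    base_method <- skipped_base
    xs <- x[kept]; ys <- y[kept]
  } else {
    base_method <- model
    xs <- x; ys <- y
  }
  ct <- suppressWarnings(
    cor.test(xs, ys, method = base_method, exact = FALSE)
  )
  r <- unname(ct$estimate)
  ci <- withr::with_seed(seed, {
    m <- length(xs)
    boot_r <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(m, m, replace = TRUE)
      suppressWarnings(cor(xs[idx], ys[idx], method = base_method))
    }, numeric(1))
    unname(quantile(boot_r, c(0.025, 0.975), na.rm = TRUE))
  })
  structure(
    list(model = model, r = r, ci95 = ci, p_value = ct$p.value,
         power = fisher_z_power(r, length(xs), alpha),
         n = n, n_used = length(xs),
         n_outliers = length(outliers), outlier_indices = outliers,
         n_boot = n_boot, seed = seed,
         skipped_base = if (model == "skipped") skipped_base else NA_character_),
    class = "beta_cor"
  )
}

# Post-hoc power of the correlation test by the Fisher z approximation:
# z_r ~ N(atanh(rho), 1/(n-3)).
fisher_z_power <- function(r, n, alpha = 0.05) {
  if (n <= 3) return(NA_real_)
  za <- qnorm(1 - alpha / 2)
  delta <- sqrt(n - 3) * abs(atanh(min(max(r, -0.999999), 0.999999)))
  pnorm(delta - za) + pnorm(-delta - za)
}

#' @export
print.beta_cor <- function(x, ...) {
  cat(sprintf(
    "<beta_cor> %s%s: r = %.3f, CI95 [%.3f, %.3f], p = %.4g, power = %.2f\n",
    x$model,
    if (x$model == "skipped") paste0(" (", x$skipped_base, ")") else "",
    x$r, x$ci95[1], x$ci95[2], x$p_value, x$power
  ))
  if (x$n_outliers > 0) {
    cat("  outliers removed:", x$n_outliers,
        paste0("(", toString(x$outlier_indices), ")"), "\n")
  }
  invisible(x)
}

#' @export
tidy.beta_cor <- function(x, ...) {
  tibble(
    model = x$model, estimate = x$r,
    conf.low = x$ci95[1], conf.high = x$ci95[2],
    p.value = x$p_value, power = x$power, n_outliers = x$n_outliers
  )
}

#' @export
glance.beta_cor <- function(x, ...) {
  tibble(n = x$n, n_used = x$n_used, n_boot = x$n_boot,
         model = x$model, seed = x$seed)
}

#' Bivariate outlier detection for the skipped correlation
#'
#' Finds points inconsistent with the overall structure of the cloud: the
#' robust center is the minimum-covariance-determinant (MCD) location; each
#' data point defines a projection direction through the center; all points
#' are projected onto every such direction and flagged by the boxplot rule
#' (beyond 1.5 IQR outside the quartiles of the projected values, quartiles
#' by the interpolated ideal-fourths estimator) on any direction.
#'
#' @param data Optional data frame with columns `x`, `y` (names passed as
#'   strings); otherwise numeric vectors.
#' @param x,y Numeric vectors of equal length (n >= 10).
#' @param seed Integer seed for the MCD subsampling, making the flagging
#'   deterministic.
#' @return Sorted integer vector of flagged indices (possibly empty).
#' @examples
#' set.seed(2)
#' x <- rnorm(50); y <- x + rnorm(50)
#' skipped_outliers(x = c(x, 10), y = c(y, -10))
#' @export
skipped_outliers <- function(data = NULL, x, y, seed = 1L) {
  if (!is.null(data)) {
    x <- data[[x]]; y <- data[[y]]
  }
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  if (n < 10) {
    abort("Skipped outlier detection needs at least 10 observations.")
  }
  X <- cbind(x, y)
  center <- withr::with_seed(seed, MASS::cov.mcd(X)$center)
  flagged <- rep(FALSE, n)
  Xc <- sweep(X, 2, center)
  for (i in seq_len(n)) {
    u <- Xc[i, ]
    nu <- sqrt(sum(u^2))
    if (nu < .Machine$double.eps) next
    d <- as.vector(Xc %*% (u / nu))
    q <- ideal_fourths(d)
    iqr <- q[2] - q[1]
    flagged <- flagged | d < q[1] - 1.5 * iqr | d > q[2] + 1.5 * iqr
  }
  which(flagged)
}

# Interpolated quartiles ("ideal fourths").
ideal_fourths <- function(x) {
  x <- sort(x)
  n <- length(x)
  j <- floor(n / 4 + 5 / 12)
  h <- n / 4 + 5 / 12 - j
  q1 <- (1 - h) * x[j] + h * x[j + 1]
  k <- n - j + 1
  q2 <- (1 - h) * x[k] + h * x[k - 1]
  c(q1, q2)
}

#' Form best and worst performer groups
#'
#' Applies the study's exclusion rules: subjects with task scores within
#' half a point of the cohort mean are excluded (they are neither clearly
#' best nor worst); the remainder split at the pass mark (worst strictly
#' below it); within each group, subjects whose beta summary lies outside
#' that group's \[5th, 95th\] percentile interval (linear-interpolation
#' quantiles) are trimmed as outliers.
#'
#' @param data Optional data frame with score/beta columns (names as
#'   strings); otherwise vectors.
#' @param scores,betas Parallel numeric vectors (or column names).
#' @param pass_mark Score threshold (default 5): worst < mark <= best.
#' @param score_margin Half-width of the exclusion band around the mean
#'   score (default 0.5).
#' @param trim Apply the per-group 5-95% beta trim (default `TRUE`). With
#'   linear-interpolation quantiles the group minimum and maximum always lie
#'   outside the interval for group sizes up to 20, so the trim removes at
#'   least the two extremes of each group; set `FALSE` to inspect the
#'   untrimmed split.
#' @return A list of class `beta_groups` with tibbles `worst` and `best`
#'   (columns `index`, `score`, `beta`) and a `log` tibble of per-step
#'   exclusion counts.
#' @export
form_groups <- function(data = NULL, scores, betas, pass_mark = 5,
                        score_margin = 0.5, trim = TRUE) {
  if (!is.null(data)) {
    scores <- data[[scores]]; betas <- data[[betas]]
  }
  if (length(scores) != length(betas)) {
    abort("`scores` and `betas` must have equal length.")
  }
  d <- tibble(index = seq_along(scores), score = scores, beta = betas)
  m <- mean(d$score)
  mid <- abs(d$score - m) <= score_margin
  d2 <- d[!mid, , drop = FALSE]
  worst <- d2[d2$score < pass_mark, , drop = FALSE]
  best <- d2[d2$score >= pass_mark, , drop = FALSE]
  if (nrow(worst) == 0 || nrow(best) == 0) {
    abort(paste0(
      "Group formation emptied the ",
      if (nrow(worst) == 0) "worst" else "best",
      "-performer group at the ",
      if (nrow(d2) == 0) "mean +/- margin exclusion" else "pass-mark split",
      " step."
    ))
  }
  trim_group <- function(g) {
    if (!trim) return(g)
    q <- quantile(g$beta, c(0.05, 0.95), type = 7)
    g[g$beta >= q[1] & g$beta <= q[2], , drop = FALSE]
  }
  worst_t <- trim_group(worst)
  best_t <- trim_group(best)
  if (nrow(worst_t) == 0 || nrow(best_t) == 0) {
    abort(paste0("The 5-95% beta trim emptied the ",
                 if (nrow(worst_t) == 0) "worst" else "best",
                 "-performer group."))
  }
  structure(
    list(
      worst = worst_t, best = best_t,
      log = tibble(
        step = c("input", "mid_score_excluded", "worst_pre_trim",
                 "best_pre_trim", "worst_trimmed", "best_trimmed"),
        n = c(nrow(d), sum(mid), nrow(worst), nrow(best),
              nrow(worst) - nrow(worst_t), nrow(best) - nrow(best_t))
      )
    ),
    class = "beta_groups"
  )
}

#' @export
print.beta_groups <- function(x, ...) {
  cat("<beta_groups> worst n =", nrow(x$worst),
      "| best n =", nrow(x$best), "\n")
  print(x$log)
  invisible(x)
}

#' Compare best and worst performers' beta summaries
#'
#' Screens the parametric requirements first — Shapiro-Wilk normality per
#' group and Bartlett homogeneity of variance across groups — and only when
#' both hold (all p > alpha) uses the two-sample t test; otherwise the
#' two-sided Mann-Whitney U test of equal medians. The reported statistic
#' for Mann-Whitney is the U of the first (worst) group.
#'
#' @param groups A `beta_groups` object from [form_groups()], or `NULL` when
#'   passing `worst`/`best` directly.
#' @param worst,best Numeric vectors of beta summaries (used when `groups`
#'   is `NULL`).
#' @param alpha Significance level (default 0.05).
#' @return An object of class `beta_group_test`: group sizes and medians,
#'   per-group Shapiro-Wilk p, Bartlett p, `test_used`, the statistic, the
#'   p value, and `significant` (p < alpha).
#' @export
compare_groups <- function(groups = NULL, worst = NULL, best = NULL,
                           alpha = 0.05) {
  if (!is.null(groups)) {
    stopifnot(inherits(groups, "beta_groups"))
    worst <- groups$worst$beta
    best <- groups$best$beta
  }
  if (length(worst) < 3 || length(best) < 3) {
    abort("Each group needs at least 3 subjects for the normality screen.")
  }
  sw_w <- shapiro.test(worst)$p.value
  sw_b <- shapiro.test(best)$p.value
  bt <- bartlett.test(list(worst, best))$p.value
  parametric <- sw_w > alpha && sw_b > alpha && bt > alpha
  if (parametric) {
    ht <- t.test(worst, best, var.equal = TRUE)
    test_used <- "t_test"
  } else {
    exact <- length(worst) <= 8 && length(best) <= 8 &&
      !any(duplicated(c(worst, best)))
    ht <- suppressWarnings(
      wilcox.test(worst, best, exact = exact, correct = TRUE)
    )
    test_used <- "mann_whitney"
  }
  structure(
    list(
      group_sizes = c(worst = length(worst), best = length(best)),
      medians = c(worst = median(worst), best = median(best)),
      normality_p = c(worst = sw_w, best = sw_b),
      variance_p = bt,
      test_used = test_used,
      statistic = unname(ht$statistic),
      p_value = ht$p.value,
      significant = ht$p.value < alpha,
      alpha = alpha
    ),
    class = "beta_group_test"
  )
}

#' @export
print.beta_group_test <- function(x, ...) {
  cat(sprintf(
    "<beta_group_test> %s: statistic = %.3f, p = %.4g (%s at alpha = %.2f)\n",
    x$test_used, x$statistic, x$p_value,
    if (x$significant) "significant" else "not significant", x$alpha
  ))
  cat(sprintf("  worst: n = %d, median = %.4g | best: n = %d, median = %.4g\n",
              x$group_sizes["worst"], x$medians["worst"],
              x$group_sizes["best"], x$medians["best"]))
  invisible(x)
}

#' @export
tidy.beta_group_test <- function(x, ...) {
  tibble(
    group = c("worst", "best"),
    n = as.integer(x$group_sizes),
    median = unname(x$medians),
    shapiro_p = unname(x$normality_p)
  )
}

#' @export
glance.beta_group_test <- function(x, ...) {
  tibble(
    test_used = x$test_used, statistic = x$statistic,
    p.value = x$p_value, significant = x$significant,
    bartlett_p = x$variance_p
  )
}

#' Correlation table across task score and mental-state answers
#'
#' Runs the three correlation models between the normalized beta summary and
#' the task score plus each of the six mental-state answers, producing the
#' long report table (variable, model, outliers, r, ci, p, power).
#'
#' @param cohort_table Data frame with a column per variable (`score`,
#'   `attention`, ...) and the beta summary column.
#' @param beta_col Name of the beta summary column (default
#'   `"normalized_beta"`).
#' @param variables Character vector of variable columns to correlate
#'   against; defaults to the task score plus the six answers present.
#' @param models Correlation models to run.
#' @param n_boot,seed Passed to [correlate()].
#' @return A tibble with one row per variable x model.
#' @export
correlation_table <- function(cohort_table, beta_col = "normalized_beta",
                              variables = NULL,
                              models = c("pearson", "spearman", "skipped"),
                              n_boot = 2000, seed = 1L) {
  if (is.null(variables)) {
    variables <- intersect(
      c("score", "attention", "stress", "relaxation", "interest",
        "fatigue", "effort"),
      names(cohort_table)
    )
  }
  grid <- tidyr::expand_grid(variable = variables, model = models)
  purrr::pmap_dfr(grid, function(variable, model) {
    row <- tryCatch(
      tidy(correlate(cohort_table, x = beta_col, y = variable,
                     model = model, n_boot = n_boot, seed = seed)),
      error = function(e) tibble(
        model = model, estimate = NA_real_, conf.low = NA_real_,
        conf.high = NA_real_, p.value = NA_real_, power = NA_real_,
        n_outliers = NA_integer_
      )
    )
    dplyr::bind_cols(tibble(variable = variable), row)
  })
}

#' Scatter plot of beta summary against task score
#'
#' @param cohort_table Data frame with the beta and score columns.
#' @param beta_col,score_col Column names.
#' @param outliers Optional integer indices (e.g. from a skipped fit) drawn
#'   highlighted.
#' @return A ggplot.
#' @export
plot_cohort_scatter <- function(cohort_table, beta_col = "normalized_beta",
                                score_col = "score", outliers = integer()) {
  d <- tibble(
    beta = cohort_table[[beta_col]],
    score = cohort_table[[score_col]],
    outlier = seq_len(nrow(cohort_table)) %in% outliers
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta, y = .data$score)) +
    ggplot2::geom_point(ggplot2::aes(color = .data$outlier), size = 2) +
    ggplot2::geom_smooth(data = function(dd) dd[!dd$outlier, ],
                         method = "lm", formula = y ~ x, se = FALSE,
                         color = "red", linewidth = 0.5) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "black", `TRUE` = "orange")) +
    ggplot2::labs(x = "Total mean beta PSD (normalized)", y = "Task score",
                  color = "Skipped outlier") +
    ggplot2::theme_minimal()
}
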