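test_that("spearman is 1 for any strictly monotone relation", {
  x <- c(1, 3, 4, 7, 9, 12, 15)
  fit <- correlate(x = x, y = exp(x), model = "spearman", n_boot = 50)
  expect_equal(fit$r, 1)
  expect_equal(fit$n_outliers, 0)
})

test_that("skipped equals spearman on an outlier-free elliptical cloud", {
  withr::with_seed(3, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100, 0, sqrt(0.75))
  })
  sk <- correlate(x = x, y = y, model = "skipped", n_boot = 50, seed = 1)
  sp <- correlate(x = x, y = y, model = "spearman", n_boot = 50, seed = 1)
  expect_equal(sk$n_outliers, 0)
  expect_equal(sk$r, sp$r, tolerance = 1e-12)
})

test_that("pearson recovers a known population correlation", {
  withr::with_seed(7, {
    x <- rnorm(1000)
    y <- 0.5 * x + sqrt(1 - 0.25) * rnorm(1000)
  })
  fit <- correlate(x = x, y = y, model = "pearson", n_boot = 200, seed = 1)
  expect_gte(fit$r, 0.45)
  expect_lte(fit$r, 0.55)
  expect_lt(fit$ci95[1], fit$r)
  expect_gt(fit$ci95[2], fit$r)
  expect_lt(fit$p_value, 1e-10)
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(correlate(x = rep(1, 10), y = rnorm(10)), "constant")
  expect_error(correlate(x = 1:3, y = 1:3), "at least 4")
  expect_error(correlate(x = 1:5, y = 1:6), "equal length")
})

test_that("achieved power behaves like a power curve", {
  p_small <- betatrace:::fisher_z_power(0.2, 20)
  p_bigr <- betatrace:::fisher_z_power(0.6, 20)
  p_bign <- betatrace:::fisher_z_power(0.2, 200)
  expect_true(all(c(p_small, p_bigr, p_bign) >= 0 &
                    c(p_small, p_bigr, p_bign) <= 1))
  expect_gt(p_bigr, p_small)
  expect_gt(p_bign, p_small)
  # null r: power collapses to the test size
  expect_equal(betatrace:::fisher_z_power(0, 30), 0.05, tolerance = 0.01)
})

test_that("projection outlier detection flags gross points and only them", {
  withr::with_seed(3, {
    x <- rnorm(100)
    y <- 0.5 * x + rnorm(100, 0, sqrt(0.75))
  })
  expect_length(skipped_outliers(x = x, y = y, seed = 1), 0)
  # one point ~10 robust SDs off the regression structure
  out <- skipped_outliers(x = c(x, 10), y = c(y, -10), seed = 1)
  expect_equal(out, 101L)
  expect_error(skipped_outliers(x = 1:5, y = 1:5), "at least 10")
})

test_that("contamination barely moves skipped but wrecks pearson", {
  withr::with_seed(10, {
    x <- rnorm(100)
    y <- 0.6 * x + rnorm(100, 0, 0.8)
    xo <- c(x, rnorm(5, 8, 0.5))
    yo <- c(y, rnorm(5, -8, 0.5))
  })
  d_pearson <- abs(correlate(x = x, y = y, model = "pearson", n_boot = 50)$r -
                     correlate(x = xo, y = yo, model = "pearson", n_boot = 50)$r)
  d_skipped <- abs(correlate(x = x, y = y, model = "skipped", n_boot = 50,
                             seed = 2)$r -
                     correlate(x = xo, y = yo, model = "skipped", n_boot = 50,
                               seed = 2)$r)
  expect_gt(d_pearson, 0.2)
  expect_lt(d_skipped, 0.1)
})

test_that("group formation applies the stated exclusion rules in order", {
  scores <- c(2, 3, 5.2, 7, 8) # mean 5.04; 5.2 sits inside the +/-0.5 band
  betas <- c(0.1, 0.2, 0.5, 0.6, 0.9)
  g <- form_groups(scores = scores, betas = betas, trim = FALSE)
  expect_equal(g$worst$score, c(2, 3))
  expect_equal(g$best$score, c(7, 8))
  expect_equal(g$log$n[g$log$step == "mid_score_excluded"], 1)

  expect_error(form_groups(scores = rep(7, 6), betas = runif(6)), "worst")
  # trimming two-member groups removes both extremes and must say so
  expect_error(form_groups(scores = scores, betas = betas), "trim")
})

test_that("the 5-95% beta trim removes only the extreme group members", {
  withr::with_seed(21, {
    scores <- c(runif(20, 0, 4), runif(20, 6, 10))
    betas <- runif(40, 0.3, 0.7)
  })
  betas[5] <- 5     # gross high beta in the worst group
  betas[25] <- 0.001 # gross low beta in the best group
  g <- form_groups(scores = scores, betas = betas)
  expect_false(5 %in% g$worst$index)
  expect_false(25 %in% g$best$index)
  # trimming is the only per-group loss beyond the quantile tails
  expect_lte(nrow(g$worst), 18)
  expect_lte(nrow(g$best), 18)
})

test_that("identical groups compare as indistinguishable", {
  withr::with_seed(5, g <- rnorm(12, 10, 2))
  res <- compare_groups(worst = g, best = g)
  expect_gt(res$p_value, 0.9)
  expect_false(res$significant)
})

test_that("a two-SD shift between groups of 20 is detected", {
  withr::with_seed(6, {
    worst <- rexp(20) # skewed: fails the normality screen
    best <- rexp(20) + 2 * sd(rexp(2000))
  })
  res <- compare_groups(worst = worst, best = best)
  expect_equal(res$test_used, "mann_whitney")
  expect_lt(res$p_value, 0.05)
  expect_true(res$significant)
  expect_lt(res$medians["worst"], res$medians["best"])
})

test_that("the U statistic equals the exhaustive pair count on small groups", {
  withr::with_seed(8, {
    for (i in 1:5) {
      worst <- exp(rnorm(sample(4:8, 1), 0, 2)) # heteroscedastic vs best
      best <- exp(rnorm(sample(4:8, 1), 1.5, 0.2))
      res <- compare_groups(worst = worst, best = best)
      if (res$test_used == "mann_whitney") {
        expect_equal(res$statistic, brute_u(worst, best))
      }
    }
  })
})

test_that("mann-whitney inference is invariant under monotone transforms", {
  withr::with_seed(9, {
    worst <- rexp(15)
    best <- rexp(15) * 2
  })
  p1 <- compare_groups(worst = worst, best = best)
  p2 <- compare_groups(worst = log(worst), best = log(best))
  p3 <- compare_groups(worst = worst^3, best = best^3)
  if (p1$test_used == "mann_whitney" && p2$test_used == "mann_whitney") {
    expect_equal(p1$p_value, p2$p_value)
  }
  if (p1$test_used == "mann_whitney" && p3$test_used == "mann_whitney") {
    expect_equal(p1$p_value, p3$p_value)
  }
})

test_that("normal well-behaved groups fall back to the t test", {
  withr::with_seed(13, {
    worst <- rnorm(15, 10, 1)
    best <- rnorm(15, 12, 1)
  })
  res <- compare_groups(worst = worst, best = best)
  expect_equal(res$test_used, "t_test")
  expect_true(res$significant)
})

test_that("the correlation table covers every variable-model pair", {
  withr::with_seed(14, {
    d <- tibble::tibble(
      normalized_beta = runif(20),
      score = runif(20, 0, 10),
      attention = runif(20, 1, 5)
    )
  })
  tab <- correlation_table(d, variables = c("score", "attention"),
                           n_boot = 50, seed = 2)
  expect_equal(nrow(tab), 6)
  expect_setequal(unique(tab$model), c("pearson", "spearman", "skipped"))
  expect_true(all(tab$estimate >= -1 & tab$estimate <= 1))
  expect_true(all(tab$conf.low <= tab$conf.high))
})

test_that("tidy and glance return one-row summaries for correlation fits", {
  fit <- correlate(x = 1:10, y = (1:10) + rnorm(10), n_boot = 50)
  td <- tidy(fit)
  expect_equal(nrow(td), 1)
  expect_named(td, c("model", "estimate", "conf.low", "conf.high",
                     "p.value", "power", "n_outliers"))
  expect_equal(glance(fit)$n, 10)
})
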