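test_that("binomial point mass matches log-space arithmetic and dbinom", {
  b <- binomial_point_p(37, 40, 0.25)
  expect_equal(b$point, 2.2066e-19, tolerance = 1e-4)
  expect_equal(binomial_point_p(28, 38, 0.25)$point, 3.69e-10,
               tolerance = 2e-3)
  expect_equal(binomial_point_p(1, 1, 0.25)$point, 0.25)
  expect_gte(b$tail, b$point)
  # independent route: R's own binomial density
  for (k in c(0, 3, 20, 40)) {
    expect_equal(binomial_point_p(k, 40, 0.25)$point, dbinom(k, 40, 0.25),
                 tolerance = 1e-12)
  }
  # point masses sum to one for every n up to the design size
  for (n in c(1, 7, 40, 60)) {
    s <- sum(vapply(0:n, function(k) binomial_point_p(k, n, 0.25)$point, 0))
    expect_equal(s, 1, tolerance = 1e-12)
  }
})

test_that("paired one-tailed t follows the closed form", {
  # differences with mean 1 and SD exactly 1 at n = 16 give t = 4
  d0 <- rep(c(-1, 1), 8)
  d <- 1 + d0 / sd(d0)
  y0 <- rep(c(0, 0.5), 8)
  res <- paired_t_one_tailed(y0 + d, y0, "greater")
  expect_equal(res$statistic, 4)
  expect_equal(res$df, 15)
  expect_equal(res$p_value, pt(4, 15, lower.tail = FALSE))
  expect_identical(res$tails, "ONE")

  # null identity: symmetric perturbation gives p = 0.5 at t = 0
  x <- c(1, 2, 3, 4, 5)
  y <- x + c(-1, 1, 0, 1, -1) * 0.1
  res0 <- paired_t_one_tailed(x, y, "greater")
  expect_equal(res0$statistic, 0)
  expect_equal(res0$p_value, 0.5)

  expect_warning(rz <- paired_t_one_tailed(x, x, "greater"), "zero variance")
  expect_true(is.na(rz$statistic))
})

test_that("repeated-measures d accounts for the paired correlation", {
  set.seed(2024)
  x <- rnorm(10, 1, 1)
  y <- rnorm(10, 0.4, 1.2)
  r <- cor(x, y)
  direct <- (mean(x - y) /
               sqrt(sd(x)^2 + sd(y)^2 - 2 * r * sd(x) * sd(y))) *
    sqrt(2 * (1 - r))
  expect_equal(cohens_d_rm(x, y), direct)
  # translation invariance
  expect_equal(cohens_d_rm(x + 5, y + 5), direct)
  # degenerate perfect correlation: constant shift
  expect_warning(dd <- cohens_d_rm(x, x + 2), "degenerate")
  expect_true(is.na(dd))
})

test_that("Welch t matches both the summary formula and stats::t.test", {
  # summaries from two unequal groups
  res <- welch_t(list(mean = 4.08, sd = 3.28, n = 35),
                 list(mean = 2.95, sd = 1.48, n = 78))
  expect_equal(res$statistic, 1.950985, tolerance = 1e-5)
  expect_equal(res$df, 40.3474, tolerance = 1e-4)
  expect_true(res$df <= 35 + 78 - 2)

  # raw-sample route against R's own Welch test
  set.seed(8)
  x <- rnorm(35, 4, 3); y <- rnorm(78, 3, 1.5)
  mine <- welch_t(x, y)
  ref <- t.test(x, y)
  expect_equal(mine$statistic, unname(ref$statistic))
  expect_equal(mine$df, unname(ref$parameter))
  expect_equal(mine$p_value, ref$p.value)

  sym <- welch_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(sym$statistic, 0)
})

test_that("repeated-measures ANOVA has the right df and F decomposition", {
  set.seed(42)
  n <- 12
  mat <- matrix(rnorm(n * 6, rep(c(0.6, rep(0.7, 5)), each = n), 0.05), n, 6)
  out <- rm_anova(mat)
  expect_equal(out$test$df, c(5, 5 * (n - 1)))
  # independent oracle: textbook within-subject decomposition
  grand <- mean(mat)
  ss_resp <- n * sum((colMeans(mat) - grand)^2)
  ss_subj <- 6 * sum((rowMeans(mat) - grand)^2)
  ss_tot <- sum((mat - grand)^2)
  ss_err <- ss_tot - ss_resp - ss_subj
  F_ref <- (ss_resp / 5) / (ss_err / (5 * (n - 1)))
  expect_equal(out$test$statistic, F_ref, tolerance = 1e-8)

  expect_equal(nrow(out$pairwise), 15)
  expect_true(all(out$pairwise$p_bonferroni <= 1))
  expect_equal(out$pairwise$p_bonferroni,
               pmin(out$pairwise$p_raw * 15, 1))
  expect_error(rm_anova(mat[, 1:5]), "ncol")
  mat[2, 3] <- NA
  expect_error(rm_anova(mat), "complete")
})

test_that("response-number effect is detected at the design's scale", {
  # first response faster than the rest, as in a full-preview study
  set.seed(7)
  n <- 35
  mat <- matrix(rnorm(n * 6, rep(c(0.6, rep(0.7, 5)), each = n), 0.05), n, 6)
  out <- rm_anova(mat)
  expect_equal(out$test$df[2], 170)
  expect_lt(out$test$p_value, 0.001)
})

test_that("required sample size comes from the noncentral t distribution", {
  expect_identical(required_sample_size(0.5, 0.05, 0.80, "two"), 34L)
  n_one <- required_sample_size(0.5, 0.05, 0.80, "one")
  expect_lt(n_one, 34)
  # monotone in the power target
  expect_gt(required_sample_size(0.5, 0.05, 0.90, "two"), 34)
  # and decreasing in effect size
  expect_lt(required_sample_size(0.8, 0.05, 0.80, "two"), 34)
})

test_that("Fisher's z is arctanh", {
  expect_equal(fisher_z(0), 0)
  expect_equal(round(fisher_z(0.99934), 3), 4.008)
  expect_equal(fisher_z(-0.5), -fisher_z(0.5))
  expect_error(fisher_z(1), "< 1")
})

test_that("model selection counts winners and flags exact ties", {
  mk <- function(sid, adj) data.frame(
    subject_id = sid, model = planning_models(), engine = "EXACT",
    adj_r2 = adj, stringsAsFactors = FALSE)
  fits <- rbind(mk("a", c(0.1, 0.2, 0.3, 0.9)),
                mk("b", c(0.0, 0.1, 0.2, 0.8)),
                mk("c", c(0.1, 0.1, 0.2, 0.7)))
  sel <- select_model(fits)
  expect_equal(sel$top_model, "FAST_PRECRASTINATION")
  expect_equal(sel$k_top, 3)
  expect_equal(sel$binomial_point_p, dbinom(3, 3, 0.25))

  tied <- rbind(mk("a", c(0.5, 0.5, 0.1, 0.2)),
                mk("b", c(0.1, 0.2, 0.3, 0.9)))
  selt <- select_model(tied)
  expect_equal(unname(selt$counts[["TIE"]]), 1)
  expect_equal(selt$k_top, 1)

  expect_error(select_model(fits[-1, ]), "lacks a fit")
})

test_that("statistics are invariant to subject ordering", {
  set.seed(99)
  x <- rnorm(20, 1); y <- rnorm(20)
  perm <- sample(20)
  a <- paired_t_one_tailed(x, y, "greater")
  b <- paired_t_one_tailed(x[perm], y[perm], "greater")
  expect_equal(a$statistic, b$statistic)
  expect_equal(cohens_d_rm(x, y), cohens_d_rm(x[perm], y[perm]))
  mat <- cbind(x, y, rnorm(20), rnorm(20), rnorm(20), rnorm(20))
  expect_equal(rm_anova(mat)$test$statistic,
               rm_anova(mat[perm, ])$test$statistic)
})
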