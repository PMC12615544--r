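test_that("exact fit recovers generative level times on noiseless data", {
  cfg <- noiseless_config("FAST_PRECRASTINATION", level_times = c(1, 2, 3))
  cm <- cell_means(filter_trials(simulate_experiment(cfg))$trials)[[1]]
  f <- fit_exact(cm, "FAST_PRECRASTINATION")
  expect_equal(unname(coef(f)), c(1, 2, 3), tolerance = 1e-6)
  expect_lt(f$sse, 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-9)
  expect_equal(f$adjusted_r2, 1, tolerance = 1e-9)
  expect_equal(f$n_cells_used, 36)
})

test_that("unconstrained-monotone solutions are plain group means", {
  lv <- build_model("FAST_PROCRASTINATION")$levels
  mu <- matrix(0.70, 6, 6); mu[lv == 3] <- 1.10
  f <- fit_exact(make_cells(mu), "FAST_PROCRASTINATION")
  expect_equal(unname(coef(f)), c(0.70, NA, 1.10))
  expect_lt(f$sse, 1e-20)
})

test_that("order violations pool to the weighted mean and match the grid", {
  # level-3 group mean deliberately below the level-1 group mean
  lv <- build_model("FAST_PROCRASTINATION")$levels
  mu <- matrix(0.90, 6, 6); mu[lv == 3] <- 0.60
  cm <- make_cells(mu)
  f <- fit_exact(cm, "FAST_PROCRASTINATION")
  pooled <- (30 * 0.90 + 6 * 0.60) / 36
  expect_equal(unname(coef(f))[1], pooled)
  expect_equal(unname(coef(f))[3], pooled)
  expect_equal(f$sse, grid_fit_sse(cm, "FAST_PROCRASTINATION"),
               tolerance = 1e-4)
})

test_that("no grid search beats the exact fitter on random fixtures", {
  set.seed(1234)
  for (i in 1:150) {
    cm <- random_fixture()
    mn <- sample(planning_models(), 1)
    f <- fit_exact(cm, mn)
    expect_lte(f$sse, grid_fit_sse(cm, mn, step = 1e-3) + 1e-9)
  }
})

test_that("Monte Carlo search is seeded, bounded below by exact, convergent", {
  set.seed(77)
  cm <- random_fixture("FAST_PRECRASTINATION", noise = 0.15)
  fe <- fit_exact(cm, "FAST_PRECRASTINATION")
  f1 <- fit_monte_carlo(cm, "FAST_PRECRASTINATION", n_draws = 2000, seed = 8)
  f2 <- fit_monte_carlo(cm, "FAST_PRECRASTINATION", n_draws = 2000, seed = 8)
  expect_identical(f1$estimates, f2$estimates)
  expect_gte(f1$sse, fe$sse)
  # more draws never hurt (same stream prefix property not assumed; just bound)
  f3 <- fit_monte_carlo(cm, "FAST_PRECRASTINATION", n_draws = 1e5, seed = 8)
  expect_gte(f3$sse, fe$sse)
  expect_lt(f3$sse, fe$sse * 1.01 + 1e-12)
  # the search must not disturb the caller's RNG stream
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(fit_monte_carlo(cm, "SLOW_PRECRASTINATION",
                                         n_draws = 100, seed = 9))
  expect_identical(runif(1), before)
})

test_that("adjusted R-squared follows the Ezekiel formula", {
  expect_equal(adjusted_r2(0, 1, 36, 3), 1)
  expect_equal(adjusted_r2(1, 1, 36, 2), 1 - 35 / 33)
  # penalty strictly grows with parameter count
  expect_lt(adjusted_r2(0.4, 1, 36, 3), adjusted_r2(0.4, 1, 36, 2))
  expect_warning(r <- adjusted_r2(0.1, 0, 36, 2), "sst")
  expect_true(is.na(r))
  # fit-level invariant: adjusted <= plain R2
  set.seed(404)
  for (i in 1:20) {
    cm <- random_fixture()
    f <- fit_exact(cm, sample(planning_models(), 1))
    expect_lte(f$adjusted_r2, f$r2 + 1e-12)
  }
})

test_that("fast pre-crastination never fits worse than slow pre-crastination", {
  # any (t1, t3) feasible for the 2-level model is feasible for the 3-level
  # one with t2 = t3, so the constrained minimum can only improve
  set.seed(55)
  for (i in 1:50) {
    cm <- random_fixture()
    s3 <- fit_exact(cm, "SLOW_PRECRASTINATION")$sse
    s4 <- fit_exact(cm, "FAST_PRECRASTINATION")$sse
    expect_lte(s4, s3 + 1e-10)
  }
})

test_that("undefined cells shrink the objective; empty levels reject", {
  mu <- predicted_times("FAST_PRECRASTINATION", c(0.6, 0.8, 1.2))
  mu[4, 3] <- NA
  f <- fit_exact(make_cells(mu), "FAST_PRECRASTINATION")
  expect_equal(f$n_cells_used, 35)
  expect_lt(f$sse, 1e-12)

  mu2 <- mu
  mu2[1, 1] <- NA  # the only level-3 cell of this model
  expect_error(fit_exact(make_cells(mu2), "FAST_PRECRASTINATION"),
               "no defined cells for level 3")
})

test_that("count-weighted fitting shifts estimates toward heavy cells", {
  lv <- build_model("SLOW_PRECRASTINATION")$levels
  mu <- matrix(0.6, 6, 6)
  mu[lv == 3] <- c(1.0, 1.0, 1.0, 1.0, 1.0, 2.0)
  counts <- matrix(10L, 6, 6); counts[6, 1] <- 90L
  cm <- make_cells(mu, counts)
  fu <- fit_exact(cm, "SLOW_PRECRASTINATION", weighted = FALSE)
  fw <- fit_exact(cm, "SLOW_PRECRASTINATION", weighted = TRUE)
  expect_equal(unname(coef(fu))[3], mean(c(rep(1, 5), 2)))
  expect_equal(unname(coef(fw))[3], (5 * 10 * 1 + 90 * 2) / 140)
})

test_that("level times are recovered from noisy subjects at the design scale", {
  # 10 reps/condition, trial noise 0.05 s: estimates should sit within
  # 0.05 s of truth for nearly all subjects
  truth <- c(0.67, 0.80, 1.20)
  cfg <- experiment_config(
    n_subjects = 200, seed = 314,
    subject_dist = fixed_subject_dist(truth, noise_sd = 0.05,
                                      outlier_prob = 0))
  cms <- cell_means(filter_trials(simulate_experiment(cfg))$trials)
  hits <- vapply(cms, function(cm) {
    est <- coef(fit_exact(cm, "FAST_PRECRASTINATION"))
    all(abs(est - truth) <= 0.05)
  }, TRUE)
  expect_gte(mean(hits), 0.95)
})

test_that("fit objects expose the standard modelling methods", {
  cfg <- noiseless_config("FAST_PRECRASTINATION",
                          level_times = c(0.6, 0.8, 1.2))
  cm <- cell_means(filter_trials(simulate_experiment(cfg))$trials)[[1]]
  f <- plan_fit(cm, "FAST_PRECRASTINATION")
  expect_named(coef(f), c("t1", "t2", "t3"))
  expect_equal(dim(predict(f)), c(6, 6))
  expect_equal(predict(f), fitted(f), tolerance = 1e-9)
  expect_lt(max(abs(residuals(f)), na.rm = TRUE), 1e-6)
  expect_output(print(summary(f)), "residual SD")
  # plotting draws without error on a null device
  pdf(NULL); on.exit(dev.off())
  expect_silent(plot(f))
  # simulate() round-trips through the generator at the fitted level times
  sim <- simulate(f, seed = 12)
  expect_equal(nrow(sim), 60)
  m4 <- as.matrix(sim[sim$missing_target == 4, paste0("t", 1:6)])
  mu <- colMeans(m4)
  expect_equal(unname(mu), c(0.8, rep(0.6, 5)), tolerance = 0.2)
})

test_that("fit tables cover every subject-model pair and export to CSV", {
  cfg <- experiment_config(n_subjects = 2, seed = 6)
  cms <- cell_means(filter_trials(simulate_experiment(cfg))$trials)
  fits <- fit_subjects(cms)
  expect_equal(nrow(fits), 8)
  expect_setequal(unique(fits$model), planning_models())
  path <- withr::local_tempfile(fileext = ".csv")
  export_fits_csv(fits, path)
  expect_equal(nrow(read.csv(path)), 8)
})
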