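# Shared fixtures and independent oracles, built in code at test time.

# Point-mass subject distribution: known level times, adjustable noise.
fixed_subject_dist <- function(level_times = c(0.67, 0.80, 1.20),
                               noise_sd = 0.12, outlier_prob = 0.005) {
  d <- default_subject_distribution()
  d$t1 <- list(fixed = level_times[1])
  d$t2 <- list(fixed = level_times[2])
  d$t3 <- list(fixed = level_times[3])
  d$noise_sd <- list(fixed = noise_sd)
  d$outlier_prob <- list(fixed = outlier_prob)
  d
}

# Near-noiseless config: generative identity holds to ~1e-9.
noiseless_config <- function(generating_model, n_subjects = 1, seed = 1,
                             level_times = c(1, 2, 3)) {
  experiment_config(
    n_subjects = n_subjects, seed = seed,
    generating_model = generating_model,
    subject_dist = fixed_subject_dist(level_times, noise_sd = 1e-9,
                                      outlier_prob = 0))
}

# Build a cell_means object directly from a 6x6 matrix of means.
make_cells <- function(means, counts = NULL, subject_id = "FX1") {
  means <- matrix(means, 6, 6,
                  dimnames = list(paste0("missing_", 1:6),
                                  paste0("response_", 1:6)))
  if (is.null(counts)) counts <- matrix(10L, 6, 6, dimnames = dimnames(means))
  counts[is.na(means)] <- 0L
  structure(list(subject_id = subject_id, means = means, counts = counts),
            class = "cell_means")
}

# Independent oracle: exhaustive grid search for the order-constrained SSE
# minimum.  Evaluates, for each level group, the SSE contribution of every
# grid value, then takes the exact minimum over all weakly ordered tuples by
# suffix minima (equivalent to enumerating the full ordered grid).
grid_fit_sse <- function(cells, model, step = 1e-3) {
  model <- build_model(model)
  lv <- model$levels
  m <- cells$means
  used <- sort(unique(as.vector(lv)))
  grid <- seq(0, max(m, na.rm = TRUE) + step, by = step)
  contrib <- vapply(used, function(g) {
    cs <- m[!is.na(m) & lv == g]
    colSums(outer(cs, grid, function(c0, t0) (t0 - c0)^2))
  }, numeric(length(grid)))
  k <- length(used)
  s <- contrib[, k]
  if (k >= 2) {
    for (j in (k - 1):1) {
      s <- contrib[, j] + rev(cummin(rev(s)))
    }
  }
  min(s)
}

# Random cell-mean fixture: a random model's predictions plus noise, with
# occasional missing cells.
random_fixture <- function(model = sample(planning_models(), 1),
                           noise = stats::runif(1, 0.02, 0.2)) {
  lt <- sort(stats::runif(3, 0.3, 1.5))
  mu <- predicted_times(model, lt)
  make_cells(mu + stats::rnorm(36, 0, noise))
}

# Hand-made trial table with known content.
manual_trials <- function(n_trials = 60, subject_id = "M01",
                          base_time = 0.5) {
  missing <- rep(1:6, length.out = n_trials)
  tm <- matrix(base_time, n_trials, 6)
  data.frame(subject_id = subject_id, trial_index = seq_len(n_trials),
             missing_target = missing, preview_time = 2.5,
             t1 = tm[, 1], t2 = tm[, 2], t3 = tm[, 3],
             t4 = tm[, 4], t5 = tm[, 5], t6 = tm[, 6],
             stringsAsFactors = FALSE)
}
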