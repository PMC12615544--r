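# Pooled adjacent violators for a handful of ordered group means.
# values/weights: one entry per level group, in ascending level order.
# Returns the weakly increasing weighted least-squares solution.
.pava <- function(values, weights) {
  stopifnot(length(values) == length(weights), all(weights > 0))
  v <- values; w <- weights
  blocks <- seq_along(v)             # block membership for back-expansion
  i <- 1L
  while (i < length(v)) {
    if (v[i] > v[i + 1L] + 1e-15) {  # adjacent violation: merge blocks
      pooled <- (v[i] * w[i] + v[i + 1L] * w[i + 1L]) / (w[i] + w[i + 1L])
      v <- c(v[seq_len(i - 1L)], pooled, v[-seq_len(i + 1L)])
      w <- c(w[seq_len(i - 1L)], w[i] + w[i + 1L], w[-seq_len(i + 1L)])
      blocks[blocks >= i + 1L] <- blocks[blocks >= i + 1L] - 1L
      i <- max(i - 1L, 1L)
    } else i <- i + 1L
  }
  v[blocks]
}

# Group the defined cells of a cell_means object by a model's levels.
# Returns per-level (ascending) vectors of cell means and weights.
.level_groups <- function(cells, model, weighted) {
  lv <- model$levels
  m <- cells$means
  cnt <- cells$counts
  if (!identical(dim(m), c(6L, 6L))) {
    stop("model fitting needs a 6x6 cell-mean matrix (withheld-target design)",
         call. = FALSE)
  }
  defined <- !is.na(m)
  used <- sort(unique(as.vector(lv)))
  groups <- lapply(used, function(g) {
    sel <- defined & lv == g
    if (!any(sel)) {
      stop("no defined cells for level ", g, " of model ", model$name,
           call. = FALSE)
    }
    list(means = m[sel], weights = if (weighted) cnt[sel] else rep(1, sum(sel)))
  })
  list(levels = used, groups = groups, defined = defined)
}

.sse_for <- function(cells, model, tvec, weighted) {
  pred <- matrix(tvec[model$levels], 6, 6)
  d <- cells$means - pred
  w <- if (weighted) cells$counts else (cells$counts > 0) * 1
  sum(w * d^2, na.rm = TRUE)
}

#' Fit a planning model to a subject's cell means
#'
#' Estimates a model's ordered level times from a subject's 6x6
#' condition-by-response mean matrix by minimising the sum of squared
#' differences between observed and predicted cell means, subject to the
#' weak order constraint t1 <= t2 <= t3.
#'
#' Two engines are available.  `"exact"` solves the order-constrained
#' least-squares problem in closed form: each level's unconstrained optimum
#' is the (optionally count-weighted) mean of its cells, and order
#' violations are repaired by pooled adjacent violators, which is the global
#' minimiser.  `"monte_carlo"` mirrors a random-search strategy: candidate
#' level-time tuples are drawn uniformly on [0, max cell mean], sorted
#' ascending, scored by SSE, and the best is kept; it is seeded and
#' deterministic, and its SSE can never beat the exact engine's.
#'
#' Fit quality is summarised by R-squared about the subject's grand cell
#' mean and by adjusted R-squared (Ezekiel), the model-selection criterion,
#' which penalises the extra level-time parameter of the fast
#' pre-crastination model.
#'
#' @param cells A `cell_means` object ([cell_means()]).
#' @param model A `planning_model` or model name.
#' @param engine `"exact"` (default) or `"monte_carlo"`.
#' @param n_draws Monte Carlo draw count (default 1e4).
#' @param weighted If `TRUE`, cells are weighted by observation counts; the
#'   default weights the 36 cell means equally.
#' @param seed Seed for the Monte Carlo engine (required there).
#' @return A `plan_fit` object: `model`, `estimates` (named `t1`,`t2`,`t3`,
#'   `NA` for a level the model does not use), `sse`, `sst`, `r2`,
#'   `adjusted_r2`, `n_cells_used`, `engine`, plus the data for methods.
#' @seealso [fit_exact()], [fit_monte_carlo()], [adjusted_r2()],
#'   [select_model()]
#' @examples
#' cfg <- experiment_config(n_subjects = 1, seed = 3)
#' cms <- cell_means(filter_trials(simulate_experiment(cfg))$trials)
#' fit <- plan_fit(cms[[1]], "FAST_PRECRASTINATION")
#' coef(fit)
#' @export
plan_fit <- function(cells, model, engine = c("exact", "monte_carlo"),
                     n_draws = 1e4, weighted = FALSE, seed = NULL) {
  engine <- match.arg(engine)
  stopifnot(inherits(cells, "cell_means"))
  model <- build_model(model)
  lg <- .level_groups(cells, model, weighted)
  n_cells <- sum(lg$defined)

  if (engine == "exact") {
    gm <- vapply(lg$groups, function(g) {
      sum(g$means * g$weights) / sum(g$weights)
    }, 0)
    gw <- vapply(lg$groups, function(g) sum(g$weights), 0)
    tv <- .pava(gm, gw)
  } else {
    if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
    if (is.null(seed)) stop("the Monte Carlo engine needs a seed",
                            call. = FALSE)
    tv <- .mc_search(lg, n_draws, seed)
  }

  tvec <- rep(NA_real_, 3)
  tvec[lg$levels] <- tv
  sse <- .sse_for(cells, model, tvec, weighted)
  w <- if (weighted) cells$counts else (cells$counts > 0) * 1
  grand <- sum(w * cells$means, na.rm = TRUE) / sum(w[lg$defined])
  sst <- sum(w * (cells$means - grand)^2, na.rm = TRUE)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  p <- model$n_params
  adj_ok <- n_cells >= p + 2
  if (!adj_ok) {
    warning("only ", n_cells, " defined cells for ", p,
            " parameters; adjusted R-squared is unreliable", call. = FALSE)
  }
  adj <- if (sst > 0 && n_cells > p + 1) {
    adjusted_r2(sse, sst, n_cells, p)
  } else NA_real_

  structure(list(
    subject_id = cells$subject_id,
    model = model,
    estimates = stats::setNames(tvec, c("t1", "t2", "t3")),
    sse = sse, sst = sst, r2 = r2, adjusted_r2 = adj,
    adj_reliable = adj_ok,
    n_cells_used = n_cells,
    engine = toupper(engine), weighted = weighted,
    cells = cells), class = "plan_fit")
}

# Uniform-then-sort Monte Carlo search over level-time tuples.
# RNG state of the caller is preserved.
.mc_search <- function(lg, n_draws, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv())) {
            rm(".Random.seed", envir = globalenv())
          })
  set.seed(seed)
  k <- length(lg$groups)
  hi <- max(vapply(lg$groups, function(g) max(g$means), 0))
  draws <- matrix(stats::runif(n_draws * k, 0, hi), n_draws, k)
  if (k == 2L) {
    draws <- cbind(pmin(draws[, 1], draws[, 2]), pmax(draws[, 1], draws[, 2]))
  } else if (k == 3L) {
    lo <- pmin(draws[, 1], draws[, 2], draws[, 3])
    up <- pmax(draws[, 1], draws[, 2], draws[, 3])
    draws <- cbind(lo, rowSums(draws) - lo - up, up)
  }
  # SSE over cells decomposes per level group:
  # sum_g [ W_g t_g^2 - 2 t_g S_g + Q_g ]
  sse <- 0
  for (j in seq_len(k)) {
    g <- lg$groups[[j]]
    W <- sum(g$weights); S <- sum(g$weights * g$means)
    Q <- sum(g$weights * g$means^2)
    sse <- sse + W * draws[, j]^2 - 2 * draws[, j] * S + Q
  }
  draws[which.min(sse), ]
}

#' Exact order-constrained fit
#'
#' Thin wrapper over [plan_fit()] with the exact (pooled-adjacent-violators)
#' engine.
#'
#' @inheritParams plan_fit
#' @return A `plan_fit` object.
#' @export
fit_exact <- function(cells, model, weighted = FALSE) {
  plan_fit(cells, model, engine = "exact", weighted = weighted)
}

#' Monte Carlo fit
#'
#' Thin wrapper over [plan_fit()] with the seeded random-search engine.
#'
#' @inheritParams plan_fit
#' @return A `plan_fit` object.
#' @export
fit_monte_carlo <- function(cells, model, n_draws = 1e4, seed,
                            weighted = FALSE) {
  plan_fit(cells, model, engine = "monte_carlo", n_draws = n_draws,
           weighted = weighted, seed = seed)
}

#' Adjusted R-squared (Ezekiel)
#'
#' `1 - (sse/sst) * (n - 1) / (n - p - 1)`, the parameter-count-penalised
#' fit criterion used to compare the four planning models.
#'
#' @param sse Residual sum of squares.
#' @param sst Total sum of squares about the grand mean.
#' @param n Number of fitted cells.
#' @param p Number of free parameters.
#' @return Adjusted R-squared (`NA` with a warning when `sst` is 0).
#' @export
adjusted_r2 <- function(sse, sst, n, p) {
  stopifnot(sse >= 0, n > p + 1, p >= 1)
  if (sst <= 0) {
    warning("sst is zero (constant data); adjusted R-squared undefined",
            call. = FALSE)
    return(NA_real_)
  }
  1 - (sse / sst) * (n - 1) / (n - p - 1)
}

#' @export
print.plan_fit <- function(x, ...) {
  est <- ifelse(is.na(x$estimates), "  --  ",
                sprintf("%6.3f", x$estimates))
  cat(sprintf("%s fit (%s) for subject %s\n", x$model$name, x$engine,
              x$subject_id))
  cat(sprintf("  level times (s): t1 = %s, t2 = %s, t3 = %s\n",
              est[1], est[2], est[3]))
  cat(sprintf("  SSE = %.5f over %d cells; R2 = %.4f; adjusted R2 = %.4f\n",
              x$sse, x$n_cells_used, x$r2, x$adjusted_r2))
  invisible(x)
}

#' @export
summary.plan_fit <- function(object, ...) {
  res <- residuals(object)
  structure(list(fit = object,
                 resid_sd = stats::sd(as.vector(res), na.rm = TRUE),
                 cells_per_level = table(object$model$levels[
                   !is.na(object$cells$means)])),
            class = "summary.plan_fit")
}

#' @export
print.summary.plan_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  residual SD = %.4f s; defined cells per level: %s\n",
              x$resid_sd,
              paste(names(x$cells_per_level), as.integer(x$cells_per_level),
                    sep = ":", collapse = ", ")))
  invisible(x)
}

#' @export
coef.plan_fit <- function(object, ...) object$estimates

# For prediction a full triple is needed; an unused level 2 is filled with
# the midpoint of its neighbours (it touches no cell, so the fill is inert).
.full_triple <- function(est) {
  t <- est
  if (is.na(t[2])) t[2] <- (t[1] + t[3]) / 2
  unname(t)
}

#' @export
predict.plan_fit <- function(object, level_times = NULL, ...) {
  lt <- if (is.null(level_times)) .full_triple(object$estimates) else
    level_times
  predicted_times(object$model, lt)
}

#' @export
fitted.plan_fit <- function(object, ...) {
  f <- predict(object)
  f[is.na(object$cells$means)] <- NA_real_
  f
}

#' @export
residuals.plan_fit <- function(object, ...) {
  object$cells$means - fitted(object)
}

#' @export
plot.plan_fit <- function(x, ...) {
  obs <- as.vector(x$cells$means)
  pre <- as.vector(fitted(x))
  rng <- range(c(obs, pre), na.rm = TRUE)
  graphics::plot(pre, obs, xlim = rng, ylim = rng,
                 xlab = "predicted cell mean (s)",
                 ylab = "observed cell mean (s)",
                 main = sprintf("%s: adj R2 = %.3f", x$model$name,
                                x$adjusted_r2), ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' @export
simulate.plan_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lt <- .full_triple(object$estimates)
  dist <- default_subject_distribution()
  dist$t1 <- list(fixed = lt[1]); dist$t2 <- list(fixed = lt[2])
  dist$t3 <- list(fixed = lt[3])
  out <- lapply(seq_len(nsim), function(i) {
    cfg <- experiment_config(n_subjects = 1,
                             generating_model = object$model$name,
                             seed = sample.int(2147483646L, 1),
                             subject_dist = dist)
    simulate_experiment(cfg)
  })
  if (nsim == 1L) out[[1]] else out
}

#' Fit every planning model to every subject
#'
#' Convenience layer over [plan_fit()]: one row per subject x model with
#' the level-time estimates and fit statistics, ready for
#' [select_model()].
#'
#' @param cms Named list of `cell_means` ([cell_means()]).
#' @param models Model names (default all four).
#' @param engine,n_draws,weighted,seed Passed to [plan_fit()].
#' @return Data frame: `subject_id`, `model`, `engine`, `t1`, `t2`, `t3`,
#'   `sse`, `r2`, `adj_r2`, `n_cells`.
#' @export
fit_subjects <- function(cms, models = planning_models(),
                         engine = c("exact", "monte_carlo"),
                         n_draws = 1e4, weighted = FALSE, seed = NULL) {
  engine <- match.arg(engine)
  rows <- list()
  for (cm in cms) {
    for (mn in models) {
      f <- plan_fit(cm, mn, engine = engine, n_draws = n_draws,
                    weighted = weighted,
                    seed = if (engine == "monte_carlo") seed else NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = f$subject_id, model = mn, engine = f$engine,
        t1 = f$estimates[1], t2 = f$estimates[2], t3 = f$estimates[3],
        sse = f$sse, r2 = f$r2, adj_r2 = f$adjusted_r2,
        n_cells = f$n_cells_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Export fit results to CSV
#'
#' @param fits Data frame from [fit_subjects()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_fits_csv <- function(fits, path) {
  utils::write.csv(fits, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
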