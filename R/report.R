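# Per-subject summary values used by the group tests: first-response time
# when target 1 was withheld vs shown, the mean of responses 2-6, and
# preview-time means by condition.
.subject_summaries <- function(cms, trials, full_preview) {
  subjects <- names(cms)
  rows <- lapply(subjects, function(sid) {
    cm <- cms[[sid]]
    tr <- trials[trials$subject_id == sid, , drop = FALSE]
    if (full_preview) {
      data.frame(subject_id = sid,
                 t1 = cm$means[1, 1],
                 t2to6 = mean(cm$means[1, 2:6], na.rm = TRUE),
                 preview_all = mean(tr$preview_time),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(subject_id = sid,
                 t1_missing1 = cm$means[1, 1],
                 t1_certain = mean(cm$means[2:6, 1], na.rm = TRUE),
                 t2to6 = mean(cm$means[, 2:6], na.rm = TRUE),
                 preview_missing1 =
                   mean(tr$preview_time[tr$missing_target == 1]),
                 preview_rest =
                   mean(tr$preview_time[tr$missing_target != 1]),
                 preview_all = mean(tr$preview_time),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Group mean +/- SE curves over subjects for each cell of the design.
.group_curves <- function(cms) {
  nr <- nrow(cms[[1]]$means)
  arr <- vapply(cms, function(cm) cm$means, matrix(0, nr, 6))
  n <- length(cms)
  list(mean = apply(arr, c(1, 2), mean, na.rm = TRUE),
       se = apply(arr, c(1, 2), stats::sd, na.rm = TRUE) / sqrt(n),
       n_subjects = n)
}

#' Run a complete simulated study
#'
#' End-to-end pipeline: simulate the configured experiment, apply the
#' trial-exclusion rules, reduce to per-subject cell means, fit the four
#' planning models per subject (withheld-target mode only), select winners
#' by adjusted R-squared, and compute the group statistics: first-response
#' time when target 1 was withheld vs shown, first response vs the mean of
#' responses 2-6, and the preview-time contrast.  Full-preview studies skip
#' model fitting and instead test the effect of response number with a
#' repeated-measures ANOVA (Bonferroni pairwise) and a one-tailed test of
#' T1 against the mean of T2-T6.
#'
#' The run is deterministic given the config's seed.  With `out_dir` set,
#' the trial table, cell means, fits, report JSON and summary plots are
#' written to disk.
#'
#' @param config An [experiment_config()] (or path to its JSON).
#' @param engine Fitting engine for [plan_fit()].
#' @param n_draws Monte Carlo draws (monte_carlo engine).
#' @param weighted Count-weighted fitting switch.
#' @param cutoff,n_practice Filter settings ([filter_trials()]).
#' @param out_dir Optional output directory for artifacts.
#' @return A `study_report` object.
#' @export
run_study <- function(config, engine = c("exact", "monte_carlo"),
                      n_draws = 1e4, weighted = FALSE, cutoff = 3,
                      n_practice = 6, out_dir = NULL) {
  engine <- match.arg(engine)
  if (is.character(config)) config <- read_config_json(config)
  stopifnot(inherits(config, "experiment_config"))
  full_preview <- config$mode == "FULL_PREVIEW"

  trials <- simulate_experiment(config)
  flt <- filter_trials(trials, cutoff = cutoff, n_practice = n_practice)
  cms <- cell_means(flt$trials)
  curves <- .group_curves(cms)
  summ <- .subject_summaries(cms, flt$trials, full_preview)

  fits <- NULL; selection <- NULL; fit_summary <- NULL; tests <- list()
  if (!full_preview) {
    fits <- fit_subjects(cms, engine = engine, n_draws = n_draws,
                         weighted = weighted,
                         seed = if (engine == "monte_carlo") config$seed)
    selection <- select_model(fits)
    fit_summary <- do.call(rbind, lapply(split(fits, fits$model), function(f) {
      data.frame(model = f$model[1], mean_adj_r2 = mean(f$adj_r2),
                 se_adj_r2 = stats::sd(f$adj_r2) / sqrt(nrow(f)))
    }))
    rownames(fit_summary) <- NULL
    tests$t1_uncertain_vs_certain <-
      paired_t_one_tailed(summ$t1_missing1, summ$t1_certain, "greater")
    tests$t1_uncertain_vs_t2to6 <-
      paired_t_one_tailed(summ$t1_missing1, summ$t2to6, "greater")
    tests$t1_certain_vs_t2to6 <-
      paired_t_one_tailed(summ$t1_certain, summ$t2to6, "greater")
    tests$preview_missing1_vs_rest <-
      paired_t_one_tailed(summ$preview_missing1, summ$preview_rest, "less")
  } else {
    mat <- cbind(summ$t1, do.call(
      rbind, lapply(cms, function(cm) cm$means[1, 2:6])))
    colnames(mat) <- paste0("T", 1:6)
    tests$response_number_anova <- rm_anova(mat)
    tests$t1_vs_t2to6 <- paired_t_one_tailed(summ$t1, summ$t2to6, "less")
  }

  preview_summary <- list(
    mean = mean(summ$preview_all), sd = stats::sd(summ$preview_all),
    n = nrow(summ))

  report <- structure(list(
    config = config, filter_report = flt$report, curves = curves,
    subject_summaries = summ, fits = fits, fit_summary = fit_summary,
    selection = selection, tests = tests,
    preview_summary = preview_summary), class = "study_report")

  if (!is.null(out_dir)) .write_study_artifacts(report, trials, cms, out_dir)
  report
}

.write_study_artifacts <- function(report, trials, cms, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials_csv(trials, file.path(out_dir, "trials.csv"))
  export_cell_means_csv(cms, file.path(out_dir, "cell_means.csv"))
  if (!is.null(report$fits)) {
    export_fits_csv(report$fits, file.path(out_dir, "fits.csv"))
  }
  write_report_json(report, file.path(out_dir, "report.json"))
  grDevices::pdf(file.path(out_dir, "summary_plots.pdf"), width = 7,
                 height = 5)
  plot(report)
  grDevices::dev.off()
  invisible(out_dir)
}

#' Serialise a study report to JSON
#'
#' Versioned, schema-stable JSON mirroring the report's components; numbers
#' are written at fixed precision so identical runs give byte-identical
#' files.
#'
#' @param report A `study_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "study_report"))
  cfg <- unclass(report$config)
  tst <- lapply(report$tests, function(t) {
    if (inherits(t, "test_result")) unclass(t) else
      list(test = unclass(t$test), pairwise = t$pairwise)
  })
  payload <- list(
    schema_version = "1.0",
    config = cfg,
    filter_report = unclass(report$filter_report),
    group_mean_curve = report$curves$mean,
    group_se_curve = report$curves$se,
    fit_summary = report$fit_summary,
    selection = if (!is.null(report$selection)) list(
      counts = as.list(report$selection$counts),
      top_model = report$selection$top_model,
      k_top = report$selection$k_top,
      n_subjects = report$selection$n_subjects,
      binomial_point_p = report$selection$binomial_point_p,
      binomial_tail_p = report$selection$binomial_tail_p),
    tests = tst,
    preview_summary = report$preview_summary)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @export
print.study_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("Study report: %d subjects, %d trials each, mode %s\n",
              cfg$n_subjects, cfg$n_trials, cfg$mode))
  print(x$filter_report)
  if (!is.null(x$selection)) {
    cat("\nMean adjusted R2 by model:\n")
    for (i in seq_len(nrow(x$fit_summary))) {
      cat(sprintf("  %-22s %.3f (SE %.3f)\n", x$fit_summary$model[i],
                  x$fit_summary$mean_adj_r2[i], x$fit_summary$se_adj_r2[i]))
    }
    cat("\n")
    print(x$selection)
  }
  cat("\nGroup tests:\n")
  for (nm in names(x$tests)) {
    t <- x$tests[[nm]]
    cat(sprintf("  %-28s ", nm))
    print(if (inherits(t, "test_result")) t else t$test)
  }
  cat(sprintf("\nPreview time: M = %.2f s, SD = %.2f (n = %d)\n",
              x$preview_summary$mean, x$preview_summary$sd,
              x$preview_summary$n))
  invisible(x)
}

#' @export
plot.study_report <- function(x, ...) {
  cm <- x$curves$mean
  graphics::matplot(t(cm), type = "b", pch = 19, lty = 1,
                    xlab = "response number", ylab = "mean time (s)",
                    main = "Mean response time by withheld-target condition",
                    ...)
  if (nrow(cm) > 1) {
    graphics::legend("topright", legend = rownames(cm), col = seq_len(nrow(cm)),
                     lty = 1, cex = 0.7)
  }
  s <- x$subject_summaries
  if (!is.null(s$preview_missing1)) {
    mns <- c(mean(s$preview_missing1), mean(s$preview_rest))
    ses <- c(stats::sd(s$preview_missing1), stats::sd(s$preview_rest)) /
      sqrt(nrow(s))
    bp <- graphics::barplot(mns, names.arg = c("target 1 missing",
                                               "target 2-6 missing"),
                            ylab = "mean preview time (s)",
                            ylim = c(0, max(mns + 2 * ses)))
    graphics::arrows(bp, mns - ses, bp, mns + ses, angle = 90, code = 3,
                     length = 0.05)
  }
  invisible(x)
}

#' Compare preview times across two studies
#'
#' Pools each study's subject-level mean preview times and contrasts them
#' with Welch's t test (unequal group sizes and variances), e.g. a
#' full-preview study against pooled withheld-target studies.  Studies must
#' not share subject ids.
#'
#' @param a,b `study_report` objects.
#' @return List with the two group summaries and the `test_result`.
#' @export
compare_experiments <- function(a, b) {
  stopifnot(inherits(a, "study_report"), inherits(b, "study_report"))
  ids_a <- a$subject_summaries$subject_id
  ids_b <- b$subject_summaries$subject_id
  if (length(intersect(ids_a, ids_b))) {
    stop("studies share subject ids: ",
         paste(utils::head(intersect(ids_a, ids_b), 3), collapse = ", "),
         "...; relabel before comparing", call. = FALSE)
  }
  pa <- a$subject_summaries$preview_all
  pb <- b$subject_summaries$preview_all
  list(group_a = list(mean = mean(pa), sd = stats::sd(pa), n = length(pa)),
       group_b = list(mean = mean(pb), sd = stats::sd(pb), n = length(pb)),
       test = welch_t(pa, pb))
}
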