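#' Apply the trial-exclusion rules
#'
#' Drops the leading practice trials (by `trial_index`), then removes
#' response-time observations above the cutoff (3 s by default).  By default
#' individual observations are dropped (set to `NA`) and the trial's other
#' observations are kept; `drop = "trial"` removes the whole trial instead.
#'
#' The returned report counts observations, not trials, and includes the
#' Pearson correlation between the filtered and unfiltered grand
#' condition-by-response mean matrices (averaged over subjects) — a check
#' that filtering leaves the pattern of means intact.
#'
#' @param trials Trial data frame ([simulate_experiment()] layout).
#' @param cutoff Seconds; observations above it are excluded.
#' @param n_practice Trials with `trial_index <= n_practice` are dropped.
#' @param drop `"observation"` (default) or `"trial"`.
#' @return List with `trials` (filtered data frame) and `report`
#'   (`filter_report`: `n_total`, `n_practice_dropped`,
#'   `n_outliers_dropped`, `retention_fraction`,
#'   `correlation_filtered_unfiltered`).
#' @export
filter_trials <- function(trials, cutoff = 3, n_practice = 6,
                          drop = c("observation", "trial")) {
  drop <- match.arg(drop)
  stopifnot(is.data.frame(trials), nrow(trials) > 0, cutoff > 0)
  tcols <- paste0("t", 1:6)
  n_total <- sum(!is.na(as.matrix(trials[tcols])))
  practice <- trials$trial_index <= n_practice
  n_practice_dropped <- sum(!is.na(as.matrix(trials[practice, tcols])))
  kept <- trials[!practice, , drop = FALSE]
  if (nrow(kept) == 0L) stop("no trials remain after the practice drop",
                             call. = FALSE)
  tm <- as.matrix(kept[tcols])
  over <- !is.na(tm) & tm > cutoff
  n_outliers <- sum(over)
  unfiltered_means <- .grand_cell_means(kept)
  if (drop == "trial") {
    bad_trial <- rowSums(over) > 0
    n_outliers <- sum(!is.na(tm[bad_trial, , drop = FALSE]))
    kept <- kept[!bad_trial, , drop = FALSE]
  } else {
    tm[over] <- NA_real_
    kept[tcols] <- tm
  }
  n_after <- sum(!is.na(as.matrix(kept[tcols])))
  if (n_after == 0L) stop("all observations were filtered out", call. = FALSE)
  filtered_means <- .grand_cell_means(kept)
  ok <- !is.na(unfiltered_means) & !is.na(filtered_means)
  corr <- if (sum(ok) >= 3 && stats::sd(unfiltered_means[ok]) > 0 &&
              stats::sd(filtered_means[ok]) > 0) {
    stats::cor(unfiltered_means[ok], filtered_means[ok])
  } else NA_real_
  denom <- n_total - n_practice_dropped
  report <- structure(list(
    n_total = n_total,
    n_practice_dropped = n_practice_dropped,
    n_outliers_dropped = n_outliers,
    retention_fraction = (denom - n_outliers) / denom,
    correlation_filtered_unfiltered = corr,
    cutoff = cutoff, n_practice = n_practice, drop = drop),
    class = "filter_report")
  list(trials = kept, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "Trial filter: %d observations; %d practice dropped; %d > %.3g s dropped\n",
    x$n_total, x$n_practice_dropped, x$n_outliers_dropped, x$cutoff))
  cat(sprintf("Retention (post-practice): %.4f; filtered/unfiltered r = %s\n",
              x$retention_fraction,
              ifelse(is.na(x$correlation_filtered_unfiltered), "NA",
                     sprintf("%.5f", x$correlation_filtered_unfiltered))))
  invisible(x)
}

# Grand condition x response means over subjects: mean over subjects of the
# per-subject cell means.  Full-preview data collapse to a 1 x 6 row.
.grand_cell_means <- function(trials) {
  cms <- cell_means(trials)
  arr <- vapply(cms, function(cm) cm$means,
                matrix(0, nrow(cms[[1]]$means), 6))
  apply(arr, c(1, 2), mean, na.rm = TRUE)
}

#' Per-subject condition-by-response mean matrices
#'
#' Reduces filtered trials to each subject's 6x6 matrix of mean response
#' times (row: withheld-target condition, column: response) with per-cell
#' observation counts.  Full-preview data (no withheld target) collapse to a
#' single-row 1x6 matrix.  Empty cells are `NA` with count 0 and produce a
#' warning.
#'
#' @param trials Filtered trial data frame.
#' @return Named list (by subject) of `cell_means` objects: `subject_id`,
#'   `means`, `counts`.
#' @export
cell_means <- function(trials) {
  stopifnot(is.data.frame(trials), nrow(trials) > 0)
  tcols <- paste0("t", 1:6)
  full_preview <- all(is.na(trials$missing_target))
  subjects <- unique(trials$subject_id)
  out <- lapply(subjects, function(sid) {
    tr <- trials[trials$subject_id == sid, , drop = FALSE]
    if (full_preview) {
      tm <- as.matrix(tr[tcols])
      means <- matrix(colMeans(tm, na.rm = TRUE), 1, 6,
                      dimnames = list("full_preview", paste0("response_", 1:6)))
      counts <- matrix(colSums(!is.na(tm)), 1, 6,
                       dimnames = dimnames(means))
    } else {
      means <- matrix(NA_real_, 6, 6,
                      dimnames = list(paste0("missing_", 1:6),
                                      paste0("response_", 1:6)))
      counts <- matrix(0L, 6, 6, dimnames = dimnames(means))
      for (m in 1:6) {
        tm <- as.matrix(tr[tr$missing_target == m, tcols, drop = FALSE])
        counts[m, ] <- colSums(!is.na(tm))
        mu <- colMeans(tm, na.rm = TRUE)
        mu[counts[m, ] == 0L] <- NA_real_
        means[m, ] <- mu
      }
    }
    means[counts == 0L] <- NA_real_
    if (any(counts == 0L)) {
      warning("subject ", sid, ": ", sum(counts == 0L),
              " empty cell(s) left undefined", call. = FALSE)
    }
    structure(list(subject_id = sid, means = means, counts = counts),
              class = "cell_means")
  })
  names(out) <- subjects
  out
}

#' @export
print.cell_means <- function(x, ...) {
  cat("Cell means for subject", x$subject_id,
      sprintf("(%d observations)\n", sum(x$counts)))
  print(round(x$means, 4))
  invisible(x)
}

#' Export per-subject cell means to CSV
#'
#' Long format: one row per subject x condition x response with the cell
#' mean and observation count.
#'
#' @param cms List of `cell_means` ([cell_means()]).
#' @param path File path.
#' @return `path`, invisibly.
#' @export
export_cell_means_csv <- function(cms, path) {
  rows <- do.call(rbind, lapply(cms, function(cm) {
    nr <- nrow(cm$means)
    data.frame(
      subject_id = cm$subject_id,
      missing_target = if (nr == 1L) NA_integer_ else rep(1:6, times = 6),
      response = rep(1:6, each = nr),
      mean = as.vector(cm$means),
      count = as.vector(cm$counts))
  }))
  rownames(rows) <- NULL
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
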