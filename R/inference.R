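#' Select the winning model per subject
#'
#' For each subject, the model with the largest adjusted R-squared wins;
#' exact ties are recorded as `"TIE"` and never silently resolved.  The
#' probability of the observed winner count under chance (each of the four
#' models equally likely per subject, chance = 1/4) is reported as the
#' exact binomial point mass together with its upper tail.
#'
#' @param fits Data frame from [fit_subjects()]: one row per subject x
#'   model, single engine.
#' @param chance Per-subject chance probability of any one model (1/4).
#' @return A `model_selection` object: `winners` (named character),
#'   `counts`, `top_model`, `k_top`, `n_subjects`, `binomial_point_p`,
#'   `binomial_tail_p`.
#' @export
select_model <- function(fits, chance = 0.25) {
  stopifnot(is.data.frame(fits),
            all(c("subject_id", "model", "adj_r2") %in% names(fits)))
  if (length(unique(fits$engine)) > 1L) {
    stop("fits mix engines; select from a single engine", call. = FALSE)
  }
  subjects <- unique(fits$subject_id)
  models <- unique(fits$model)
  winners <- vapply(subjects, function(sid) {
    f <- fits[fits$subject_id == sid, ]
    miss <- setdiff(models, f$model)
    if (length(miss)) {
      stop("subject ", sid, " lacks a fit for model ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
    best <- max(f$adj_r2)
    at <- f$model[f$adj_r2 == best]
    if (length(at) > 1L) "TIE" else at
  }, "")
  counts <- table(factor(winners, levels = c(models, "TIE")))
  counts_no_tie <- counts[names(counts) != "TIE"]
  top <- names(counts_no_tie)[which.max(counts_no_tie)]
  k <- as.integer(counts_no_tie[top])
  n <- length(subjects)
  bp <- binomial_point_p(k, n, chance)
  structure(list(winners = winners, counts = counts, top_model = top,
                 k_top = k, n_subjects = n,
                 binomial_point_p = bp$point, binomial_tail_p = bp$tail),
            class = "model_selection")
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection by adjusted R-squared over", x$n_subjects,
      "subjects:\n")
  for (nm in names(x$counts)) {
    if (x$counts[[nm]] > 0) cat(sprintf("  %-22s %d\n", nm, x$counts[[nm]]))
  }
  cat(sprintf("Top model %s for %d/%d; exact binomial point p = %.4e (tail %.4e)\n",
              x$top_model, x$k_top, x$n_subjects,
              x$binomial_point_p, x$binomial_tail_p))
  invisible(x)
}

#' Exact binomial point probability
#'
#' Point mass `choose(n, k) * chance^k * (1 - chance)^(n - k)`, evaluated in
#' log space (log-gamma via `lchoose`) so that tiny probabilities such as
#' 2.2066e-19 for 37 winners out of 40 at chance 1/4 are exact to the
#' printed figures.  The companion upper tail P(X >= k) is also returned.
#'
#' @param k Successes (0..n).
#' @param n Trials.
#' @param chance Success probability in (0, 1).
#' @return List with `point` and `tail`.
#' @export
binomial_point_p <- function(k, n, chance) {
  stopifnot(k >= 0, k <= n, chance > 0, chance < 1)
  point <- exp(lchoose(n, k) + k * log(chance) + (n - k) * log1p(-chance))
  tail <- stats::pbinom(k - 1, n, chance, lower.tail = FALSE)
  list(point = point, tail = tail)
}

#' One-tailed paired t test
#'
#' Classical paired t on subject-wise differences with df = n - 1, plus the
#' repeated-measures effect size [cohens_d_rm()].
#'
#' @param x,y Paired per-subject values.
#' @param direction `"greater"` tests mean(x) > mean(y); `"less"` the
#'   reverse.
#' @return A `test_result` list: `statistic`, `df`, `p_value`,
#'   `effect_size` (d_rm), `tails = "ONE"`.
#' @export
paired_t_one_tailed <- function(x, y, direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(length(x) == length(y), length(x) >= 3)
  d <- x - y
  if (stats::sd(d) == 0) {
    warning("zero variance of paired differences; t undefined",
            call. = FALSE)
    return(.test_result(NA_real_, length(x) - 1, NA_real_, NA_real_, "ONE"))
  }
  tt <- stats::t.test(x, y, paired = TRUE, alternative = direction)
  .test_result(unname(tt$statistic), unname(tt$parameter),
               tt$p.value, cohens_d_rm(x, y), "ONE")
}

.test_result <- function(statistic, df, p, es, tails) {
  structure(list(statistic = statistic, df = df, p_value = p,
                 effect_size = es, tails = tails), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("t/F = %.4f, df = %s, %s-tailed p = %.4g, effect size = %s\n",
              x$statistic,
              paste(signif(x$df, 4), collapse = ", "),
              ifelse(identical(x$tails, "ONE"), "one", "two"),
              x$p_value,
              ifelse(is.na(x$effect_size), "NA",
                     sprintf("%.3f", x$effect_size))))
  invisible(x)
}

#' Repeated-measures Cohen's d
#'
#' Effect size for paired designs that accounts for the paired correlation
#' r: `d_rm = (mean(x - y) / sd_diff) * sqrt(2 * (1 - r))`, where
#' `sd_diff = sqrt(sd_x^2 + sd_y^2 - 2 r sd_x sd_y)` is the SD of the
#' difference scores.
#'
#' @param x,y Paired samples (n >= 3).
#' @return d_rm (`NA` with a warning when a SD or the denominator is 0).
#' @export
cohens_d_rm <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  sx <- stats::sd(x); sy <- stats::sd(y)
  if (sx == 0 || sy == 0) {
    warning("zero variance in a sample; d_rm undefined", call. = FALSE)
    return(NA_real_)
  }
  r <- stats::cor(x, y)
  denom2 <- sx^2 + sy^2 - 2 * r * sx * sy
  if (denom2 <= 0) {
    warning("degenerate paired correlation; d_rm undefined", call. = FALSE)
    return(NA_real_)
  }
  (mean(x - y) / sqrt(denom2)) * sqrt(2 * (1 - r))
}

#' One-way repeated-measures ANOVA over the six responses
#'
#' Tests the effect of response number (T1..T6) within subjects via
#' `aov(time ~ response + Error(subject))`, with df (5, 5(n-1)), and runs
#' all 15 pairwise paired t tests with Bonferroni-multiplied p values
#' (capped at 1).  The reported effect size is partial eta-squared.
#'
#' @param mat Complete numeric matrix, subjects x 6 mean response times.
#' @return List with `test` (a `test_result`, `statistic` = F,
#'   `df = c(5, 5*(n-1))`) and `pairwise` (data frame: `i`, `j`, `t`, `df`,
#'   `p_raw`, `p_bonferroni`).
#' @export
rm_anova <- function(mat) {
  mat <- as.matrix(mat)
  stopifnot(ncol(mat) == 6, nrow(mat) >= 2)
  if (anyNA(mat)) stop("rm_anova requires a complete subjects x 6 matrix",
                       call. = FALSE)
  n <- nrow(mat)
  long <- data.frame(
    time = as.vector(mat),
    response = factor(rep(1:6, each = n)),
    subject = factor(rep(seq_len(n), times = 6)))
  fit <- stats::aov(time ~ response + Error(subject), data = long)
  tab <- summary(fit)[["Error: Within"]][[1]]
  Fval <- tab["response", "F value"]
  p <- tab["response", "Pr(>F)"]
  ss_eff <- tab["response", "Sum Sq"]
  ss_err <- tab["Residuals", "Sum Sq"]
  df <- c(tab["response", "Df"], tab["Residuals", "Df"])
  pairs <- utils::combn(6, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(c0) {
    i <- pairs[1, c0]; j <- pairs[2, c0]
    tt <- stats::t.test(mat[, i], mat[, j], paired = TRUE)
    data.frame(i = i, j = j, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  }))
  pw$p_bonferroni <- pmin(pw$p_raw * nrow(pw), 1)
  list(test = .test_result(Fval, df, p, ss_eff / (ss_eff + ss_err), "TWO"),
       pairwise = pw)
}

#' Welch's t test (raw samples or summaries)
#'
#' Unequal-variance t with Welch-Satterthwaite df, for groups of unequal
#' size and spread.  Accepts raw samples or `list(mean =, sd =, n =)`
#' summaries; the pooled-SD effect size d_pooled is returned alongside.
#'
#' @param x,y Numeric vectors, or summary lists with `mean`, `sd`, `n`.
#' @return A `test_result` (two-tailed) with `effect_size` = d_pooled.
#' @export
welch_t <- function(x, y) {
  sm <- function(v) {
    if (is.list(v)) {
      stopifnot(all(c("mean", "sd", "n") %in% names(v)), v$n >= 2)
      v
    } else {
      stopifnot(length(v) >= 2)
      list(mean = mean(v), sd = stats::sd(v), n = length(v))
    }
  }
  a <- sm(x); b <- sm(y)
  if (a$sd == 0 && b$sd == 0) {
    warning("zero variance in both groups; Welch t undefined", call. = FALSE)
    return(.test_result(NA_real_, NA_real_, NA_real_, NA_real_, "TWO"))
  }
  va <- a$sd^2 / a$n; vb <- b$sd^2 / b$n
  tstat <- (a$mean - b$mean) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  sp <- sqrt(((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / (a$n + b$n - 2))
  d <- if (sp > 0) (a$mean - b$mean) / sp else NA_real_
  .test_result(tstat, df, p, d, "TWO")
}

#' A-priori sample size for a one-sample t test
#'
#' Smallest n at which a one-sample t test with noncentrality `d * sqrt(n)`
#' reaches the target power, found by iterating n over the noncentral t
#' distribution.  At d = 0.5, alpha = .05 two-sided and 80% power the
#' answer is 34 participants.
#'
#' @param d Effect size (> 0).
#' @param alpha Type-I error rate.
#' @param power Target power in (alpha, 1).
#' @param tails `"two"` (default) or `"one"`.
#' @param n_max Search limit.
#' @return Smallest sufficient n (integer).
#' @export
required_sample_size <- function(d, alpha = 0.05, power = 0.80,
                                 tails = c("two", "one"), n_max = 1e5) {
  tails <- match.arg(tails)
  stopifnot(d > 0, alpha > 0, alpha < 1, power > alpha, power < 1)
  for (n in 2:n_max) {
    df <- n - 1
    ncp <- d * sqrt(n)
    pw <- if (tails == "two") {
      crit <- stats::qt(1 - alpha / 2, df)
      1 - stats::pt(crit, df, ncp) + stats::pt(-crit, df, ncp)
    } else {
      1 - stats::pt(stats::qt(1 - alpha, df), df, ncp)
    }
    if (pw >= power) return(as.integer(n))
  }
  stop("target power not reachable within n_max", call. = FALSE)
}

#' Fisher's z transform
#'
#' `atanh(r)`; for r = 0.99934 this gives 4.008.
#'
#' @param r Correlation with |r| < 1.
#' @return z value.
#' @export
fisher_z <- function(r) {
  stopifnot(is.numeric(r))
  if (any(abs(r) >= 1)) stop("|r| must be < 1", call. = FALSE)
  atanh(r)
}
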