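# Trial times are floored here so additive Gaussian noise can never
# produce a non-positive response or preview time.
.time_floor <- 0.05

#' Subject-level generative parameters
#'
#' Bundles the quantities that characterise one simulated subject: the three
#' ordered level times that the planning models map onto response times, the
#' trial-to-trial noise, a small probability of a long-time outlier (a lapse
#' well above the 3-s analysis cutoff), and the preview-time distribution,
#' including the reduction in preview time observed when target 1 is the one
#' withheld (the subject cannot finish preparing the first response during
#' the preview, so ends the preview sooner).
#'
#' @param level_times Ascending positive triple (seconds): time to execute a
#'   fully prepared (level 1), partly prepared (level 2) and unprepared
#'   (level 3) response.
#' @param noise_sd Additive Gaussian trial noise on each response time
#'   (seconds, > 0).
#' @param outlier_prob Per-observation probability of replacing a response
#'   time by a long outlier; keep below 0.05.
#' @param outlier_range Interval (seconds) for uniform outlier draws; its
#'   lower end must exceed the 3-s filter cutoff so the filter removes
#'   exactly the injected contamination.
#' @param preview_base Mean self-paced preview time (seconds).
#' @param preview_first_missing_delta Reduction in mean preview time when
#'   target 1 is withheld (seconds).
#' @param preview_sd SD of preview times (seconds).
#' @return A `subject_params` object (validated list).
#' @export
subject_params <- function(level_times = c(0.67, 0.80, 1.20),
                           noise_sd = 0.12,
                           outlier_prob = 0.005,
                           outlier_range = c(3, 10),
                           preview_base = 3.0,
                           preview_first_missing_delta = 0.4,
                           preview_sd = 1.4) {
  stopifnot(is.numeric(level_times), length(level_times) == 3L,
            all(level_times > 0), !is.unsorted(level_times),
            is.numeric(noise_sd), noise_sd > 0,
            outlier_prob >= 0, outlier_prob <= 1,
            length(outlier_range) == 2L,
            outlier_range[1] < outlier_range[2],
            preview_base > 0, preview_sd > 0,
            preview_first_missing_delta >= 0)
  if (outlier_prob > 0 && outlier_range[1] < 3) {
    stop("outlier_range must lie above the 3-s cutoff", call. = FALSE)
  }
  structure(list(level_times = as.numeric(level_times),
                 noise_sd = noise_sd, outlier_prob = outlier_prob,
                 outlier_range = as.numeric(outlier_range),
                 preview_base = preview_base,
                 preview_first_missing_delta = preview_first_missing_delta,
                 preview_sd = preview_sd),
            class = "subject_params")
}

#' Default between-subject parameter distribution
#'
#' Each entry is either `list(fixed = value)` (a point mass) or
#' `list(mean = m, sd = s)` (Gaussian, resampled/clamped into the field's
#' legal range).  Defaults echo the group means typically seen in this task:
#' fully-prepared responses around 0.67 s, unprepared around 1.2 s, preview
#' times of about 3 s with large between-trial spread.
#'
#' @return A named list of distribution specs, one per [subject_params()]
#'   field component.
#' @export
default_subject_distribution <- function() {
  list(
    t1 = list(mean = 0.67, sd = 0.08),
    t2 = list(mean = 0.80, sd = 0.08),
    t3 = list(mean = 1.20, sd = 0.10),
    noise_sd = list(fixed = 0.12),
    outlier_prob = list(fixed = 0.005),
    outlier_low = list(fixed = 3),
    outlier_high = list(fixed = 10),
    preview_base = list(mean = 3.0, sd = 0.6),
    preview_first_missing_delta = list(mean = 0.4, sd = 0.1),
    preview_sd = list(fixed = 1.4)
  )
}

.draw_field <- function(spec, lower = -Inf, upper = Inf) {
  if (!is.list(spec)) stop("malformed distribution spec", call. = FALSE)
  if (!is.null(spec$fixed)) {
    x <- spec$fixed
  } else if (!is.null(spec$mean) && !is.null(spec$sd)) {
    x <- stats::rnorm(1, spec$mean, spec$sd)
  } else {
    stop("distribution spec needs either $fixed or $mean/$sd", call. = FALSE)
  }
  min(max(x, lower), upper)
}

#' Draw one subject's parameters from a distribution spec
#'
#' Uses the current RNG stream (seed it with `set.seed()` for
#' reproducibility).  Level times are sorted ascending after drawing, so the
#' returned object always satisfies the `subject_params` invariants.
#'
#' @param dist Distribution spec as in [default_subject_distribution()].
#' @return A `subject_params` object.
#' @export
sample_subject <- function(dist = default_subject_distribution()) {
  lt <- sort(c(.draw_field(dist$t1, lower = .time_floor),
               .draw_field(dist$t2, lower = .time_floor),
               .draw_field(dist$t3, lower = .time_floor)))
  subject_params(
    level_times = lt,
    noise_sd = .draw_field(dist$noise_sd, lower = 1e-12),
    outlier_prob = .draw_field(dist$outlier_prob, lower = 0, upper = 0.05),
    outlier_range = c(.draw_field(dist$outlier_low),
                      .draw_field(dist$outlier_high)),
    preview_base = .draw_field(dist$preview_base, lower = .time_floor),
    preview_first_missing_delta =
      .draw_field(dist$preview_first_missing_delta, lower = 0),
    preview_sd = .draw_field(dist$preview_sd, lower = 1e-6))
}

#' Experiment configuration
#'
#' Describes a simulated study.  In `WITHHELD_ONE` mode (the main design)
#' each subject runs 6 conditions x `reps_per_condition` trials in random
#' order, with one of the six targets withheld from the preview on every
#' trial; the first `n_practice` trials are practice (generated identically,
#' excluded later by preprocessing).  In `FULL_PREVIEW` mode all targets are
#' previewed on every trial, so every response is fully prepared (level 1)
#' and no planning model can be fit.
#'
#' @param n_subjects Number of subjects.
#' @param reps_per_condition Trials per withheld-target condition (default
#'   10, giving 60 trials).
#' @param n_practice Leading practice trials (default 6).
#' @param mode `"WITHHELD_ONE"` or `"FULL_PREVIEW"`.
#' @param generating_model Model generating the response-time structure
#'   (ignored in `FULL_PREVIEW` mode).
#' @param seed Integer seed; drives a per-subject substream so subject k's
#'   data are unchanged when more subjects are added.
#' @param subject_dist Between-subject parameter distribution
#'   ([default_subject_distribution()]).
#' @param n_trials Trials per subject; must equal
#'   `6 * reps_per_condition` in `WITHHELD_ONE` mode.
#' @param subject_prefix Prefix for subject ids (set differently for
#'   experiments that will be compared, so ids never collide).
#' @param full_preview_base Mean preview time used in `FULL_PREVIEW` mode
#'   (with all six targets to encode, previews run longer).
#' @return An `experiment_config` object (validated list).
#' @export
experiment_config <- function(n_subjects = 40,
                              reps_per_condition = 10,
                              n_practice = 6,
                              mode = c("WITHHELD_ONE", "FULL_PREVIEW"),
                              generating_model = "FAST_PRECRASTINATION",
                              seed = 1,
                              subject_dist = default_subject_distribution(),
                              n_trials = NULL,
                              subject_prefix = "S",
                              full_preview_base = 4.1) {
  mode <- match.arg(mode)
  if (is.null(n_trials)) n_trials <- 6L * reps_per_condition
  stopifnot(n_subjects >= 1, reps_per_condition >= 1,
            n_practice >= 0, n_practice < n_trials,
            is.numeric(seed), length(seed) == 1L)
  if (mode == "WITHHELD_ONE" && n_trials != 6L * reps_per_condition) {
    stop("in WITHHELD_ONE mode n_trials must be 6 * reps_per_condition",
         call. = FALSE)
  }
  generating_model <- build_model(generating_model)$name
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 reps_per_condition = as.integer(reps_per_condition),
                 n_practice = as.integer(n_practice),
                 mode = mode, generating_model = generating_model,
                 seed = as.integer(seed), subject_dist = subject_dist,
                 subject_prefix = subject_prefix,
                 full_preview_base = full_preview_base),
            class = "experiment_config")
}

# Deterministic per-subject seed: mixes the subject index into the global
# seed so earlier subjects are stable when n_subjects grows.
.subject_seed <- function(seed, i) {
  (abs(as.integer(seed)) + 104729L * as.integer(i)) %% 2147483647L
}

.simulate_subject <- function(config, i) {
  set.seed(.subject_seed(config$seed, i))
  pars <- sample_subject(config$subject_dist)
  nt <- config$n_trials
  if (config$mode == "WITHHELD_ONE") {
    missing <- sample(rep.int(1:6, config$reps_per_condition))
    pred <- predicted_times(config$generating_model, pars$level_times)
  } else {
    missing <- rep(NA_integer_, nt)
    pred <- matrix(pars$level_times[1], 1, 6)
  }
  rt <- matrix(NA_real_, nt, 6)
  preview <- numeric(nt)
  for (tr in seq_len(nt)) {
    row <- if (config$mode == "WITHHELD_ONE") pred[missing[tr], ] else pred[1, ]
    times <- pmax(row + stats::rnorm(6, 0, pars$noise_sd), .time_floor)
    is_out <- stats::runif(6) < pars$outlier_prob
    if (any(is_out)) {
      times[is_out] <- stats::runif(sum(is_out), pars$outlier_range[1],
                                    pars$outlier_range[2])
    }
    rt[tr, ] <- times
    pb <- if (config$mode == "FULL_PREVIEW") config$full_preview_base else
      pars$preview_base -
        pars$preview_first_missing_delta * isTRUE(missing[tr] == 1L)
    preview[tr] <- max(stats::rnorm(1, pb, pars$preview_sd), .time_floor)
  }
  data.frame(
    subject_id = sprintf("%s%02d", config$subject_prefix, i),
    trial_index = seq_len(nt),
    missing_target = missing,
    preview_time = preview,
    t1 = rt[, 1], t2 = rt[, 2], t3 = rt[, 3],
    t4 = rt[, 4], t5 = rt[, 5], t6 = rt[, 6],
    stringsAsFactors = FALSE)
}

#' Simulate an experiment
#'
#' Generates the full trial table for a configured study: per subject, a
#' seeded random permutation of the condition sequence, response times equal
#' to the generating model's predicted level time plus Gaussian noise
#' (floored at 0.05 s), occasional uniform long-time outliers, and a preview
#' time that is shorter when target 1 is the withheld one.
#'
#' @param config An [experiment_config()].
#' @return Data frame with one row per trial: `subject_id`, `trial_index`,
#'   `missing_target` (1-6, `NA` in full-preview mode), `preview_time`,
#'   `t1`..`t6` (seconds).
#' @examples
#' cfg <- experiment_config(n_subjects = 2, seed = 7)
#' trials <- simulate_experiment(cfg)
#' table(trials$missing_target[trials$subject_id == "S01"])
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  out <- do.call(rbind, lapply(seq_len(config$n_subjects),
                               function(i) .simulate_subject(config, i)))
  rownames(out) <- NULL
  out
}

#' Write / read a trial table as CSV
#'
#' Times are written with 6 decimal places so identical simulations yield
#' byte-identical files.  `missing_target` is empty for full-preview trials.
#'
#' @param trials Trial data frame from [simulate_experiment()].
#' @param path File path.
#' @return `path` (writer) or the trial data frame (reader).
#' @export
write_trials_csv <- function(trials, path) {
  df <- trials
  num <- c("preview_time", paste0("t", 1:6))
  for (v in num) df[[v]] <- sprintf("%.6f", df[[v]])
  df$missing_target <- ifelse(is.na(trials$missing_target), "",
                              as.character(trials$missing_target))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "trial_index", "missing_target", "preview_time",
            paste0("t", 1:6))
  if (!all(need %in% names(df))) {
    stop("trial CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  df$missing_target <- suppressWarnings(as.integer(df$missing_target))
  df[need]
}

#' Read an externally deposited trial CSV (best effort)
#'
#' Maps arbitrary column names onto the trial-record layout via a
#' user-supplied mapping, for re-analysing raw data deposited elsewhere.
#'
#' @param path CSV path.
#' @param mapping Named character vector: names are the canonical columns
#'   (`subject_id`, `trial_index`, `missing_target`, `preview_time`,
#'   `t1`..`t6`), values the column names in the file.
#' @return Trial data frame in canonical layout.
#' @export
read_external_trials <- function(path, mapping) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("subject_id", "trial_index", "missing_target", "preview_time",
            paste0("t", 1:6))
  stopifnot(all(need %in% names(mapping)))
  missing_cols <- setdiff(unname(mapping[need]), names(raw))
  if (length(missing_cols)) {
    stop("file lacks mapped columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  out <- raw[, unname(mapping[need])]
  names(out) <- need
  out$trial_index <- as.integer(out$trial_index)
  out$missing_target <- suppressWarnings(as.integer(out$missing_target))
  for (v in c("preview_time", paste0("t", 1:6))) out[[v]] <- as.numeric(out[[v]])
  out
}

#' Write / read an experiment configuration as JSON
#'
#' The JSON mirrors [experiment_config()]; unknown keys are rejected so
#' typos cannot silently fall back to defaults.
#'
#' @param config An `experiment_config`.
#' @param path JSON path.
#' @return `path` (writer) or an `experiment_config` (reader).
#' @export
write_config_json <- function(config, path) {
  stopifnot(inherits(config, "experiment_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config_json
#' @export
read_config_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  legal <- names(formals(experiment_config))
  legal <- c(legal[legal != "subject_dist"], "subject_dist")
  unknown <- setdiff(names(raw), legal)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(raw$subject_dist)) {
    raw$subject_dist <- lapply(raw$subject_dist, as.list)
  }
  do.call(experiment_config, raw)
}
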