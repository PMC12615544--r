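#' Names of the four planning models
#'
#' The four models describe how a person may schedule the preparation
#' ("specification") of six cued responses when one of the six targets is
#' withheld from a preview: preparation of the uncertain response can be
#' deferred as late as possible (procrastination) or done as early as
#' possible (pre-crastination), and the overall sequence can be completed
#' slowly or quickly.
#'
#' @return Character vector of the four model names.
#' @export
planning_models <- function() {
  c("SLOW_PROCRASTINATION", "FAST_PROCRASTINATION",
    "SLOW_PRECRASTINATION", "FAST_PRECRASTINATION")
}

# Hard-coded 6x6 ordinal level matrices: row = withheld-target condition m,
# column = response j.  Level 1 = fully prepared, 2 = partly prepared,
# 3 = unprepared.  These are definitional constants, not data.
.level_matrices <- local({
  rn <- paste0("missing_", 1:6)
  cn <- paste0("response_", 1:6)
  m1 <- matrix(c(3, 3, 3, 3, 3, 3,
                 1, 3, 3, 3, 3, 3,
                 1, 1, 3, 3, 3, 3,
                 1, 1, 1, 3, 3, 3,
                 1, 1, 1, 1, 3, 3,
                 1, 1, 1, 1, 1, 3), 6, 6, byrow = TRUE)
  m2 <- matrix(c(3, 1, 1, 1, 1, 1,
                 1, 3, 1, 1, 1, 1,
                 1, 1, 3, 1, 1, 1,
                 1, 1, 1, 3, 1, 1,
                 1, 1, 1, 1, 3, 1,
                 1, 1, 1, 1, 1, 3), 6, 6, byrow = TRUE)
  m3 <- matrix(c(3, 1, 1, 1, 1, 1,
                 3, 1, 1, 1, 1, 1,
                 3, 1, 1, 1, 1, 1,
                 3, 1, 1, 1, 1, 1,
                 3, 1, 1, 1, 1, 1,
                 3, 1, 1, 1, 1, 1), 6, 6, byrow = TRUE)
  m4 <- matrix(c(3, 1, 1, 1, 1, 1,
                 2, 1, 1, 1, 1, 1,
                 2, 1, 1, 1, 1, 1,
                 2, 1, 1, 1, 1, 1,
                 2, 1, 1, 1, 1, 1,
                 2, 1, 1, 1, 1, 1), 6, 6, byrow = TRUE)
  out <- list(SLOW_PROCRASTINATION = m1, FAST_PROCRASTINATION = m2,
              SLOW_PRECRASTINATION = m3, FAST_PRECRASTINATION = m4)
  lapply(out, function(m) { dimnames(m) <- list(rn, cn); m })
})

#' Build a planning model
#'
#' Constructs one of the four ordinal planning models as a `planning_model`
#' object: a 6x6 matrix of preparation levels (1 = fully prepared, 2 =
#' partly prepared, 3 = unprepared), with row `m` giving the levels of
#' responses 1..6 when target `m` was withheld from the preview, plus the
#' number of free level-time parameters (the number of distinct levels the
#' matrix uses: 2 for the first three models, 3 for fast pre-crastination).
#'
#' @param name One of [planning_models()].  Case-insensitive; spaces and
#'   hyphens may stand in for underscores.
#' @return A `planning_model` object: list with `name`, `levels` (6x6
#'   integer matrix) and `n_params`.
#' @examples
#' build_model("FAST_PRECRASTINATION")$levels[2, ]  # 2 1 1 1 1 1
#' @export
build_model <- function(name) {
  if (inherits(name, "planning_model")) return(name)
  stopifnot(is.character(name), length(name) == 1L)
  key <- toupper(gsub("[ -]", "_", name))
  if (!key %in% names(.level_matrices)) {
    stop("unknown model '", name, "'; valid names: ",
         paste(planning_models(), collapse = ", "), call. = FALSE)
  }
  lv <- .level_matrices[[key]]
  structure(list(name = key, levels = lv,
                 n_params = length(unique(as.vector(lv)))),
            class = "planning_model")
}

#' @export
print.planning_model <- function(x, ...) {
  cat("Planning model:", x$name,
      sprintf("(%d level-time parameters)\n", x$n_params))
  cat("Ordinal preparation levels (rows: withheld target; cols: response):\n")
  print(x$levels)
  invisible(x)
}

#' Predicted response times under a planning model
#'
#' Substitutes concrete level times into a model's 6x6 ordinal level matrix:
#' entry (m, j) becomes `level_times[levels[m, j]]`.
#'
#' @param model A `planning_model` or model name.
#' @param level_times Numeric triple `(t1, t2, t3)`, weakly ascending,
#'   all non-negative, in seconds.  `t2` may be `NA` for a model that does
#'   not use level 2.
#' @return 6x6 numeric matrix of predicted times (seconds).
#' @export
predicted_times <- function(model, level_times) {
  model <- build_model(model)
  stopifnot(is.numeric(level_times), length(level_times) == 3L)
  used <- sort(unique(as.vector(model$levels)))
  t <- level_times
  if (any(is.na(t[used]))) {
    stop("level_times must be defined for every level the model uses (",
         paste(used, collapse = ","), ")", call. = FALSE)
  }
  tc <- t[!is.na(t)]
  if (any(tc < 0)) {
    stop("level times must be non-negative", call. = FALSE)
  }
  if (is.unsorted(tc)) {
    stop("level times must be weakly ascending (t1 <= t2 <= t3)",
         call. = FALSE)
  }
  out <- matrix(t[model$levels], 6, 6, dimnames = dimnames(model$levels))
  out
}

#' Theoretical mean number of time steps to complete the task
#'
#' Costs each (condition, response) cell its ordinal level value and averages
#' the per-condition row sums over the six withheld-target conditions.  The
#' slow procrastination model takes 13 steps on average
#' ((18+16+14+12+10+8)/6), fast procrastination and slow pre-crastination 8,
#' and fast pre-crastination 43/6 (about 7.17) — the fastest of the four.
#'
#' @param model A `planning_model` or model name.
#' @return Mean steps (numeric scalar).
#' @export
theoretical_mean_steps <- function(model) {
  model <- build_model(model)
  mean(rowSums(model$levels))
}

#' Export a model's level matrix to CSV
#'
#' Writes the 6x6 level matrix with a `missing_target` label column and
#' `response_1..response_6` headers.
#'
#' @param model A `planning_model` or model name.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_model_csv <- function(model, path) {
  model <- build_model(model)
  df <- data.frame(missing_target = 1:6, model$levels,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
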