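TRIAL_LOG_COLUMNS <- c("subject_id", "condition", "trial_index",
                       "stimulus_id", "valence", "majority_category",
                       "trial_correct_category", "response",
                       "outcome_class", "points_delta",
                       "cumulative_points")

session_to_log_df <- function(session) {
  tr <- session$trials
  data.frame(subject_id = session$subject_id,
             condition = session$condition,
             tr[, c("trial_index", "stimulus_id", "valence",
                    "majority_category", "trial_correct_category",
                    "response", "outcome_class", "points_delta",
                    "cumulative_points")],
             stringsAsFactors = FALSE)
}

#' Write a trial log
#'
#' Serializes one session, or a whole cohort, to the package's UTF-8 CSV
#' trial-log dialect (one row per trial; columns `subject_id`, `condition`,
#' `trial_index`, `stimulus_id`, `valence`, `majority_category`,
#' `trial_correct_category`, `response`, `outcome_class`, `points_delta`,
#' `cumulative_points`). `write_trial_log()` followed by
#' [read_trial_log()] is the identity on the logged fields.
#'
#' @param x a `subject_session` or a list of them (a cohort).
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(x, path) {
  if (inherits(x, "subject_session")) x <- list(x)
  stopifnot(length(x) >= 1, all(vapply(x, inherits, logical(1),
                                       "subject_session")))
  df <- do.call(rbind, lapply(x, session_to_log_df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a trial log
#'
#' Parses and validates a trial-log CSV. Every code column is checked
#' against its legal values and violations are reported with the
#' offending row; each subject must have exactly `n_trials` rows with
#' consistent cumulative points.
#'
#' @param path CSV file in the trial-log dialect.
#' @param n_trials expected trials per subject (default 160).
#' @param config [task_config()] attached to the returned sessions.
#' @return a single `subject_session` if the file holds one subject,
#'   otherwise a named list of sessions (class `cohort`).
#' @export
read_trial_log <- function(path, n_trials = 160L, config = task_config()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  missing_cols <- setdiff(TRIAL_LOG_COLUMNS, names(df))
  if (length(missing_cols))
    stop("trial log is missing columns: ",
         paste(missing_cols, collapse = ", "))
  check <- function(col, allowed) {
    bad <- which(!(df[[col]] %in% allowed))
    if (length(bad))
      stop(sprintf("invalid %s '%s' at row %d", col,
                   as.character(df[[col]][bad[1]]), bad[1]))
  }
  check("condition", CONDITIONS)
  check("stimulus_id", STIMULI)
  check("valence", VALENCES)
  check("majority_category", c("A", "B"))
  check("trial_correct_category", c("A", "B"))
  check("response", RESPONSES)
  check("outcome_class", OUTCOME_CLASSES)
  if (!is.numeric(df$points_delta) || !is.numeric(df$cumulative_points))
    stop("points columns must be numeric")
  sessions <- lapply(split(df, df$subject_id), function(sub) {
    sub <- sub[order(sub$trial_index), , drop = FALSE]
    if (nrow(sub) != n_trials)
      stop(sprintf("subject '%s': expected %d trials, found %d",
                   sub$subject_id[1], n_trials, nrow(sub)))
    if (length(unique(sub$condition)) != 1L)
      stop(sprintf("subject '%s': inconsistent condition codes",
                   sub$subject_id[1]))
    tr <- sub[, setdiff(TRIAL_LOG_COLUMNS, c("subject_id", "condition"))]
    tr$is_optimal <- tr$response == tr$majority_category
    rownames(tr) <- NULL
    subject_session(sub$subject_id[1], sub$condition[1], tr,
                    config = config)
  })
  if (length(sessions) == 1L) sessions[[1]]
  else structure(sessions, class = "cohort")
}
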