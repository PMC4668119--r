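#' Behavioral summary of one subject
#'
#' Scores a session the way the behavioral analysis scores subjects. An
#' optimal response is a classification with the stimulus's majority
#' category, regardless of that trial's realized outcome; skips count as
#' non-optimal, so percent optimal, skips, and non-optimal classifications
#' partition each valence's trials exactly. An adaptive response is an
#' optimal classification on reward-based trials, and an optimal
#' classification or a skip on punishment-based trials (skipping removes
#' all risk of punishment). A subject is an avoider with at least one
#' skip; a frequent avoider by the configured threshold: `"count"` mode
#' requires at least 10 skips, `"percent"` mode at least 10% of trials
#' (16 of 160).
#'
#' @param session a `subject_session`.
#' @param threshold_mode `"count"` (default) or `"percent"`.
#' @return one-row data frame with `subject_id`, `condition`,
#'   `percent_optimal_reward`, `percent_optimal_punishment`,
#'   `skips_reward`, `skips_punishment`, `percent_adaptive_reward`,
#'   `percent_adaptive_punishment`, `total_points`, `avoider`,
#'   `frequent_avoider`.
#' @export
summarize_subject <- function(session,
                              threshold_mode = c("count", "percent")) {
  threshold_mode <- match.arg(threshold_mode)
  stopifnot(inherits(session, "subject_session"))
  tr <- session$trials
  optimal <- tr$response == tr$majority_category
  skip <- tr$response == "skip"
  reward <- tr$valence == "reward"
  pct <- function(x) 100 * mean(x)
  skips_total <- sum(skip)
  threshold <- if (threshold_mode == "count") 10L
               else ceiling(0.10 * nrow(tr))
  data.frame(
    subject_id = session$subject_id, condition = session$condition,
    percent_optimal_reward = pct(optimal[reward]),
    percent_optimal_punishment = pct(optimal[!reward]),
    skips_reward = sum(skip & reward),
    skips_punishment = sum(skip & !reward),
    percent_adaptive_reward = pct(optimal[reward]),
    percent_adaptive_punishment = pct((optimal | skip)[!reward]),
    total_points = utils::tail(tr$cumulative_points, 1L),
    avoider = skips_total >= 1L,
    frequent_avoider = skips_total >= threshold,
    stringsAsFactors = FALSE)
}

#' Behavioral summaries for a cohort
#'
#' @param sessions list of `subject_session` objects.
#' @param threshold_mode passed to [summarize_subject()].
#' @return data frame with one row per subject.
#' @export
summarize_cohort <- function(sessions,
                             threshold_mode = c("count", "percent")) {
  threshold_mode <- match.arg(threshold_mode)
  if (inherits(sessions, "subject_session")) sessions <- list(sessions)
  out <- do.call(rbind, lapply(sessions, summarize_subject,
                               threshold_mode = threshold_mode))
  rownames(out) <- NULL
  out
}

#' Kendall's tau-b rank correlation
#'
#' Tie-corrected rank correlation (concordant minus discordant pairs over
#' the geometric mean of tie-adjusted pair counts), the appropriate
#' nonparametric association measure when tied scores are common, as with
#' grid-valued parameter estimates and skip counts. When either variable
#' is entirely tied the coefficient is undefined: the function warns and
#' returns `NA`.
#'
#' @param x,y numeric vectors of equal length (>= 2).
#' @return tau-b in `[-1, 1]`, or `NA` if undefined.
#' @export
kendall_tau_b <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y), length(x) == length(y),
            length(x) >= 2L, !anyNA(x), !anyNA(y))
  if (length(unique(x)) < 2L || length(unique(y)) < 2L) {
    warning("tau_b undefined: a variable is entirely tied")
    return(NA_real_)
  }
  unname(stats::cor(x, y, method = "kendall"))
}

#' Cohort-level behavior report with parameter correlations
#'
#' Combines behavioral summaries with fitted parameters from one model
#' variant: per-condition means and SDs of every summary measure, tau-b of
#' each fitted parameter against total skip count across all subjects,
#' and tau-b of `rs_rew` / `rs_pun` against valence-specific skip counts
#' restricted to subjects with at least one skip of that valence (the
#' parameters are undefined for subjects who never experienced post-skip
#' feedback).
#'
#' @param sessions list of `subject_session` objects.
#' @param fit_table a [fit_cohort()] result covering these subjects.
#' @param model variant whose estimates are correlated (default
#'   `"full"`).
#' @param threshold_mode passed to [summarize_subject()].
#' @return list with `summaries` (per subject), `condition_summary`
#'   (per-condition mean/SD of each measure), `correlations` (data frame:
#'   `parameter`, `against`, `n`, `tau_b`; `tau_b` is `NA` where
#'   undefined).
#' @export
cohort_report <- function(sessions, fit_table, model = "full",
                          threshold_mode = c("count", "percent")) {
  threshold_mode <- match.arg(threshold_mode)
  summaries <- summarize_cohort(sessions, threshold_mode)
  ft <- as.data.frame(fit_table)
  ft <- ft[ft$model == model, , drop = FALSE]
  if (!nrow(ft)) stop("fit table has no rows for model '", model, "'")
  if (!setequal(ft$subject_id, summaries$subject_id))
    stop("subject ids in sessions and fit table do not match")
  ft <- ft[match(summaries$subject_id, ft$subject_id), , drop = FALSE]

  num_cols <- names(summaries)[vapply(summaries, is.numeric, logical(1))]
  condition_summary <- do.call(rbind, lapply(
    split(summaries, summaries$condition), function(d) {
      data.frame(condition = d$condition[1], n = nrow(d),
                 measure = num_cols,
                 mean = vapply(num_cols, function(cc) mean(d[[cc]]),
                               numeric(1)),
                 sd = vapply(num_cols, function(cc) stats::sd(d[[cc]]),
                             numeric(1)),
                 stringsAsFactors = FALSE)
    }))
  rownames(condition_summary) <- NULL

  total_skips <- summaries$skips_reward + summaries$skips_punishment
  safe_tau <- function(x, y) {
    if (length(x) < 2L || length(unique(x)) < 2L ||
        length(unique(y)) < 2L) NA_real_ else kendall_tau_b(x, y)
  }
  cors <- data.frame(
    parameter = PARAM_NAMES, against = "total_skips",
    n = length(total_skips),
    tau_b = vapply(PARAM_NAMES, function(p)
      safe_tau(ft[[p]], total_skips), numeric(1)),
    stringsAsFactors = FALSE)
  rew_avoiders <- summaries$skips_reward >= 1L
  pun_avoiders <- summaries$skips_punishment >= 1L
  cors <- rbind(cors, data.frame(
    parameter = c("rs_rew", "rs_pun"),
    against = c("skips_reward", "skips_punishment"),
    n = c(sum(rew_avoiders), sum(pun_avoiders)),
    tau_b = c(safe_tau(ft$rs_rew[rew_avoiders],
                       summaries$skips_reward[rew_avoiders]),
              safe_tau(ft$rs_pun[pun_avoiders],
                       summaries$skips_punishment[pun_avoiders])),
    stringsAsFactors = FALSE))
  rownames(cors) <- NULL
  list(summaries = summaries, condition_summary = condition_summary,
       correlations = cors, model = model)
}
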