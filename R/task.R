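#' Task configuration
#'
#' Describes one run of the probabilistic classification task: four
#' stimuli presented `n_per_stimulus` times each in a fully intermixed
#' order, each stimulus associated with a majority category that is
#' trial-correct on a `contingency` fraction of its trials (realized
#' exactly, e.g. 32 of 40 at the default 0.8). Stimuli S1 and S2 are
#' reward-based (correct responses win `reward_points`); S3 and S4 are
#' punishment-based (incorrect responses lose `punishment_points`).
#' Counterbalancing of category assignment is expressed by remapping
#' `majority_categories`.
#'
#' @param n_trials total trials per session.
#' @param n_per_stimulus presentations of each of the four stimuli.
#' @param contingency fraction of each stimulus's trials on which its
#'   majority category is the trial-correct category. Must yield an
#'   integral trial count.
#' @param reward_points points gained on a win (positive).
#' @param punishment_points points lost on a loss (negative).
#' @param majority_categories named character vector mapping each stimulus
#'   to its majority category ("A" or "B").
#' @return an object of class `task_config`.
#' @export
task_config <- function(n_trials = 160L, n_per_stimulus = 40L,
                        contingency = 0.8, reward_points = 25L,
                        punishment_points = -25L,
                        majority_categories = c(S1 = "A", S2 = "B",
                                                S3 = "A", S4 = "B")) {
  n_trials <- as.integer(n_trials)
  n_per_stimulus <- as.integer(n_per_stimulus)
  if (n_trials != 4L * n_per_stimulus)
    stop("n_trials must equal 4 * n_per_stimulus")
  n_major <- n_per_stimulus * contingency
  if (abs(n_major - round(n_major)) > 1e-9)
    stop(sprintf(
      "contingency %g does not divide %d trials per stimulus into whole counts",
      contingency, n_per_stimulus))
  if (!identical(sort(names(majority_categories)), sort(STIMULI)) ||
      !all(majority_categories %in% c("A", "B")))
    stop("majority_categories must map S1..S4 to 'A' or 'B'")
  if (reward_points <= 0 || punishment_points >= 0)
    stop("reward_points must be positive and punishment_points negative")
  structure(list(n_trials = n_trials, n_per_stimulus = n_per_stimulus,
                 contingency = contingency,
                 n_majority = as.integer(round(n_major)),
                 reward_points = as.integer(reward_points),
                 punishment_points = as.integer(punishment_points),
                 majority_categories = majority_categories[STIMULI]),
            class = "task_config")
}

stimulus_valence <- function(stimulus_id) {
  ifelse(stimulus_id %in% c("S1", "S2"), "reward", "punishment")
}

#' Generate a trial schedule
#'
#' Builds the full list of trial specifications and intermixes them with a
#' single seeded uniform shuffle. Contingencies are realized exactly: at
#' the defaults each stimulus contributes 32 trials on which its majority
#' category is trial-correct and 8 on which the minority category is.
#'
#' @param seed integer seed; the same seed always yields the same schedule.
#' @param config a [task_config()].
#' @return a data frame of class `trial_schedule` with columns
#'   `trial_index`, `stimulus_id`, `valence`, `majority_category`,
#'   `trial_correct_category`.
#' @examples
#' sched <- generate_schedule(1)
#' table(sched$stimulus_id, sched$trial_correct_category == sched$majority_category)
#' @export
generate_schedule <- function(seed, config = task_config()) {
  stopifnot(inherits(config, "task_config"))
  per_stim <- lapply(STIMULI, function(s) {
    maj <- config$majority_categories[[s]]
    corr <- c(rep(maj, config$n_majority),
              rep(other_category(maj),
                  config$n_per_stimulus - config$n_majority))
    data.frame(stimulus_id = s, valence = stimulus_valence(s),
               majority_category = maj, trial_correct_category = corr,
               stringsAsFactors = FALSE)
  })
  sched <- do.call(rbind, per_stim)
  ord <- with_seed(seed, sample.int(nrow(sched)))
  sched <- sched[ord, , drop = FALSE]
  sched <- cbind(trial_index = seq_len(nrow(sched)), sched)
  rownames(sched) <- NULL
  attr(sched, "config") <- config
  attr(sched, "seed") <- as.integer(seed)
  class(sched) <- c("trial_schedule", "data.frame")
  sched
}

#' Resolve the outcome of one trial
#'
#' Deterministic outcome rules: on a reward-based trial, responding with
#' the trial-correct category wins points and any other category response
#' receives the ambiguous no-feedback outcome; on a punishment-based trial,
#' responding with the trial-incorrect category loses points and the
#' correct category receives no feedback. A skip never gains or loses
#' points. In the feedback condition a skip additionally displays the
#' category that would have produced feedback: the trial-correct category
#' on reward trials ("you would have won") and its opposite on punishment
#' trials ("you would have lost"); in the no-feedback condition nothing is
#' displayed.
#'
#' @param trial a list or one-row data frame with at least `valence` and
#'   `trial_correct_category`.
#' @param response `"A"`, `"B"` or `"skip"`.
#' @param condition `"no_feedback"` or `"feedback"`.
#' @param config a [task_config()] supplying the point values.
#' @return list with `outcome_class`, `points_delta`, `display_category`
#'   (`NA` unless a skip in the feedback condition).
#' @export
resolve_outcome <- function(trial, response,
                            condition = c("no_feedback", "feedback"),
                            config = task_config()) {
  condition <- match.arg(condition)
  response <- match.arg(response, RESPONSES)
  valence <- match.arg(trial$valence, VALENCES)
  correct <- match.arg(trial$trial_correct_category, c("A", "B"))
  display <- NA_character_
  if (response == "skip") {
    outcome <- if (valence == "reward") "skip_reward_trial"
               else "skip_punishment_trial"
    delta <- 0L
    if (condition == "feedback")
      display <- if (valence == "reward") correct else other_category(correct)
  } else if (valence == "reward") {
    if (response == correct) {
      outcome <- "win"; delta <- config$reward_points
    } else {
      outcome <- "none"; delta <- 0L
    }
  } else {
    if (response != correct) {
      outcome <- "lose"; delta <- config$punishment_points
    } else {
      outcome <- "none"; delta <- 0L
    }
  }
  list(outcome_class = outcome, points_delta = as.integer(delta),
       display_category = display)
}

# Vectorized outcome resolution used when assembling simulated sessions.
resolve_outcomes_vec <- function(valence, correct, response, condition,
                                 config) {
  skip <- response == "skip"
  reward <- valence == "reward"
  outcome <- character(length(response))
  hit <- response == correct
  outcome[skip & reward] <- "skip_reward_trial"
  outcome[skip & !reward] <- "skip_punishment_trial"
  outcome[!skip & reward & hit] <- "win"
  outcome[!skip & reward & !hit] <- "none"
  outcome[!skip & !reward & !hit] <- "lose"
  outcome[!skip & !reward & hit] <- "none"
  delta <- integer(length(response))
  delta[outcome == "win"] <- config$reward_points
  delta[outcome == "lose"] <- config$punishment_points
  display <- rep(NA_character_, length(response))
  if (condition == "feedback") {
    display[skip & reward] <- correct[skip & reward]
    display[skip & !reward] <- other_category(correct[skip & !reward])
  }
  list(outcome_class = outcome, points_delta = delta,
       display_category = display)
}

#' Construct a subject session
#'
#' A session is one subject's complete pass through the task: an ordered
#' trial log plus identifying metadata and, for synthetic subjects, the
#' ground-truth generating parameters.
#'
#' @param subject_id character scalar.
#' @param condition `"no_feedback"` or `"feedback"`.
#' @param trials data frame of trial records.
#' @param ground_truth optional [agent_parameters()] (synthetic subjects).
#' @param phenotype optional phenotype label for synthetic subjects.
#' @param config the [task_config()] the session was generated under.
#' @return object of class `subject_session`.
#' @export
subject_session <- function(subject_id, condition, trials,
                            ground_truth = NULL, phenotype = NULL,
                            config = task_config()) {
  condition <- match.arg(condition, CONDITIONS)
  x <- structure(list(subject_id = as.character(subject_id),
                      condition = condition, trials = trials,
                      ground_truth = ground_truth, phenotype = phenotype,
                      config = config),
                 class = "subject_session")
  validate_session(x)
  x
}

validate_session <- function(session, n_trials = NULL) {
  stopifnot(inherits(session, "subject_session"))
  tr <- session$trials
  needed <- c("trial_index", "stimulus_id", "valence", "majority_category",
              "trial_correct_category", "response", "outcome_class",
              "points_delta", "cumulative_points")
  missing_cols <- setdiff(needed, names(tr))
  if (length(missing_cols))
    stop("trial log is missing columns: ", paste(missing_cols, collapse = ", "))
  n_expect <- n_trials %||% session$config$n_trials
  if (!is.null(n_expect) && nrow(tr) != n_expect)
    stop(sprintf("subject '%s': expected %d trials, found %d",
                 session$subject_id, n_expect, nrow(tr)))
  check_codes <- function(col, allowed) {
    bad <- which(!(tr[[col]] %in% allowed))
    if (length(bad))
      stop(sprintf("subject '%s': invalid %s '%s' at row %d",
                   session$subject_id, col, tr[[col]][bad[1]], bad[1]))
  }
  check_codes("stimulus_id", STIMULI)
  check_codes("response", RESPONSES)
  check_codes("outcome_class", OUTCOME_CLASSES)
  check_codes("valence", VALENCES)
  check_codes("majority_category", c("A", "B"))
  check_codes("trial_correct_category", c("A", "B"))
  if (!isTRUE(all(cumsum(tr$points_delta) == tr$cumulative_points)))
    stop(sprintf("subject '%s': cumulative_points do not match points_delta",
                 session$subject_id))
  invisible(session)
}

#' @export
print.subject_session <- function(x, ...) {
  nsk <- sum(x$trials$response == "skip")
  cat(sprintf("<subject_session> %s (%s): %d trials, %d skips, %d points\n",
              x$subject_id, x$condition, nrow(x$trials), nsk,
              utils::tail(x$trials$cumulative_points, 1)))
  invisible(x)
}

# 0-based integer codes consumed by the C++ likelihood/fitting core.
session_codes <- function(session) {
  tr <- session$trials
  list(stim = match(tr$stimulus_id, STIMULI) - 1L,
       resp = match(tr$response, RESPONSES) - 1L,
       outc = match(tr$outcome_class, OUTCOME_CLASSES) - 1L,
       valence = match(tr$valence, VALENCES) - 1L)
}
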