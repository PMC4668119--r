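#' Softmax action probabilities
#'
#' Maps the three expectancy values of the presented stimulus to choice
#' probabilities over (A, B, skip):
#' \deqn{\Pr(r) = \frac{e^{Q[r,s]/T}}{\sum_{j} e^{Q[j,s]/T}}}{
#'   Pr(r) = exp(Q[r,s]/T) / sum_j exp(Q[j,s]/T)}
#' computed stably by subtracting the row maximum before exponentiation.
#' `temperature = 0` is handled as the limiting case: probability 1 on the
#' argmax, split uniformly over ties (within `1e-12`).
#'
#' @param q_row numeric length-3 vector of expectancies for (A, B, skip).
#' @param temperature softmax temperature in `[0, 1]`.
#' @return named probability vector over `A`, `B`, `skip`, summing to 1.
#' @examples
#' action_probabilities(c(1, 0, 0), temperature = 1)
#' @export
action_probabilities <- function(q_row, temperature) {
  stopifnot(length(q_row) == 3L, all(is.finite(q_row)),
            is.numeric(temperature), length(temperature) == 1L,
            temperature >= 0, temperature <= 1)
  q_row <- as.numeric(q_row)
  m <- max(q_row)
  if (temperature == 0) {
    top <- q_row >= m - 1e-12
    p <- top / sum(top)
  } else {
    e <- exp((q_row - m) / temperature)
    p <- e / sum(e)
  }
  stats::setNames(p, RESPONSES)
}

#' Reinforcement value of a trial outcome
#'
#' Maps an outcome class to the scalar reinforcement that drives the
#' expectancy update: a win is fixed at +1 and a loss at -1; the
#' ambiguous no-feedback outcome takes the subjective value `r0`; the
#' feedback following a skip takes `rs_rew` or `rs_pun` depending on the
#' trial's valence. The same mapping applies in both task conditions.
#'
#' @param outcome_class one of `"win"`, `"lose"`, `"none"`,
#'   `"skip_reward_trial"`, `"skip_punishment_trial"`.
#' @param params an [agent_parameters()] object.
#' @return scalar reinforcement in `[-1, 1]`.
#' @export
reinforcement_value <- function(outcome_class, params) {
  stopifnot(inherits(params, "agent_parameters"))
  outcome_class <- match.arg(outcome_class, OUTCOME_CLASSES)
  switch(outcome_class,
         win = params$r_plus,
         lose = params$r_minus,
         none = params$r0,
         skip_reward_trial = params$rs_rew,
         skip_punishment_trial = params$rs_pun)
}

#' Prediction-error expectancy update
#'
#' One application of the dual-learning-rate delta rule: with prediction
#' error `PE = R - q`, the expectancy moves by `PE * lr_plus` when the
#' outcome was better than expected, by `PE * lr_minus` when worse, and
#' not at all when `PE = 0`. Only the chosen (response, stimulus) entry is
#' ever updated.
#'
#' @param q current expectancy.
#' @param R received reinforcement.
#' @param lr_plus,lr_minus learning rates in `[0, 1]`.
#' @return updated expectancy.
#' @export
update_expectancy <- function(q, R, lr_plus, lr_minus) {
  pe <- R - q
  if (pe > 0) q + pe * lr_plus
  else if (pe < 0) q + pe * lr_minus
  else q
}

#' Simulate one subject session
#'
#' Generative use of the model: on each scheduled trial the agent samples
#' a response from [action_probabilities()], the task resolves the
#' outcome, and the chosen entry of the expectancy table (initialized to
#' zero) is updated by [update_expectancy()] with the outcome's
#' reinforcement value. There is no counterfactual updating: the category
#' displayed after an informational skip never changes any expectancy.
#'
#' @param params [agent_parameters()]; stored in the returned session as
#'   ground truth.
#' @param schedule a [generate_schedule()] result.
#' @param condition `"no_feedback"` or `"feedback"`.
#' @param seed integer seed for the choice sequence.
#' @param subject_id identifier for the synthetic subject.
#' @return a `subject_session`.
#' @examples
#' sched <- generate_schedule(1)
#' s <- simulate_session(agent_parameters(0.4, 0.4, 0.23, r0 = 0), sched,
#'                       seed = 7)
#' sum(s$trials$response == "skip")
#' @export
simulate_session <- function(params, schedule,
                             condition = c("no_feedback", "feedback"),
                             seed, subject_id = "sim") {
  condition <- match.arg(condition)
  stopifnot(inherits(params, "agent_parameters"),
            inherits(schedule, "trial_schedule"))
  config <- attr(schedule, "config")
  stim0 <- match(schedule$stimulus_id, STIMULI) - 1L
  val0 <- match(schedule$valence, VALENCES) - 1L
  corr0 <- match(schedule$trial_correct_category, c("A", "B")) - 1L
  sim <- with_seed(seed,
    simulate_cpp(stim0, val0, corr0, params$lr_plus, params$lr_minus,
                 params$temperature, params$r0, params$rs_rew,
                 params$rs_pun))
  response <- RESPONSES[sim$response + 1L]
  res <- resolve_outcomes_vec(schedule$valence,
                              schedule$trial_correct_category,
                              response, condition, config)
  tr <- data.frame(trial_index = schedule$trial_index,
                   stimulus_id = schedule$stimulus_id,
                   valence = schedule$valence,
                   majority_category = schedule$majority_category,
                   trial_correct_category = schedule$trial_correct_category,
                   response = response,
                   outcome_class = res$outcome_class,
                   points_delta = res$points_delta,
                   cumulative_points = cumsum(res$points_delta),
                   display_category = res$display_category,
                   is_optimal = response == schedule$majority_category,
                   stringsAsFactors = FALSE)
  session <- subject_session(subject_id, condition, tr,
                             ground_truth = params, config = config)
  attr(session, "seed") <- as.integer(seed)
  session
}

#' Teacher-forced negative log likelihood of a session
#'
#' Replays the subject's logged responses and outcomes while letting the
#' expectancies evolve exactly as they would have under `params`, and
#' accumulates \eqn{-\sum_t \log \Pr(r_t)} over trials. A logged response
#' that the model assigns probability zero (possible only under the
#' `temperature = 0` argmax limit) yields `+Inf`, which is a legal,
#' comparable likelihood value. This is the plain per-trial reference
#' implementation; the grid fitter reproduces it to machine precision
#' (see [grid_negll()]).
#'
#' @param params [agent_parameters()].
#' @param session a `subject_session`.
#' @param per_trial if `TRUE`, return the vector of per-trial
#'   contributions instead of their sum.
#' @return scalar negative log likelihood (or per-trial vector).
#' @export
session_negll <- function(params, session, per_trial = FALSE) {
  stopifnot(inherits(params, "agent_parameters"),
            inherits(session, "subject_session"))
  tr <- session$trials
  if (!all(tr$stimulus_id %in% STIMULI))
    stop("session uses stimulus labels outside S1..S4")
  Q <- matrix(0, nrow = 4, ncol = 3,
              dimnames = list(STIMULI, RESPONSES))
  nll <- numeric(nrow(tr))
  for (t in seq_len(nrow(tr))) {
    s <- tr$stimulus_id[t]
    r <- tr$response[t]
    p <- action_probabilities(Q[s, ], params$temperature)
    nll[t] <- -log(p[[r]])
    R <- reinforcement_value(tr$outcome_class[t], params)
    Q[s, r] <- update_expectancy(Q[s, r], R, params$lr_plus,
                                 params$lr_minus)
  }
  if (per_trial) nll else sum(nll)
}

#' Vectorized grid likelihood
#'
#' Evaluates the teacher-forced negative log likelihood of one session at
#' many parameter points using the compiled likelihood core (the same
#' code path the grid fitter sweeps). Agrees with [session_negll()] to
#' within 1e-9 at every point.
#'
#' @param session a `subject_session`.
#' @param params matrix or data frame with columns `lr_plus`, `lr_minus`,
#'   `temperature`, `r0`, `rs_rew`, `rs_pun` (one row per point), or a
#'   single [agent_parameters()] object.
#' @return numeric vector of negative log likelihoods, one per row.
#' @export
grid_negll <- function(session, params) {
  stopifnot(inherits(session, "subject_session"))
  if (inherits(params, "agent_parameters"))
    params <- matrix(param_vector(params), nrow = 1,
                     dimnames = list(NULL, PARAM_NAMES))
  params <- as.matrix(as.data.frame(params))
  if (is.null(colnames(params))) colnames(params) <- PARAM_NAMES
  params <- params[, PARAM_NAMES, drop = FALSE]
  storage.mode(params) <- "double"
  codes <- session_codes(session)
  negll_points_cpp(codes$stim, codes$resp, codes$outc, params)
}
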