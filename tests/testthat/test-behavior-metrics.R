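# Build a 160-trial session with prescribed responses per valence.
scripted_session <- function(reward_response, punishment_response,
                             subject_id = "scripted") {
  sched <- generate_schedule(77)
  response <- ifelse(sched$valence == "reward", reward_response,
                     punishment_response)
  pick <- function(rule, i) switch(rule,
    optimal = sched$majority_category[i],
    nonoptimal = other_category(sched$majority_category[i]),
    skip = "skip")
  resp <- vapply(seq_len(nrow(sched)), function(i)
    pick(response[i], i), character(1))
  res <- avoidrl:::resolve_outcomes_vec(sched$valence,
                                        sched$trial_correct_category,
                                        resp, "no_feedback",
                                        attr(sched, "config"))
  tr <- data.frame(sched, response = resp,
                   outcome_class = res$outcome_class,
                   points_delta = res$points_delta,
                   cumulative_points = cumsum(res$points_delta),
                   is_optimal = resp == sched$majority_category,
                   stringsAsFactors = FALSE)
  subject_session(subject_id, "no_feedback", tr)
}

test_that("definitional subjects are scored exactly", {
  all_opt <- summarize_subject(scripted_session("optimal", "optimal"))
  expect_equal(all_opt$percent_optimal_reward, 100)
  expect_equal(all_opt$percent_optimal_punishment, 100)
  expect_false(all_opt$avoider)
  expect_false(all_opt$frequent_avoider)

  # optimal on reward, skip all punishment: fully adaptive on punishment
  skipper <- summarize_subject(scripted_session("optimal", "skip"))
  expect_equal(skipper$percent_adaptive_punishment, 100)
  expect_equal(skipper$percent_optimal_punishment, 0)
  expect_equal(skipper$skips_punishment, 80L)
  expect_true(skipper$avoider)
  expect_true(skipper$frequent_avoider)
})

test_that("avoider and frequent-avoider thresholds follow the configured mode", {
  one_skip <- scripted_session("optimal", "optimal")
  one_skip$trials$response[one_skip$trials$valence == "punishment"][1] <- "skip"
  one_skip$trials$outcome_class[one_skip$trials$response == "skip"] <-
    "skip_punishment_trial"
  one_skip$trials$points_delta[one_skip$trials$response == "skip"] <- 0L
  one_skip$trials$cumulative_points <- cumsum(one_skip$trials$points_delta)
  s1 <- summarize_subject(one_skip)
  expect_true(s1$avoider)
  expect_false(s1$frequent_avoider)

  make_n_skips <- function(n) {
    s <- scripted_session("optimal", "optimal")
    idx <- which(s$trials$valence == "punishment")[seq_len(n)]
    s$trials$response[idx] <- "skip"
    s$trials$outcome_class[idx] <- "skip_punishment_trial"
    s$trials$points_delta[idx] <- 0L
    s$trials$cumulative_points <- cumsum(s$trials$points_delta)
    s
  }
  ten <- make_n_skips(10)
  expect_true(summarize_subject(ten, "count")$frequent_avoider)
  expect_false(summarize_subject(ten, "percent")$frequent_avoider)
  sixteen <- make_n_skips(16)
  expect_true(summarize_subject(sixteen, "percent")$frequent_avoider)
  expect_false(summarize_subject(make_n_skips(9), "count")$frequent_avoider)
})

test_that("adaptive responding dominates optimal responding on punishment trials", {
  for (seed in c(101, 102, 103)) {
    s <- random_session(seed)
    b <- summarize_subject(s)
    expect_gte(b$percent_adaptive_punishment, b$percent_optimal_punishment)
    expect_equal(b$percent_adaptive_reward, b$percent_optimal_reward)
    expect_true(!b$frequent_avoider || b$avoider)
    expect_equal(b$total_points,
                 utils::tail(s$trials$cumulative_points, 1))
  }
})

test_that("tau-b matches brute-force pair enumeration, including ties", {
  expect_equal(kendall_tau_b(1:10, (1:10)^2), 1)
  expect_equal(kendall_tau_b(1:10, -(1:10)), -1)
  x <- c(1, 2, 2, 3)
  y <- c(1, 2, 3, 3)
  expect_equal(kendall_tau_b(x, y), tau_b_brute(x, y))
  set.seed(12)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    x <- sample(0:6, n, replace = TRUE)   # heavy ties, like grid estimates
    y <- sample(0:10, n, replace = TRUE)
    if (length(unique(x)) < 2 || length(unique(y)) < 2) next
    expect_equal(kendall_tau_b(x, y), tau_b_brute(x, y),
                 tolerance = 1e-12)
  }
  expect_warning(res <- kendall_tau_b(rep(1, 5), 1:5), "entirely tied")
  expect_true(is.na(res))
})

test_that("cohort report correlates parameters with avoidance and flags undefined cells", {
  # cohort whose r0 varies while everything else is fixed: more negative
  # valuation of the ambiguous outcome should track more skipping
  grid <- grid_spec("desk")
  r0_vals <- grid$r0
  sessions <- lapply(seq_along(r0_vals), function(i) {
    params <- agent_parameters(0.4, 0.4, 0.23, r0 = r0_vals[i],
                               rs_rew = -0.2, rs_pun = 0.5)
    lapply(1:5, function(j)
      simulate_session(params, generate_schedule(200 + j),
                       seed = 1000 * i + j,
                       subject_id = sprintf("r0_%02d_%d", i, j)))
  })
  sessions <- unlist(sessions, recursive = FALSE)
  # pseudo fit table carrying the generating parameters as estimates
  ft <- do.call(rbind, lapply(sessions, function(s) {
    data.frame(subject_id = s$subject_id, model = "full", k = 6,
               neg_lle = 0, bic = 0,
               t(vapply(avoidrl:::PARAM_NAMES,
                        function(p) s$ground_truth[[p]], numeric(1))),
               stringsAsFactors = FALSE)
  }))
  rep <- cohort_report(sessions, ft, model = "full")
  cors <- rep$correlations
  tau_r0 <- cors$tau_b[cors$parameter == "r0" &
                         cors$against == "total_skips"]
  expect_lt(tau_r0, 0)
  # fixed parameters are entirely tied: correlation undefined, flagged NA
  expect_true(is.na(cors$tau_b[cors$parameter == "lr_plus" &
                                 cors$against == "total_skips"]))
  # rs correlations restricted to subjects with >= 1 skip of that valence
  n_pun <- cors$n[cors$parameter == "rs_pun" &
                    cors$against == "skips_punishment"]
  skips_pun <- vapply(sessions, function(s)
    sum(s$trials$response == "skip" & s$trials$valence == "punishment"),
    numeric(1))
  expect_equal(n_pun, sum(skips_pun >= 1))
  expect_error(cohort_report(sessions[1:3], ft), "do not match")
})
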