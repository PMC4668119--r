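#' Random-effects Bayesian model selection (variational Dirichlet)
#'
#' Treats the model identity behind each subject's data as a random
#' effect: model frequencies `r` follow a Dirichlet(alpha) posterior
#' estimated by fixed-point iteration. Per subject `n` and model `k` the
#' assignment weight is
#' `u_nk \propto exp(psi(alpha_k) - psi(sum_j alpha_j) + L_nk)`
#' (normalized over models with max-subtraction for stability), and
#' `alpha_k = alpha0_k + sum_n u_nk`. Iteration stops when
#' `max |delta alpha| < 1e-6` (cap 10,000 iterations). Adding a constant
#' to any subject's row of log evidence leaves the result unchanged.
#'
#' @param log_evidence subjects x models matrix of log model evidence
#'   (finite; typically `-BIC/2`).
#' @param alpha0 prior Dirichlet concentrations (scalar or per model;
#'   default 1, a uniform prior over frequencies).
#' @param tol convergence tolerance on `alpha`.
#' @param max_iter iteration cap.
#' @return list with `alpha`, `expected_frequency` (`alpha / sum(alpha)`),
#'   `weights` (subjects x models), `converged`, `n_iterations`.
#' @export
variational_bms <- function(log_evidence, alpha0 = 1, tol = 1e-6,
                            max_iter = 10000L) {
  L <- as.matrix(log_evidence)
  if (!is.numeric(L) || nrow(L) < 1L || ncol(L) < 2L)
    stop("log_evidence must be a numeric matrix with >= 1 subject and >= 2 models")
  if (any(!is.finite(L))) stop("log_evidence must be finite")
  K <- ncol(L)
  if (length(alpha0) == 1L) alpha0 <- rep(alpha0, K)
  stopifnot(length(alpha0) == K, all(alpha0 > 0))
  alpha <- alpha0
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ln_u <- sweep(L, 2L, digamma(alpha) - digamma(sum(alpha)), "+")
    u <- exp(ln_u - apply(ln_u, 1L, max))
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    delta <- max(abs(alpha_new - alpha))
    alpha <- alpha_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  names(alpha) <- colnames(L)
  list(alpha = alpha, expected_frequency = alpha / sum(alpha),
       weights = u, converged = converged, n_iterations = it)
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' The exceedance probability of model `i` is the posterior probability
#' that its frequency is the largest:
#' `phi_i = Pr(r_i > r_j for all j != i | alpha)`.
#' Estimated by seeded Monte Carlo: `n_samples` frequency vectors are
#' drawn from Dirichlet(alpha) and each sample is credited to its largest
#' component (ties, a measure-zero event, are broken uniformly). The
#' sample counts partition `n_samples` exactly, so the probabilities sum
#' to 1 by construction. For two models the closed form
#' `phi_1 = 1 - I_{0.5}(alpha_1, alpha_2)` (regularized incomplete beta)
#' is available as an independent cross-check.
#'
#' @param alpha positive Dirichlet concentrations.
#' @param n_samples Monte Carlo sample count (default 1e6).
#' @param seed integer seed.
#' @return named probability vector; attribute `"counts"` holds the raw
#'   integer tallies.
#' @export
exceedance_probabilities <- function(alpha, n_samples = 1e6, seed = 1L) {
  alpha <- as.numeric(alpha)
  if (any(!is.finite(alpha)) || any(alpha <= 0))
    stop("alpha must be positive")
  K <- length(alpha)
  stopifnot(K >= 2L, n_samples >= 1)
  n_samples <- as.integer(n_samples)
  counts <- with_seed(seed, {
    total <- integer(K)
    chunk <- 250000L
    done <- 0L
    while (done < n_samples) {
      m <- min(chunk, n_samples - done)
      g <- vapply(alpha, function(a) stats::rgamma(m, shape = a),
                  numeric(m))
      if (m == 1L) g <- matrix(g, nrow = 1L)
      total <- total + tabulate(max.col(g, ties.method = "random"), K)
      done <- done + m
    }
    total
  })
  p <- counts / n_samples
  names(p) <- names(alpha)
  attr(p, "counts") <- counts
  p
}

# Closed-form exceedance for exactly two models (beta CDF); used as an
# independent cross-check of the Monte Carlo estimator.
exceedance_beta_k2 <- function(alpha) {
  stopifnot(length(alpha) == 2L, all(alpha > 0))
  p1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
  c(p1, 1 - p1)
}

#' Compare fitted models across a cohort
#'
#' Builds the subjects x models log-evidence matrix from per-subject BIC
#' values (`log evidence ~ -BIC/2`, the Laplace-style approximation),
#' runs [variational_bms()] and [exceedance_probabilities()], and bundles
#' the results.
#'
#' @param fit_table a [fit_cohort()] result (or any data frame with
#'   `subject_id`, `model`, `bic`).
#' @param models models to compare (default: all present).
#' @param alpha0 prior concentration (default 1 per model).
#' @param n_samples Monte Carlo samples for exceedance.
#' @param seed integer seed.
#' @return a `bms_result`: list with `alpha`, `alpha0`,
#'   `expected_frequency`, `exceedance`, `n_subjects`, `n_samples`,
#'   `seed`, `converged`, `n_iterations`.
#' @export
run_model_comparison <- function(fit_table, models = NULL, alpha0 = 1,
                                 n_samples = 1e6, seed = 1L) {
  ft <- as.data.frame(fit_table)
  stopifnot(all(c("subject_id", "model", "bic") %in% names(ft)))
  models <- models %||% unique(ft$model)
  subjects <- unique(ft$subject_id)
  bic <- matrix(NA_real_, length(subjects), length(models),
                dimnames = list(subjects, models))
  keep <- ft$model %in% models
  bic[cbind(match(ft$subject_id[keep], subjects),
            match(ft$model[keep], models))] <- ft$bic[keep]
  if (anyNA(bic)) {
    holes <- which(is.na(bic), arr.ind = TRUE)
    stop("fit table is missing subject x model cells: ",
         paste(sprintf("%s/%s", subjects[holes[, 1]], models[holes[, 2]]),
               collapse = ", "))
  }
  bms <- variational_bms(-bic / 2, alpha0 = alpha0)
  phi <- exceedance_probabilities(bms$alpha, n_samples = n_samples,
                                  seed = seed)
  structure(list(alpha = bms$alpha, alpha0 = rep(alpha0, length(models)),
                 expected_frequency = bms$expected_frequency,
                 exceedance = phi, n_subjects = length(subjects),
                 n_samples = as.integer(n_samples),
                 seed = as.integer(seed), converged = bms$converged,
                 n_iterations = bms$n_iterations, models = models),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat(sprintf("<bms_result> %d subjects, %d models (converged: %s, %d iterations)\n",
              x$n_subjects, length(x$models), x$converged, x$n_iterations))
  tab <- data.frame(model = x$models, alpha = unname(x$alpha),
                    expected_frequency = unname(x$expected_frequency),
                    exceedance = as.numeric(x$exceedance))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}
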