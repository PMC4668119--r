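#' Agent parameters for the avoidance Q-learning model
#'
#' Bundles the six free parameters of the full model. `lr_plus` and
#' `lr_minus` are the learning rates applied when an outcome is better
#' (positive prediction error) or worse (negative prediction error) than
#' expected; `temperature` is the softmax explore/exploit parameter (low
#' values concentrate choice on the highest expectancy); `r0` is the
#' subjective reinforcement value of the ambiguous no-feedback outcome
#' (a missed reward or a successfully avoided punishment); `rs_rew` and
#' `rs_pun` are the subjective values of the feedback that follows a skip
#' on reward-based and punishment-based trials. The explicit outcomes are
#' fixed constants: a win reinforces at +1 and a loss at -1.
#'
#' @param lr_plus,lr_minus learning rates in `[0, 1]`.
#' @param temperature softmax temperature in `[0, 1]`. `0` is interpreted
#'   as the argmax limit (ties split uniformly).
#' @param r0 value of the no-feedback outcome, in `[-1, 1]`.
#' @param rs_rew,rs_pun value of post-skip feedback on reward-based and
#'   punishment-based trials, in `[-1, 1]`.
#' @return an object of class `agent_parameters`.
#' @examples
#' p <- agent_parameters(0.4, 0.1, temperature = 0.23, r0 = 0.5)
#' reinforcement_value("none", p)
#' @export
agent_parameters <- function(lr_plus, lr_minus, temperature, r0 = 0,
                             rs_rew = 0, rs_pun = 0) {
  vals <- c(lr_plus = lr_plus, lr_minus = lr_minus,
            temperature = temperature, r0 = r0,
            rs_rew = rs_rew, rs_pun = rs_pun)
  if (!is.numeric(vals) || length(vals) != 6L || anyNA(vals) ||
      any(!is.finite(vals)))
    stop("all agent parameters must be finite numeric scalars")
  rate_like <- vals[c("lr_plus", "lr_minus", "temperature")]
  if (any(rate_like < 0 | rate_like > 1))
    stop("lr_plus, lr_minus and temperature must lie in [0, 1]")
  value_like <- vals[c("r0", "rs_rew", "rs_pun")]
  if (any(value_like < -1 | value_like > 1))
    stop("r0, rs_rew and rs_pun must lie in [-1, 1]")
  structure(c(as.list(vals), list(r_plus = 1, r_minus = -1)),
            class = "agent_parameters")
}

#' @export
print.agent_parameters <- function(x, ...) {
  cat("<agent_parameters>\n")
  cat(sprintf("  LR+ = %g  LR- = %g  T = %g\n",
              x$lr_plus, x$lr_minus, x$temperature))
  cat(sprintf("  R0 = %g  RSrew = %g  RSpun = %g  (R+ = +1, R- = -1)\n",
              x$r0, x$rs_rew, x$rs_pun))
  invisible(x)
}

#' Free parameters as a named vector
#'
#' @param params an [agent_parameters()] object.
#' @return named numeric vector in the canonical order `lr_plus`,
#'   `lr_minus`, `temperature`, `r0`, `rs_rew`, `rs_pun`.
#' @export
param_vector <- function(params) {
  stopifnot(inherits(params, "agent_parameters"))
  vapply(PARAM_NAMES, function(nm) params[[nm]], numeric(1))
}

#' Agent parameters from a vector in canonical order
#'
#' @param v numeric vector of length 6 (order as [param_vector()]).
#' @return an [agent_parameters()] object.
#' @export
params_from_vector <- function(v) {
  v <- as.numeric(v)
  agent_parameters(v[1], v[2], v[3], v[4], v[5], v[6])
}
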