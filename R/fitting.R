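#' Model variants
#'
#' The six model variants fitted to each subject, expressed as constraints
#' on the full six-parameter model:
#' \describe{
#'   \item{full}{all six parameters free (k = 6).}
#'   \item{no_RS}{`rs_rew = rs_pun = 0` (k = 4); post-skip feedback is
#'     treated as carrying no reinforcement, so the skip expectancy never
#'     leaves zero.}
#'   \item{one_RS}{`rs_rew = rs_pun` tied (k = 5).}
#'   \item{one_LR}{single learning rate `lr_plus = lr_minus` (k = 5).}
#'   \item{fixed_T}{`temperature = 0.23`, the cohort mean under the full
#'     model (k = 5). The fixed value is used exactly even though it lies
#'     off the 0.05 search lattice.}
#'   \item{no_R0}{`r0 = rs_rew = rs_pun = 0` (k = 3).}
#' }
#'
#' @param name variant name.
#' @return a `model_spec`: list with `name`, `fixed` (named values),
#'   `ties` (list of tied parameter pairs) and `k` (free parameters).
#' @export
model_spec <- function(name = c("full", "no_RS", "one_RS", "one_LR",
                                "fixed_T", "no_R0")) {
  name <- match.arg(name)
  spec <- switch(name,
    full = list(fixed = numeric(0), ties = list(), k = 6L),
    no_RS = list(fixed = c(rs_rew = 0, rs_pun = 0), ties = list(), k = 4L),
    one_RS = list(fixed = numeric(0), ties = list(c("rs_rew", "rs_pun")),
                  k = 5L),
    one_LR = list(fixed = numeric(0), ties = list(c("lr_plus", "lr_minus")),
                  k = 5L),
    fixed_T = list(fixed = c(temperature = 0.23), ties = list(), k = 5L),
    no_R0 = list(fixed = c(r0 = 0, rs_rew = 0, rs_pun = 0), ties = list(),
                 k = 3L))
  structure(c(list(name = name), spec), class = "model_spec")
}

#' All six model variants
#' @return named list of [model_spec()] objects.
#' @export
model_specs <- function() {
  nms <- c("full", "no_RS", "one_RS", "one_LR", "fixed_T", "no_R0")
  stats::setNames(lapply(nms, model_spec), nms)
}

as_model_spec <- function(model) {
  if (inherits(model, "model_spec")) model else model_spec(model)
}

#' Parameter search grids
#'
#' Value lists swept by the grid-search estimator. The `standard` preset uses
#' steps of 0.05 for the rates and temperature (21 values from 0 to 1) and
#' 0.1 for the outcome values (21 values from -1 to +1). The `desk` preset
#' coarsens the rates and temperature to steps of 0.1 (11 values) for
#' desk-scale work; outcome values keep the 0.1 step.
#'
#' @param preset `"desk"` or `"standard"`.
#' @param ... named per-parameter numeric vectors overriding the preset
#'   (names among `lr_plus`, `lr_minus`, `temperature`, `r0`, `rs_rew`,
#'   `rs_pun`).
#' @return a `grid_spec`: named list of value vectors.
#' @export
grid_spec <- function(preset = c("desk", "standard"), ...) {
  preset <- match.arg(preset)
  rate_step <- if (preset == "standard") 0.05 else 0.1
  rates <- round(seq(0, 1, by = rate_step), 10)
  values <- round(seq(-1, 1, by = 0.1), 10)
  g <- list(lr_plus = rates, lr_minus = rates, temperature = rates,
            r0 = values, rs_rew = values, rs_pun = values)
  over <- list(...)
  bad <- setdiff(names(over), PARAM_NAMES)
  if (length(bad)) stop("unknown grid parameters: ",
                        paste(bad, collapse = ", "))
  for (nm in names(over)) {
    v <- sort(unique(as.numeric(over[[nm]])))
    if (!length(v)) stop("empty value list for ", nm)
    lo <- if (nm %in% c("r0", "rs_rew", "rs_pun")) -1 else 0
    if (any(v < lo | v > 1))
      stop("grid values for ", nm, " outside parameter bounds")
    g[[nm]] <- v
  }
  structure(c(g, list(preset = preset)), class = "grid_spec")
}

#' Build the parameter lattice for a model variant
#'
#' Forms the Cartesian product of the grid values over the variant's free
#' parameters; fixed parameters take their fixed value and tied parameters
#' share one dimension. The lattice is returned as a lazy descriptor (the
#' standard-grid full model has 21^6 = 85,766,121 points); use
#' [expand_parameter_grid()] to materialize small lattices.
#'
#' @param model a [model_spec()] or variant name.
#' @param grid a [grid_spec()].
#' @return a `parameter_grid` with elements `values` (six value lists
#'   after applying constraints), `free`, `ties`, `n_points`.
#' @examples
#' build_grid("no_RS", grid_spec("standard"))$n_points  # 21^4
#' @export
build_grid <- function(model, grid = grid_spec("desk")) {
  model <- as_model_spec(model)
  stopifnot(inherits(grid, "grid_spec"))
  values <- lapply(stats::setNames(PARAM_NAMES, PARAM_NAMES),
                   function(nm) grid[[nm]])
  for (nm in names(model$fixed)) values[[nm]] <- model$fixed[[nm]]
  tied_followers <- character(0)
  for (tie in model$ties) {
    lead <- tie[1]
    for (follower in tie[-1]) {
      if (!identical(values[[follower]], values[[lead]]))
        stop("tied parameters ", lead, " and ", follower,
             " must share a value list")
      tied_followers <- c(tied_followers, follower)
    }
  }
  if (any(vapply(values, length, integer(1)) == 0L))
    stop("empty value list in grid")
  free <- setdiff(setdiff(PARAM_NAMES, names(model$fixed)), tied_followers)
  n_points <- prod(vapply(values[free], length, integer(1)))
  structure(list(model = model, values = values, free = free,
                 ties = model$ties, fixed = model$fixed,
                 n_points = n_points),
            class = "parameter_grid")
}

#' Materialize a parameter lattice
#'
#' @param pgrid a [build_grid()] result.
#' @param max_points refuse to expand lattices larger than this.
#' @return data frame with one row per lattice point and the six
#'   parameter columns.
#' @export
expand_parameter_grid <- function(pgrid, max_points = 2e6) {
  stopifnot(inherits(pgrid, "parameter_grid"))
  if (pgrid$n_points > max_points)
    stop(sprintf("lattice has %.0f points; refusing to materialize more than %.0f",
                 pgrid$n_points, max_points))
  tied_followers <- unlist(lapply(pgrid$ties, `[`, -1))
  dims <- setdiff(PARAM_NAMES, tied_followers)
  df <- expand.grid(pgrid$values[dims], KEEP.OUT.ATTRS = FALSE)
  for (tie in pgrid$ties)
    for (follower in tie[-1]) df[[follower]] <- df[[tie[1]]]
  df[, PARAM_NAMES]
}

#' Grid-search maximum-likelihood fit of one subject
#'
#' Evaluates the teacher-forced negative log likelihood
#' ([session_negll()]) at every point of the variant's parameter lattice
#' and returns the minimum, the full set of lattice points attaining it,
#' per-parameter tie ranges resolved by their median
#' ([resolve_tie_ranges()]), and the BIC. The sweep runs in compiled code
#' and is argmin-equivalent to exhaustive evaluation (asserted against a
#' naive per-trial loop in the test suite).
#'
#' @param session a `subject_session`.
#' @param model a [model_spec()] or variant name.
#' @param grid a [grid_spec()].
#' @param tol negLLE tolerance within which lattice points count as tied.
#' @param max_argmin cap on stored argmin points (the tie count is exact
#'   even when storage is truncated).
#' @return a `fit_result`: list with `subject_id`, `model`, `k`,
#'   `best_params`, `tie_range`, `neg_lle`, `bic`, `n_grid_points`,
#'   `argmin` (matrix of tied lattice points), `n_argmin`,
#'   `argmin_truncated`.
#' @export
fit_subject <- function(session, model = "full", grid = grid_spec("desk"),
                        tol = 1e-9, max_argmin = 500000L) {
  stopifnot(inherits(session, "subject_session"))
  model <- as_model_spec(model)
  pgrid <- build_grid(model, grid)
  v <- pgrid$values
  tie_lr <- any(vapply(pgrid$ties, function(t)
    setequal(t, c("lr_plus", "lr_minus")), logical(1)))
  tie_rs <- any(vapply(pgrid$ties, function(t)
    setequal(t, c("rs_rew", "rs_pun")), logical(1)))
  lr_pairs <- if (tie_lr) {
    cbind(v$lr_plus, v$lr_plus)
  } else {
    eg <- expand.grid(lr_plus = v$lr_plus, lr_minus = v$lr_minus,
                      KEEP.OUT.ATTRS = FALSE)
    cbind(eg$lr_plus, eg$lr_minus)
  }
  codes <- session_codes(session)
  res <- fit_grid_cpp(codes$stim, codes$resp, codes$outc, codes$valence,
                      lr_pairs, v$r0, v$rs_rew, v$rs_pun, v$temperature,
                      tie_rs, tol, as.integer(max_argmin))
  if (res$truncated)
    warning(sprintf("subject '%s', model '%s': argmin set truncated at %d of %.0f tied points",
                    session$subject_id, model$name, nrow(res$argmin),
                    res$n_argmin))
  ties <- resolve_tie_ranges(res$argmin)
  structure(list(subject_id = session$subject_id, model = model$name,
                 k = model$k, best_params = ties$best_params,
                 tie_range = ties$tie_range, neg_lle = res$neg_lle,
                 bic = compute_bic(res$neg_lle, model$k,
                                   nrow(session$trials)),
                 n_grid_points = res$n_grid_points,
                 argmin = res$argmin, n_argmin = res$n_argmin,
                 argmin_truncated = res$truncated),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> %s / %s: negLLE = %.4f, BIC = %.4f (k = %d, %s tied point%s)\n",
              x$subject_id, x$model, x$neg_lle, x$bic, x$k,
              format(x$n_argmin, big.mark = ","),
              if (x$n_argmin == 1) "" else "s"))
  print(x$best_params)
  invisible(x)
}

#' Resolve tie ranges of a grid argmin set
#'
#' When several lattice points fit equally well, each parameter's estimate
#' is the median of the set of values that parameter takes across the
#' argmin set (for an even number of distinct values, the midpoint of the
#' two central ones); singleton sets report their unique value. Ties are
#' resolved per parameter (marginally), so a reported estimate can fall
#' between lattice points.
#'
#' @param argmin matrix or data frame of tied lattice points with the six
#'   parameter columns.
#' @return list with `best_params` ([agent_parameters()]) and `tie_range`
#'   (named list of sorted distinct values per parameter).
#' @export
resolve_tie_ranges <- function(argmin) {
  argmin <- as.data.frame(argmin)
  if (!nrow(argmin)) stop("empty argmin set")
  stopifnot(all(PARAM_NAMES %in% names(argmin)))
  tie_range <- lapply(stats::setNames(PARAM_NAMES, PARAM_NAMES),
                      function(nm) sort(unique(argmin[[nm]])))
  est <- vapply(tie_range, stats::median, numeric(1))
  list(best_params = params_from_vector(est), tie_range = tie_range)
}

#' Bayesian Information Criterion
#'
#' `BIC = k * ln(n) + 2 * negLLE`; lower is better. With 160 trials the
#' per-parameter penalty is `ln(160) = 5.075`.
#'
#' @param neg_lle non-negative negative log likelihood.
#' @param k number of free parameters.
#' @param n number of observations (trials), default 160.
#' @return scalar BIC.
#' @export
compute_bic <- function(neg_lle, k, n = 160L) {
  if (!is.numeric(neg_lle) || length(neg_lle) != 1L || is.na(neg_lle) ||
      neg_lle < 0)
    stop("neg_lle must be a non-negative scalar")
  if (k < 0 || n < 1) stop("k must be >= 0 and n >= 1")
  k * log(n) + 2 * neg_lle
}

#' Fit a cohort of subjects under several model variants
#'
#' @param sessions list of `subject_session` objects (unique subject ids).
#' @param models character vector of variant names or list of
#'   [model_spec()]s.
#' @param grid a [grid_spec()].
#' @param ... passed to [fit_subject()].
#' @return data frame (class `fit_table`) with one row per subject x
#'   model: `subject_id`, `model`, `k`, `neg_lle`, `bic`, the six
#'   parameter estimates and `n_tied`. The full `fit_result` objects are
#'   attached as attribute `"fits"`.
#' @export
fit_cohort <- function(sessions, models = names(model_specs()),
                       grid = grid_spec("desk"), ...) {
  if (inherits(sessions, "subject_session")) sessions <- list(sessions)
  ids <- vapply(sessions, function(s) s$subject_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate subject_id: ", ids[duplicated(ids)][1])
  models <- lapply(models, as_model_spec)
  fits <- list()
  rows <- list()
  for (s in sessions) {
    for (m in models) {
      f <- fit_subject(s, m, grid, ...)
      fits[[paste(s$subject_id, m$name, sep = ".")]] <- f
      est <- param_vector(f$best_params)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = s$subject_id, model = m$name, k = f$k,
        neg_lle = f$neg_lle, bic = f$bic, t(est),
        n_tied = f$n_argmin, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  class(tab) <- c("fit_table", "data.frame")
  tab
}
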