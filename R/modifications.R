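#' Modifications: the optimiser-problem interface
#'
#' A modification is the set of binary settings that mediate between an
#' optimiser's search space and the model parameter space: log transforms
#' (applied to a problem-specific set of parameters), scale-factor
#' transforms (rescaling so the data-generating parameters map to one),
#' rectangular parameter bounds, and transition-rate bounds. Optimiser
#' hyperparameter overrides ride along as a named list.
#'
#' @param log_transform,scale_transform,parameter_bounds,rate_bounds
#'   Logical on/off flags.
#' @param hyperparameters Named list of optimiser hyperparameter overrides.
#' @return An object of class `modification`.
#' @export
modification <- function(log_transform = FALSE, scale_transform = FALSE,
                         parameter_bounds = FALSE, rate_bounds = FALSE,
                         hyperparameters = list()) {
  structure(list(log_transform = isTRUE(log_transform),
                 scale_transform = isTRUE(scale_transform),
                 parameter_bounds = isTRUE(parameter_bounds),
                 rate_bounds = isTRUE(rate_bounds),
                 hyperparameters = hyperparameters),
            class = "modification")
}

#' Map parameters between model space and optimiser search space
#'
#' The scale transform (if enabled) divides by the problem's true
#' parameters, so the truth maps to a vector of ones; the log transform (if
#' enabled) then takes `log` of the problem's designated log-parameter set.
#' `from_search_space()` is the exact inverse.
#'
#' @param params Model-space parameter vector (`to_search_space`) or
#'   search-space vector (`from_search_space`).
#' @param mod A [modification()].
#' @param problem A benchmark problem (see [build_problem()]).
#' @return The transformed vector.
#' @export
to_search_space <- function(params, mod, problem) {
  x <- params
  if (mod$scale_transform) x <- x / problem$p_star
  if (mod$log_transform && length(problem$log_idx)) {
    if (any(x[problem$log_idx] <= 0)) {
      stop("log transform requires positive parameters", call. = FALSE)
    }
    x[problem$log_idx] <- log(x[problem$log_idx])
  }
  x
}

#' @rdname to_search_space
#' @export
from_search_space <- function(params, mod, problem) {
  x <- params
  if (mod$log_transform && length(problem$log_idx)) {
    x[problem$log_idx] <- exp(x[problem$log_idx])
  }
  if (mod$scale_transform) x <- x * problem$p_star
  x
}

# Jacobian diag d(model params)/d(search params) at a search-space point
transform_jacobian <- function(x_search, mod, problem) {
  p <- from_search_space(x_search, mod, problem)
  d <- rep(1, length(p))
  if (mod$log_transform && length(problem$log_idx)) {
    # p = s * exp(x) with s = p_star (scaled) or 1, so dp/dx = p
    d[problem$log_idx] <- p[problem$log_idx]
  }
  if (mod$scale_transform) {
    nolog <- setdiff(seq_along(p), if (mod$log_transform) problem$log_idx
                     else integer())
    d[nolog] <- problem$p_star[nolog]
  }
  d
}

#' Discontinuous bound-violation penalty
#'
#' When bounds are enabled and violated, the model is not solved; instead a
#' penalty is returned that jumps discontinuously to at least 1e5 at the
#' bound and grows with the violation distance `d` as
#' `1e5 * (1 + log(1 + d))` per violated bound, summed over parameter-bound
#' violations and (via the maximum transition rate over the physiological
#' voltage range) rate-bound violations. A value exactly at a bound counts
#' as a violation.
#'
#' @param params Model-space parameter vector.
#' @param lower,upper Parameter bounds (recycled to length of `params`).
#' @param rates List of [rate_expr()] carrying their own `lb`/`ub`; may be
#'   empty.
#' @return Non-negative scalar; zero iff strictly inside all bounds.
#' @export
penalty <- function(params, lower = NULL, upper = NULL, rates = list()) {
  H <- function(x) as.numeric(x >= 0)  # Heaviside with H(0) = 1
  term <- function(d) H(d) * (1 + log(1 + pmax(d, 0)))
  pen <- 0
  if (!is.null(lower)) pen <- pen + sum(term(lower - params))
  if (!is.null(upper)) pen <- pen + sum(term(params - upper))
  for (r in rates) {
    mr <- max_rate(r, params)
    pen <- pen + term(r$lb - mr) + term(mr - r$ub)
  }
  unname(1e5 * pen)
}

# Subgradient of the penalty: zero strictly inside bounds, derivative of
# the log terms outside; rate terms chain through d(max rate)/dp.
penalty_gradient <- function(params, lower = NULL, upper = NULL,
                             rates = list()) {
  g <- numeric(length(params))
  if (!is.null(lower)) {
    d <- lower - params
    v <- d >= 0
    g[v] <- g[v] - 1 / (1 + d[v])
  }
  if (!is.null(upper)) {
    d <- params - upper
    v <- d >= 0
    g[v] <- g[v] + 1 / (1 + d[v])
  }
  for (r in rates) {
    mr <- max_rate(r, params)
    vmax <- argmax_rate_voltage(r, params)
    dr <- rate_grad(r, params, vmax)
    if (r$lb - mr >= 0) g <- g - dr / (1 + r$lb - mr)
    if (mr - r$ub >= 0) g <- g + dr / (1 + mr - r$ub)
  }
  unname(1e5 * g)
}

# voltage at which the maximum rate is attained (for the subgradient)
argmax_rate_voltage <- function(rate, params, v_range = c(-120, 60)) {
  switch(rate$kind,
    pos_exp = if (params[rate$b_index] >= 0) v_range[2] else v_range[1],
    neg_exp = if (params[rate$b_index] >= 0) v_range[1] else v_range[2],
    constant = 0,
    general = {
      v <- seq(v_range[1], v_range[2], by = 1)
      v[which.max(rate$fun(params, v))]
    }
  )
}

#' Check bounds for a proposed parameter vector
#'
#' `in_bounds` is `TRUE` iff the penalty under the active bounds is zero.
#' Which bounds are active follows the modification, except that problems
#' flagged `force_bounds` (the wide-search staircase problems) always have
#' parameter and rate bounds active.
#'
#' @param params Model-space parameter vector.
#' @param mod A [modification()].
#' @param problem A benchmark problem.
#' @return A list: `in_bounds`, `penalty`, and the active bound sets.
#' @export
check_bounds <- function(params, mod, problem) {
  use_pb <- mod$parameter_bounds || isTRUE(problem$force_bounds)
  use_rb <- mod$rate_bounds || isTRUE(problem$force_bounds)
  lower <- if (use_pb) problem$lower else NULL
  upper <- if (use_pb) problem$upper else NULL
  rates <- if (use_rb) problem$rates else list()
  pen <- penalty(params, lower, upper, rates)
  list(in_bounds = pen == 0, penalty = pen,
       lower = lower, upper = upper, rates = rates)
}
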