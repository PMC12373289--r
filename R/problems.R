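# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

new_benchmark_problem <- function(name, model, protocol, p_star, sampling,
                                  lower, upper, log_idx, sigma = 0,
                                  data_seed = 1L, cost_kind = "trace_rmse",
                                  cost_threshold = NA_real_,
                                  n_run_default = 10L,
                                  force_bounds = FALSE,
                                  sampling_reject_rates = FALSE,
                                  settings = solver_settings(),
                                  param_names = NULL) {
  stopifnot(length(lower) == length(p_star),
            length(upper) == length(p_star),
            all(lower < upper))
  pr <- structure(list(
    name = name, model = model, protocol = protocol,
    p_star = p_star, sampling = sampling,
    lower = lower, upper = upper, rates = model$rates,
    log_idx = log_idx, sigma = sigma, data_seed = data_seed,
    cost_kind = cost_kind, cost_threshold = cost_threshold,
    n_run_default = as.integer(n_run_default),
    force_bounds = force_bounds,
    sampling_reject_rates = sampling_reject_rates,
    settings = settings,
    param_names = param_names %||% paste0("p", seq_along(p_star)),
    data = NULL
  ), class = "benchmark_problem")
  pr$data <- generate_data(pr, data_seed)
  pr
}

#' @export
print.benchmark_problem <- function(x, ...) {
  cat("<benchmark_problem> ", x$name, "\n",
      "  parameters: ", length(x$p_star),
      "  cost: ", x$cost_kind,
      if (x$sigma > 0) paste0("  (iid noise, sd = ", x$sigma, ")")
      else "  (noise free)", "\n",
      "  success threshold: ", format(x$cost_threshold), "\n", sep = "")
  invisible(x)
}

#' Number of parameters of a problem
#' @param problem A benchmark problem.
#' @return Integer.
#' @export
n_parameters <- function(problem) length(problem$p_star)

#' Regenerate a problem's data
#'
#' Noise-free problems return exactly the model output at the true
#' parameters (so the cost at truth is zero by construction); noisy
#' problems add i.i.d. Gaussian noise with the problem's stored standard
#' deviation, deterministically for a given seed.
#'
#' @param problem A benchmark problem.
#' @param seed RNG seed (defaults to the problem's stored data seed).
#' @return For trace problems, a numeric vector over the protocol's
#'   sampling times; for summary-statistic problems, a tibble of curves.
#' @export
generate_data <- function(problem, seed = problem$data_seed) {
  if (problem$cost_kind == "summary_stats") {
    return(compute_summary_statistics(problem$model, problem$p_star))
  }
  sim <- solve_model(problem$model, problem$protocol, problem$p_star)
  if (is_sim_failure(sim)) {
    stop("data generation failed at the true parameters", call. = FALSE)
  }
  y <- sim$current
  if (problem$sigma > 0) {
    y <- y + with_seed(seed, stats::rnorm(length(y), 0, problem$sigma))
  }
  y
}

# residual vector scaled so that ||r||_2 equals the reported cost
problem_residuals_raw <- function(problem, params) {
  if (problem$cost_kind == "summary_stats") {
    ss <- compute_summary_statistics(problem$model, params)
    if (is_sim_failure(ss)) return(ss)
    r <- ss$value - problem$data$value
  } else {
    sim <- solve_model(problem$model, problem$protocol, params)
    if (is_sim_failure(sim)) return(sim)
    r <- sim$current - problem$data
  }
  r / sqrt(length(r))
}

#' Cost of a parameter vector
#'
#' The root-mean-square error between the simulated and data traces (trace
#' problems) or between the simulated and data summary-statistic curves.
#' If bounds active under `mod` are violated, the model is *not* solved and
#' the discontinuous [penalty()] is returned instead. A failed simulation
#' maps to the large finite cost `1e5 + number of failed points`, so
#' optimisers can rank failures. Every call is recorded on `tracker` when
#' one is supplied.
#'
#' @param problem A benchmark problem (see [build_problem()]).
#' @param params Model-space parameter vector.
#' @param mod A [modification()] deciding which bounds are active.
#' @param tracker Optional [new_tracker()] ledger.
#' @return Non-negative scalar cost.
#' @export
problem_cost <- function(problem, params, mod = modification(),
                         tracker = NULL) {
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  bc <- check_bounds(params, mod, problem)
  if (!bc$in_bounds) {
    if (!is.null(tracker)) {
      record_evaluation(tracker, params, bc$penalty, in_bounds = FALSE,
                        solved = FALSE)
    }
    return(bc$penalty)
  }
  t0 <- proc.time()["elapsed"]
  r <- problem_residuals_raw(problem, params)
  dt <- unname(proc.time()["elapsed"] - t0)
  cost <- if (is_sim_failure(r)) 1e5 + r$n_failed else sqrt(sum(r^2))
  if (!is.null(tracker)) {
    record_evaluation(tracker, params, cost, in_bounds = TRUE,
                      solved = TRUE, with_sensitivities = FALSE,
                      wall_time_s = dt)
  }
  cost
}

#' Gradient of the cost
#'
#' Inside the bounds the gradient is computed from a sensitivity solve
#' (recorded as one gradient evaluation): for an RMSE cost `C`,
#' `dC/dp = (1/C) * mean(residual * dsim/dp)`, defined as zero at an exact
#' zero of the cost. Summary-statistic costs use central finite differences
#' of the cost, still charged as a single gradient solve. Outside the
#' bounds the subgradient of the penalty is returned without solving.
#'
#' @inheritParams problem_cost
#' @return Gradient vector (model space).
#' @export
problem_gradient <- function(problem, params, mod = modification(),
                             tracker = NULL) {
  if (any(!is.finite(params))) stop("non-finite parameters", call. = FALSE)
  bc <- check_bounds(params, mod, problem)
  if (!bc$in_bounds) {
    if (!is.null(tracker)) {
      record_evaluation(tracker, params, bc$penalty, in_bounds = FALSE,
                        solved = FALSE)
    }
    return(penalty_gradient(params, bc$lower, bc$upper, bc$rates))
  }
  t0 <- proc.time()["elapsed"]
  rj <- problem_res_jac_raw(problem, params)
  dt <- unname(proc.time()["elapsed"] - t0)
  if (is_sim_failure(rj)) {
    if (!is.null(tracker)) {
      record_evaluation(tracker, params, 1e5 + rj$n_failed,
                        in_bounds = TRUE, solved = TRUE,
                        with_sensitivities = TRUE, wall_time_s = dt)
    }
    return(rep(0, length(params)))
  }
  cost <- sqrt(sum(rj$r^2))
  g <- if (cost == 0) rep(0, length(params))
       else as.numeric(crossprod(rj$J, rj$r)) / cost
  if (!is.null(tracker)) {
    record_evaluation(tracker, params, cost, in_bounds = TRUE,
                      solved = TRUE, with_sensitivities = TRUE,
                      wall_time_s = dt)
  }
  g
}

# residuals and jacobian (scaled like problem_residuals_raw)
problem_res_jac_raw <- function(problem, params) {
  if (problem$cost_kind == "summary_stats") {
    r0 <- problem_residuals_raw(problem, params)
    if (is_sim_failure(r0)) return(r0)
    np <- length(params)
    J <- matrix(0, length(r0), np)
    for (i in seq_len(np)) {
      h <- 1e-6 * max(abs(params[i]), 1e-3)
      pp <- params; pp[i] <- pp[i] + h
      pm <- params; pm[i] <- pm[i] - h
      rp <- problem_residuals_raw(problem, pp)
      rm <- problem_residuals_raw(problem, pm)
      if (is_sim_failure(rp) || is_sim_failure(rm)) {
        return(sim_failure(length(r0)))
      }
      J[, i] <- (rp - rm) / (2 * h)
    }
    return(list(r = r0, J = J))
  }
  sim <- solve_with_sensitivities(problem$model, problem$protocol, params,
                                  problem$settings)
  if (is_sim_failure(sim)) return(sim)
  m <- length(sim$current)
  list(r = (sim$current - problem$data) / sqrt(m),
       J = sim$sensitivities / sqrt(m))
}

#' Sample initial parameter vectors
#'
#' Draws starting points from the problem's sampling region: per-parameter
#' log-uniform factors around the truth, uniform offsets, uniform
#' fractions, or box draws, with optional rejection against the rate
#' bounds (staircase-style regions). The sampler is part of the problem:
#' it never depends on an approach's modification, so all approaches share
#' identical starts for a given seed.
#'
#' @param problem A benchmark problem.
#' @param n Number of vectors.
#' @param seed RNG seed.
#' @return An `n` x `n_parameters` matrix, rows are parameter vectors.
#' @export
sample_initial_parameters <- function(problem, n, seed) {
  stopifnot(n >= 1)
  np <- n_parameters(problem)
  draw_one <- function() {
    p <- numeric(np)
    for (i in seq_len(np)) {
      s <- problem$sampling[[i]]
      p[i] <- switch(s$kind,
        log_uniform_factor = problem$p_star[i] *
          exp(stats::runif(1, log(s$lo %||% 0.1), log(s$hi %||% 10))),
        uniform_offset = problem$p_star[i] +
          stats::runif(1, -(s$width %||% 60), s$width %||% 60),
        uniform_fraction = problem$p_star[i] *
          (1 + stats::runif(1, -(s$frac %||% 0.25), s$frac %||% 0.25)),
        log_uniform_box = exp(stats::runif(1, log(problem$lower[i]),
                                           log(problem$upper[i]))),
        uniform_box = stats::runif(1, problem$lower[i], problem$upper[i]),
        stop("unknown sampling kind: ", s$kind, call. = FALSE)
      )
    }
    p
  }
  with_seed(seed, {
    out <- matrix(NA_real_, n, np)
    attempts <- 0L
    for (k in seq_len(n)) {
      repeat {
        attempts <- attempts + 1L
        if (attempts > 1e6) {
          stop("rejection sampling exceeded 1e6 attempts", call. = FALSE)
        }
        p <- draw_one()
        ok <- all(p > problem$lower & p < problem$upper)
        if (ok && problem$sampling_reject_rates) {
          ok <- penalty(p, rates = problem$rates) == 0
        }
        if (ok) break
      }
      out[k, ] <- p
    }
    colnames(out) <- problem$param_names
    out
  })
}

#' Attach a modification and tracker: the optimiser-facing black box
#'
#' Returns the closure bundle an optimiser sees: cost, gradient, residuals
#' and residual-Jacobian in *search* space, search-space box bounds (when
#' parameter bounds are active), and a seeded start sampler. Optimisers
#' never touch the truth, the data, or the bound geometry beyond this
#' surface.
#'
#' @param problem A benchmark problem.
#' @param mod A [modification()].
#' @param tracker A [new_tracker()]; every evaluation is recorded on it.
#' @return A list of closures and metadata (class `modified_problem`).
#' @export
modified_problem <- function(problem, mod, tracker) {
  np <- n_parameters(problem)
  use_pb <- mod$parameter_bounds || isTRUE(problem$force_bounds)
  lower <- if (use_pb) to_search_space(problem$lower, mod, problem)
           else rep(-Inf, np)
  upper <- if (use_pb) to_search_space(problem$upper, mod, problem)
           else rep(Inf, np)

  cost <- function(x) {
    problem_cost(problem, from_search_space(x, mod, problem), mod, tracker)
  }
  gradient <- function(x) {
    g <- problem_gradient(problem, from_search_space(x, mod, problem),
                          mod, tracker)
    g * transform_jacobian(x, mod, problem)
  }
  residuals <- function(x) {
    p <- from_search_space(x, mod, problem)
    bc <- check_bounds(p, mod, problem)
    m <- trace_length(problem)
    if (!bc$in_bounds) {
      record_evaluation(tracker, p, bc$penalty, in_bounds = FALSE,
                        solved = FALSE)
      return(rep(bc$penalty / sqrt(m), m))
    }
    t0 <- proc.time()["elapsed"]
    r <- problem_residuals_raw(problem, p)
    dt <- unname(proc.time()["elapsed"] - t0)
    if (is_sim_failure(r)) {
      cst <- 1e5 + r$n_failed
      record_evaluation(tracker, p, cst, solved = TRUE, wall_time_s = dt)
      return(rep(cst / sqrt(m), m))
    }
    record_evaluation(tracker, p, sqrt(sum(r^2)), solved = TRUE,
                      wall_time_s = dt)
    r
  }
  jacobian <- function(x) {
    p <- from_search_space(x, mod, problem)
    bc <- check_bounds(p, mod, problem)
    m <- trace_length(problem)
    tj <- transform_jacobian(x, mod, problem)
    if (!bc$in_bounds) {
      record_evaluation(tracker, p, bc$penalty, in_bounds = FALSE,
                        solved = FALSE)
      gp <- penalty_gradient(p, bc$lower, bc$upper, bc$rates) * tj
      return(matrix(gp / sqrt(m), m, np, byrow = TRUE))
    }
    t0 <- proc.time()["elapsed"]
    rj <- problem_res_jac_raw(problem, p)
    dt <- unname(proc.time()["elapsed"] - t0)
    if (is_sim_failure(rj)) {
      record_evaluation(tracker, p, 1e5 + rj$n_failed, solved = TRUE,
                        with_sensitivities = TRUE, wall_time_s = dt)
      return(matrix(0, m, np))
    }
    record_evaluation(tracker, p, sqrt(sum(rj$r^2)), solved = TRUE,
                      with_sensitivities = TRUE, wall_time_s = dt)
    sweep(rj$J, 2, tj, `*`)
  }
  sample_starts <- function(n, seed) {
    m <- sample_initial_parameters(problem, n, seed)
    t(apply(m, 1, to_search_space, mod = mod, problem = problem))
  }
  feasible <- function(x) {
    # bound probe: infeasible attempts are recorded (penalty, no solve),
    # mirroring how the harness charges out-of-bounds proposals
    p <- from_search_space(x, mod, problem)
    bc <- check_bounds(p, mod, problem)
    if (!bc$in_bounds) {
      record_evaluation(tracker, p, bc$penalty, in_bounds = FALSE,
                        solved = FALSE)
    }
    bc$in_bounds
  }
  structure(list(cost = cost, gradient = gradient, residuals = residuals,
                 jacobian = jacobian, sample_starts = sample_starts,
                 feasible = feasible,
                 lower = lower, upper = upper, n_par = np,
                 mod = mod, tracker = tracker),
            class = "modified_problem")
}

trace_length <- function(problem) {
  if (problem$cost_kind == "summary_stats") nrow(problem$data)
  else length(problem$data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
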