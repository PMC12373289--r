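#' Termination criteria for a benchmark run
#'
#' A run ends when any of these fires, checked at every function
#' evaluation: the best cost drops below the problem's success threshold
#' (success); the best cost has improved by less than
#' `improvement_epsilon` over the last `stagnation_window` model solves
#' (out-of-bounds penalty evaluations do not count towards the window);
#' or a very large cap on total model solves is reached, set high enough
#' (2.5e4; 1e4 for genetic algorithms) to discourage termination by
#' iteration count.
#'
#' @param cost_threshold Success threshold on the cost.
#' @param stagnation_window Model solves over which improvement is measured.
#' @param improvement_epsilon Minimum improvement that resets stagnation.
#' @param max_evaluations Cap on total model solves.
#' @param wall_clock_s Optional wall-clock cap in seconds (`Inf` = off).
#' @return An object of class `termination_spec`.
#' @export
termination_spec <- function(cost_threshold,
                             stagnation_window = 2500,
                             improvement_epsilon = 1e-7,
                             max_evaluations = 2.5e4,
                             wall_clock_s = Inf) {
  stopifnot(cost_threshold > 0, stagnation_window > 0,
            improvement_epsilon > 0, max_evaluations > 0)
  structure(list(cost_threshold = cost_threshold,
                 stagnation_window = stagnation_window,
                 improvement_epsilon = improvement_epsilon,
                 max_evaluations = max_evaluations,
                 wall_clock_s = wall_clock_s),
            class = "termination_spec")
}

#' Per-run evaluation tracker
#'
#' The tracker is the harness's ledger: every parameter vector an optimiser
#' attempts is recorded, with whether it was inside the active bounds,
#' whether the model was solved (and with or without sensitivities), the
#' wall time of the solve, the cost (including penalties), and the running
#' best cost. It is a mutable environment so that black-box cost closures
#' can update it.
#'
#' @param spec A [termination_spec()].
#' @param keep_records Keep the full per-evaluation record list (versus
#'   counters and the best-cost history only).
#' @return An object of class `eval_tracker` (an environment).
#' @export
new_tracker <- function(spec, keep_records = TRUE) {
  tr <- new.env(parent = emptyenv())
  tr$spec <- spec
  tr$keep_records <- isTRUE(keep_records)
  tr$n_cost <- 0L
  tr$n_grad <- 0L
  tr$n_oob <- 0L
  tr$best_cost <- Inf
  tr$best_params <- NULL
  tr$status <- "running"
  tr$t_start <- unname(proc.time()["elapsed"])
  tr$history <- numeric(4096)  # best cost after each model solve
  tr$n_hist <- 0L
  tr$records <- vector("list", 256)
  tr$n_rec <- 0L
  class(tr) <- c("eval_tracker", "environment")
  tr
}

termination_condition <- function(status) {
  structure(class = c("chanbench_terminate", "condition"),
            list(message = status, call = NULL))
}

#' Record one evaluation
#'
#' Updates counters (out-of-bounds attempts do not increment the
#' model-solve counters), the running best cost (strictly-lower costs
#' only), and the best-cost history used by the stagnation criterion, then
#' checks termination: if a criterion fires, a `chanbench_terminate`
#' condition is signalled, which [run_approach()] catches to unwind the
#' optimiser.
#'
#' @param tracker An [new_tracker()] environment.
#' @param params Attempted parameter vector (model space).
#' @param cost Cost at the attempt, including any penalty.
#' @param in_bounds Was the attempt inside the active bounds?
#' @param solved Was the model actually solved?
#' @param with_sensitivities Was the solve a (more expensive) gradient
#'   solve?
#' @param wall_time_s Wall time of the solve, seconds.
#' @return The tracker, invisibly.
#' @export
record_evaluation <- function(tracker, params, cost, in_bounds = TRUE,
                              solved = TRUE, with_sensitivities = FALSE,
                              wall_time_s = NA_real_) {
  if (!in_bounds) {
    tracker$n_oob <- tracker$n_oob + 1L
  } else if (solved) {
    if (with_sensitivities) tracker$n_grad <- tracker$n_grad + 1L
    else tracker$n_cost <- tracker$n_cost + 1L
  }
  if (is.finite(cost) && cost < tracker$best_cost) {
    tracker$best_cost <- cost
    tracker$best_params <- params
  }
  if (in_bounds && solved) {
    n <- tracker$n_hist + 1L
    if (n > length(tracker$history)) {
      tracker$history <- c(tracker$history,
                           numeric(length(tracker$history)))
    }
    tracker$history[n] <- tracker$best_cost
    tracker$n_hist <- n
  }
  if (tracker$keep_records) {
    k <- tracker$n_rec + 1L
    if (k > length(tracker$records)) {
      tracker$records <- c(tracker$records,
                           vector("list", length(tracker$records)))
    }
    tracker$records[[k]] <- list(params = params, cost = cost,
                                 in_bounds = in_bounds, solved = solved,
                                 with_sensitivities = with_sensitivities,
                                 wall_time_s = wall_time_s,
                                 best_cost = tracker$best_cost)
    tracker$n_rec <- k
  }
  status <- check_termination(tracker, tracker$spec)
  if (status != "running") {
    tracker$status <- status
    stop(termination_condition(status))
  }
  invisible(tracker)
}

#' Check the termination criteria
#'
#' @param tracker An `eval_tracker`.
#' @param spec A [termination_spec()].
#' @return One of `"running"`, `"success"`, `"stagnated"`,
#'   `"max_iterations"`.
#' @export
check_termination <- function(tracker, spec = tracker$spec) {
  if (tracker$best_cost < spec$cost_threshold) return("success")
  n <- tracker$n_hist
  w <- spec$stagnation_window
  if (n >= w) {
    improvement <- tracker$history[n - w + 1L] - tracker$history[n]
    if (improvement < spec$improvement_epsilon) return("stagnated")
  }
  if (tracker$n_cost + tracker$n_grad >= spec$max_evaluations) {
    return("max_iterations")
  }
  if (is.finite(spec$wall_clock_s) &&
      unname(proc.time()["elapsed"]) - tracker$t_start > spec$wall_clock_s) {
    return("max_iterations")
  }
  "running"
}

#' Summarise a tracked run
#'
#' Collapses a tracker into one run-result row. The converted time in
#' function evaluations (FEs) is `cost solves + time_ratio * gradient
#' solves`: gradient solves are charged at the problem's relative expense.
#'
#' @param tracker An `eval_tracker`.
#' @param time_ratio FEs per gradient solve (see [time_ratio()]).
#' @param run_id Optional identifier carried into the row.
#' @return A one-row tibble of class `run_result` with columns `run_id`,
#'   `success`, `status`, `cost_solves`, `grad_solves`, `oob_attempts`,
#'   `best_cost`, `fe_time` and a list-column `best_params`.
#' @export
summarise_run <- function(tracker, time_ratio = 1, run_id = NA_integer_) {
  out <- tibble::tibble(
    run_id = run_id,
    success = tracker$status == "success" ||
      tracker$best_cost < tracker$spec$cost_threshold,
    status = tracker$status,
    cost_solves = tracker$n_cost,
    grad_solves = tracker$n_grad,
    oob_attempts = tracker$n_oob,
    best_cost = tracker$best_cost,
    fe_time = tracker$n_cost + time_ratio * tracker$n_grad,
    best_params = list(tracker$best_params)
  )
  class(out) <- c("run_result", class(out))
  out
}

#' Per-evaluation records as a tibble
#'
#' @param tracker An `eval_tracker` created with `keep_records = TRUE`.
#' @return A tibble with one row per attempted parameter vector.
#' @export
tracker_records <- function(tracker) {
  recs <- tracker$records[seq_len(tracker$n_rec)]
  tibble::tibble(
    evaluation = seq_along(recs),
    cost = vapply(recs, `[[`, 0, "cost"),
    in_bounds = vapply(recs, `[[`, TRUE, "in_bounds"),
    solved = vapply(recs, `[[`, TRUE, "solved"),
    with_sensitivities = vapply(recs, `[[`, TRUE, "with_sensitivities"),
    wall_time_s = vapply(recs, `[[`, 0, "wall_time_s"),
    best_cost = vapply(recs, `[[`, 0, "best_cost"),
    params = lapply(recs, `[[`, "params")
  )
}
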