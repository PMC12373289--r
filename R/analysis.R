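#' Expected Run Time of a set of optimisation runs
#'
#' The Expected Run Time (ERT) is the mean computational effort until the
#' first success under a restart strategy:
#' `ERT = T_s + T_f * (1 - p_hat) / p_hat`, where `T_s` and `T_f` are the
#' mean converted times (in function evaluations) of successful and failed
#' runs and `p_hat` the observed success fraction. With every run
#' successful, `ERT = T_s`; with no successes the point estimate is
#' infinite (the bootstrap quantifies the uncertainty instead).
#'
#' @param results A `run_result` tibble (rows = runs) with columns
#'   `success` and `fe_time`, e.g. stacked [run_approach()] outputs.
#' @return An object of class `ert_estimate`: a list with `n_run`, `x`
#'   (success count), `p_hat`, `t_s`, `t_f`, `ert`.
#' @export
expected_run_time <- function(results) {
  stopifnot(nrow(results) >= 1)
  n <- nrow(results)
  x <- sum(results$success)
  p_hat <- x / n
  t_s <- if (x > 0) mean(results$fe_time[results$success]) else NA_real_
  t_f <- if (x < n) mean(results$fe_time[!results$success]) else NA_real_
  ert <- if (x == 0) {
    Inf
  } else if (x == n) {
    t_s
  } else {
    t_s + t_f * (1 - p_hat) / p_hat
  }
  structure(list(n_run = n, x = x, p_hat = p_hat, t_s = t_s, t_f = t_f,
                 ert = ert),
            class = "ert_estimate")
}

#' @export
print.ert_estimate <- function(x, ...) {
  cat("<ert_estimate> ", x$x, "/", x$n_run, " successes (p_hat = ",
      signif(x$p_hat, 3), ")\n  T_s = ", signif(x$t_s, 4), " FEs, T_f = ",
      signif(x$t_f, 4), " FEs, ERT = ", signif(x$ert, 4), " FEs\n",
      sep = "")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ert_estimate <- function(x, ...) {
  tibble::tibble(term = c("p_hat", "t_s", "t_f", "ert"),
                 estimate = c(x$p_hat, x$t_s, x$t_f, x$ert))
}

#' @exportS3Method generics::glance
glance.ert_estimate <- function(x, ...) {
  tibble::tibble(n_run = x$n_run, successes = x$x, p_hat = x$p_hat,
                 t_s = x$t_s, t_f = x$t_f, ert = x$ert)
}

#' Relative cost of a gradient solve, in function evaluations
#'
#' A gradient solve is charged at the cheaper of the sensitivity solve and
#' its finite-difference emulation by `n_parameters + 1` plain solves:
#' `ratio = min(grad_time, (n_parameters + 1) * cost_time) / cost_time`.
#' Simultaneous-perturbation methods need only two plain solves per
#' gradient estimate, so `is_spsa` overrides the ratio to 2.
#'
#' @param cost_time Mean wall time of a solve without sensitivities, s.
#' @param grad_time Mean wall time of a solve with sensitivities, s.
#' @param n_parameters Number of model parameters.
#' @param is_spsa Simultaneous-perturbation override.
#' @return The time ratio (FEs per gradient solve).
#' @export
time_ratio <- function(cost_time, grad_time, n_parameters,
                       is_spsa = FALSE) {
  stopifnot(cost_time > 0, grad_time > 0)
  if (is_spsa) return(2)
  min(grad_time, (n_parameters + 1) * cost_time) / cost_time
}

#' Measure a problem's time ratio
#'
#' Times a handful of cost and gradient solves at sampled parameter
#' vectors and applies [time_ratio()].
#'
#' @param problem A benchmark problem.
#' @param n_rep Number of solves to average.
#' @param seed Seed for the sampled parameter vectors.
#' @return A tibble with `cost_time`, `grad_time`, `ratio`.
#' @export
measure_time_ratio <- function(problem, n_rep = 3, seed = 1L) {
  ps <- sample_initial_parameters(problem, n_rep, seed)
  tc <- system.time(
    for (i in seq_len(n_rep)) problem_cost(problem, ps[i, ]))["elapsed"]
  tg <- system.time(
    for (i in seq_len(n_rep)) problem_gradient(problem, ps[i, ]))["elapsed"]
  ct <- max(tc / n_rep, 1e-6)
  gt <- max(tg / n_rep, 1e-6)
  tibble::tibble(cost_time = ct, grad_time = gt,
                 ratio = time_ratio(ct, gt, n_parameters(problem)))
}

#' Bootstrap the ERT distribution
#'
#' Each replicate resamples the runs with replacement to obtain the mean
#' success and failure times (when a resample contains only successes, the
#' failure time is a single random draw from all observed times,
#' reflecting the increased uncertainty; symmetrically for the success
#' time), and draws the success rate from the Jeffreys-prior posterior
#' `Beta(x + 0.5, n_run - x + 0.5)` given the observed success count `x`
#' -- never exactly zero, so every bootstrapped ERT is finite and
#' positive even for approaches that always failed.
#'
#' @param results A `run_result` tibble.
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return Numeric vector of `n_boot` bootstrapped ERT values.
#' @export
bootstrap_ert <- function(results, n_boot = 1e4, seed = 1L) {
  n <- nrow(results)
  stopifnot(n >= 1)
  succ <- results$success
  times <- results$fe_time
  x_obs <- sum(succ)
  with_seed(seed, {
    p <- stats::rbeta(n_boot, x_obs + 0.5, n - x_obs + 0.5)
    t_s <- numeric(n_boot)
    t_f <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      idx <- sample.int(n, n, replace = TRUE)
      s <- succ[idx]
      t_s[b] <- if (any(s)) mean(times[idx][s]) else sample(times, 1)
      t_f[b] <- if (any(!s)) mean(times[idx][!s]) else sample(times, 1)
    }
    t_s + t_f * (1 - p) / p
  })
}

#' All-pairs comparison of two bootstrapped samples
#'
#' The fraction of pairs `(a, b)` with `a < b` (ties counted half),
#' computed exactly by sorting and rank counting rather than materialising
#' the full pair grid; identical to the nested-loop count. An approach is
#' significantly better when it wins at least 95% of comparisons.
#'
#' @param samples_a,samples_b Numeric vectors (e.g. [bootstrap_ert()]
#'   draws); lengths may differ.
#' @param level Significance level on the winning fraction.
#' @return A list: `fraction_a_better`, `a_significant`, `b_significant`.
#' @export
compare_approaches <- function(samples_a, samples_b, level = 0.95) {
  stopifnot(length(samples_a) >= 1, length(samples_b) >= 1)
  sb <- sort(samples_b)
  nb <- length(sb)
  # for each a: number of b strictly greater, plus half the ties
  n_ge <- nb - findInterval(samples_a, sb)            # b > a
  n_gt_or_eq <- nb - findInterval(samples_a, sb, left.open = TRUE)
  ties <- n_gt_or_eq - n_ge
  wins <- sum(n_ge) + 0.5 * sum(ties)
  frac <- wins / (length(samples_a) * nb)
  list(fraction_a_better = frac,
       a_significant = frac >= level,
       b_significant = frac <= 1 - level)
}

#' Head-to-head comparison of two approaches
#'
#' Runs both approaches on the *same* freshly sampled starting vectors in
#' batches, bootstrapping the ERT of each accumulated result set after
#' every batch, until one approach is significantly better or the batch
#' budget is exhausted.
#'
#' @param spec_a,spec_b [approach_spec()]s (or approach names); either may
#'   also be a function `(problem, start, seed) -> run_result` for custom
#'   approaches.
#' @param problem A benchmark problem.
#' @param batch_size Starts per batch.
#' @param seed Integer seed.
#' @param max_batches Batch budget.
#' @param n_boot Bootstrap replicates per test.
#' @return A list: `winner` (`"A"`, `"B"` or `"undecided"`),
#'   `fraction_a_better`, `n_runs`, and both `run_result` tibbles.
#' @export
head_to_head <- function(spec_a, spec_b, problem, batch_size = 10,
                         seed = 1L, max_batches = 10, n_boot = 2000) {
  runner <- function(spec) {
    if (is.function(spec)) return(spec)
    function(problem, start, seed) run_approach(spec, problem, start, seed)
  }
  run_a <- runner(spec_a)
  run_b <- runner(spec_b)
  res_a <- NULL
  res_b <- NULL
  seeds <- with_seed(seed, sample.int(2^31 - 2, max_batches))
  frac <- 0.5
  for (batch in seq_len(max_batches)) {
    starts <- sample_initial_parameters(problem, batch_size, seeds[batch])
    for (i in seq_len(batch_size)) {
      res_a <- dplyr::bind_rows(res_a,
                                run_a(problem, starts[i, ], seeds[batch] + i))
      res_b <- dplyr::bind_rows(res_b,
                                run_b(problem, starts[i, ], seeds[batch] + i))
    }
    bs_a <- bootstrap_ert(res_a, n_boot, seed = seeds[batch] + 7L)
    bs_b <- bootstrap_ert(res_b, n_boot, seed = seeds[batch] + 11L)
    cmp <- compare_approaches(bs_a, bs_b)
    frac <- cmp$fraction_a_better
    if (cmp$a_significant) {
      return(list(winner = "A", fraction_a_better = frac,
                  n_runs = nrow(res_a), results_a = res_a,
                  results_b = res_b))
    }
    if (cmp$b_significant) {
      return(list(winner = "B", fraction_a_better = frac,
                  n_runs = nrow(res_a), results_a = res_a,
                  results_b = res_b))
    }
  }
  list(winner = "undecided", fraction_a_better = frac,
       n_runs = nrow(res_a), results_a = res_a, results_b = res_b)
}

#' @exportS3Method ggplot2::autoplot
autoplot.ert_estimate <- function(object, samples = NULL, ...) {
  if (is.null(samples)) {
    stop("supply bootstrap samples via `samples = bootstrap_ert(...)`",
         call. = FALSE)
  }
  df <- tibble::tibble(ert = samples)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$ert)) +
    ggplot2::geom_histogram(bins = 50) +
    ggplot2::scale_x_log10() +
    ggplot2::geom_vline(xintercept = object$ert, linetype = 2) +
    ggplot2::labs(x = "Expected run time (FEs)", y = "Bootstrap draws")
}
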