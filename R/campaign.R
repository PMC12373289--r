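#' Run a benchmark campaign
#'
#' Samples `n_run` starting parameter vectors from the problem's sampling
#' region and runs every requested approach from each of them -- the same
#' starts for every approach, so comparisons are paired. Per-run records
#' are written as JSON (one file per run) and a summary table as CSV when
#' an output directory is given. Identical configuration and seed give
#' byte-identical outputs.
#'
#' @param problem A benchmark problem or problem name.
#' @param approaches Character vector of approach names from
#'   [approach_registry()], and/or the special name `"new_approach"` (the
#'   multistart trust-region approach, run once per campaign with the
#'   start budget `n_run`).
#' @param n_run Number of starts (default: the problem's standard count).
#' @param seed Integer campaign seed.
#' @param out_dir Optional output directory.
#' @param time_ratio FEs per gradient solve (default `n_parameters + 1`).
#' @return A tibble of run summaries (one row per approach x start).
#' @export
run_campaign <- function(problem, approaches, n_run = NULL, seed = 1L,
                         out_dir = NULL,
                         time_ratio = NULL) {
  if (is.character(problem)) problem <- build_problem(problem)
  n_run <- n_run %||% problem$n_run_default
  time_ratio <- time_ratio %||% (n_parameters(problem) + 1)
  starts <- sample_initial_parameters(problem, n_run, seed)
  run_seeds <- with_seed(seed, sample.int(2^31 - 2, n_run))
  out <- purrr::map_dfr(approaches, function(ap) {
    if (identical(ap, "new_approach")) {
      res <- run_new_approach(problem, max_restarts = n_run - 1,
                              seed = seed, time_ratio = time_ratio)
      res$approach <- ap
      res$run_id <- 1L
      return(res)
    }
    spec <- approach_spec(ap)
    purrr::map_dfr(seq_len(n_run), function(i) {
      res <- run_approach(spec, problem, starts[i, ], seed = run_seeds[i],
                          time_ratio = time_ratio)
      res$approach <- ap
      res$run_id <- i
      res
    })
  })
  out <- dplyr::relocate(out, "approach", "run_id")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_len(nrow(out))) {
      row <- out[k, ]
      rec <- list(problem = problem$name, approach = row$approach,
                  run_id = row$run_id, seed = seed,
                  success = row$success, status = row$status,
                  cost_solves = row$cost_solves,
                  grad_solves = row$grad_solves,
                  oob_attempts = row$oob_attempts,
                  best_cost = row$best_cost, fe_time = row$fe_time,
                  best_params = row$best_params[[1]])
      jsonlite::write_json(
        rec, file.path(out_dir, sprintf("run_%s_%03d.json",
                                        gsub("\\W", "_", row$approach),
                                        row$run_id)),
        auto_unbox = TRUE, digits = NA)
    }
    readr::write_csv(dplyr::select(out, -"best_params"),
                     file.path(out_dir, "summary.csv"))
  }
  out
}

#' Analyse campaign summaries
#'
#' Computes the ERT of every approach in a campaign summary and, when
#' several approaches are present, bootstraps each against the approach
#' with the lowest ERT estimate to flag which differences are
#' significant.
#'
#' @param summary A summary tibble from [run_campaign()], or path(s) to
#'   `summary.csv` files it wrote.
#' @param n_boot Bootstrap replicates per approach.
#' @param seed Integer seed for the bootstrap.
#' @return A tibble with one row per approach: success counts, `t_s`,
#'   `t_f`, `ert`, the bootstrap comparison fraction against the best
#'   approach (`p_hat_vs_best`, `NA` for the best row itself) and
#'   `best_significantly_better`.
#' @export
analyse_runs <- function(summary, n_boot = 1e4, seed = 1L) {
  if (is.character(summary)) {
    summary <- purrr::map_dfr(summary, readr::read_csv,
                              show_col_types = FALSE)
  }
  stopifnot(all(c("approach", "success", "fe_time") %in% names(summary)))
  ests <- summary |>
    dplyr::group_by(.data$approach) |>
    dplyr::group_modify(function(df, key) glance(expected_run_time(df))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$ert)
  if (nrow(ests) == 1) {
    ests$p_hat_vs_best <- NA_real_
    ests$best_significantly_better <- NA
    return(ests)
  }
  best_name <- ests$approach[1]
  boots <- lapply(ests$approach, function(ap) {
    bootstrap_ert(dplyr::filter(summary, .data$approach == ap),
                  n_boot = n_boot, seed = seed)
  })
  names(boots) <- ests$approach
  frac <- vapply(ests$approach, function(ap) {
    if (ap == best_name) return(NA_real_)
    # fraction of pairs where the challenger beats the best approach
    compare_approaches(boots[[ap]], boots[[best_name]])$fraction_a_better
  }, 0)
  ests$p_hat_vs_best <- frac
  ests$best_significantly_better <- ifelse(is.na(frac), NA, frac <= 0.05)
  ests
}

#' Write the fixture problem to disk
#'
#' Materialises the fast 3-parameter fixture problem as plain-text files:
#' protocol CSV, data trace CSV, and a JSON description (true parameters,
#' bounds, threshold). Intended for inspecting the fixture or driving
#' external tools; the in-memory problem from `build_problem("fixture_hh")`
#' is what tests use.
#'
#' @param dir Output directory.
#' @param seed Data seed (the fixture is noise free, so this only records
#'   provenance).
#' @return The directory, invisibly.
#' @export
make_fixture <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pr <- build_problem("fixture_hh")
  write_protocol_csv(pr$protocol, file.path(dir, "protocol.csv"))
  readr::write_csv(
    tibble::tibble(time_ms = protocol_sampling_times(pr$protocol),
                   current = pr$data),
    file.path(dir, "trace.csv"))
  jsonlite::write_json(
    list(name = pr$name, p_star = pr$p_star, lower = pr$lower,
         upper = pr$upper, log_idx = pr$log_idx,
         cost_threshold = pr$cost_threshold, seed = seed),
    file.path(dir, "problem.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Plot a simulated current trace over a protocol
#'
#' @param problem A benchmark problem (trace cost kind).
#' @param params Parameters to simulate (default: the true parameters).
#' @return A ggplot object: data (points) and simulation (line).
#' @export
plot_trace <- function(problem, params = problem$p_star) {
  stopifnot(problem$cost_kind == "trace_rmse")
  sim <- solve_model(problem$model, problem$protocol, params)
  if (is_sim_failure(sim)) stop("simulation failed", call. = FALSE)
  df <- tibble::tibble(time = sim$time, simulated = sim$current,
                       data = problem$data)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$data), size = 0.2,
                        alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$simulated),
                       colour = "firebrick") +
    ggplot2::labs(x = "Time (ms)", y = "Current (nA)")
}
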