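#' Registry of published optimisation approaches
#'
#' The registry reconstructs, row for row, the published pairings of an
#' optimiser with a modification that have been applied to ion channel
#' model fitting: 42 approaches drawn from 30 publications. Each approach
#' is named by the first author's surname and year, with an a-z suffix
#' where one publication described several. Flags give whether the
#' optimiser uses gradient information and which modification settings
#' (log transform, scale-factor transform, parameter bounds, rate bounds)
#' the original description implies. `implemented` marks approaches whose
#' optimiser has a runnable implementation here; the rest are registry
#' entries that error informatively if run. `duplicate_of` is `NA`
#' throughout: several rows coincide in optimiser and flags, but published
#' duplicate status also depends on hyperparameter detail that the flags
#' do not carry, so no pairing is asserted.
#'
#' @return A tibble with one row per approach: `name`, `citation`,
#'   `optimiser`, `category`, `uses_gradient`, `log_transform`,
#'   `scale_transform`, `parameter_bounds`, `rate_bounds`, `implemented`,
#'   `duplicate_of`.
#' @examples
#' reg <- approach_registry()
#' nrow(reg)                         # 42
#' dplyr::n_distinct(reg$citation)   # 30
#' @export
approach_registry <- function() {
  r <- function(name, citation, optimiser, category, grad = FALSE,
                lg = FALSE, sc = FALSE, pb = FALSE, rb = FALSE) {
    tibble::tibble(name = name, citation = citation, optimiser = optimiser,
                   category = category, uses_gradient = grad,
                   log_transform = lg, scale_transform = sc,
                   parameter_bounds = pb, rate_bounds = rb)
  }
  reg <- dplyr::bind_rows(
    r("Balser1990a", "Balser1990", "lm", "gradient_descent", grad = TRUE),
    r("Balser1990b", "Balser1990", "nelder_mead", "simplex"),
    r("Maryak1998", "Maryak1998", "spsa", "gradient_descent", grad = TRUE),
    r("Clancy1999", "Clancy1999", "lm", "gradient_descent", grad = TRUE),
    r("Vanier1999a", "Vanier1999", "conjugate_gd", "gradient_descent",
      grad = TRUE, sc = TRUE, pb = TRUE),
    r("Vanier1999b", "Vanier1999", "simulated_annealing", "other",
      sc = TRUE, pb = TRUE),
    r("Vanier1999c", "Vanier1999", "stochastic_search", "other",
      sc = TRUE, pb = TRUE),
    r("Vanier1999d", "Vanier1999", "random_search", "other",
      sc = TRUE, pb = TRUE),
    r("Sachse2003a", "Sachse2003", "conjugate_gd", "gradient_descent",
      grad = TRUE),
    r("Sachse2003b", "Sachse2003", "powell", "gradient_descent",
      grad = TRUE),
    r("Dokos2004", "Dokos2004", "curvilinear_gd", "gradient_descent",
      grad = TRUE, pb = TRUE),
    r("Gurkiewicz2007a", "Gurkiewicz2007", "ga", "genetic_algorithm",
      pb = TRUE),
    r("Gurkiewicz2007b", "Gurkiewicz2007", "ga", "genetic_algorithm",
      pb = TRUE),
    r("Bueno-Orovio2008", "BuenoOrovio2008", "sqp", "gradient_descent",
      grad = TRUE, pb = TRUE),
    r("Seemann2009a", "Seemann2009", "pso", "pso"),
    r("Seemann2009b", "Seemann2009", "powell", "gradient_descent",
      grad = TRUE),
    r("Zhou2009", "Zhou2009", "de/lm", "hybrid", grad = TRUE),
    r("Guo2010", "Guo2010", "curvilinear_gd", "gradient_descent",
      grad = TRUE, pb = TRUE),
    r("Liu2011", "Liu2011", "pso/nelder_mead", "hybrid", pb = TRUE),
    r("Ben-Shalom2012", "BenShalom2012", "ga", "genetic_algorithm",
      pb = TRUE),
    r("Bot2012", "Bot2012", "ga", "genetic_algorithm", sc = TRUE,
      pb = TRUE),
    r("Chen2012", "Chen2012", "pso", "pso", pb = TRUE),
    r("Davies2012", "Davies2012", "nelder_mead", "simplex", sc = TRUE,
      pb = TRUE),
    r("Wilhelms2012a", "Wilhelms2012", "powell", "gradient_descent",
      grad = TRUE),
    r("Wilhelms2012b", "Wilhelms2012", "trr", "gradient_descent",
      grad = TRUE, pb = TRUE),
    r("Abed2013", "Abed2013", "curvilinear_gd", "gradient_descent",
      grad = TRUE, pb = TRUE),
    r("Du2014", "Du2014", "trr", "gradient_descent", grad = TRUE,
      pb = TRUE),
    r("Groenendaal2015", "Groenendaal2015", "ga", "genetic_algorithm",
      sc = TRUE, pb = TRUE),
    r("Loewe2016a", "Loewe2016", "trr", "gradient_descent", grad = TRUE,
      pb = TRUE),
    r("Loewe2016b", "Loewe2016", "pso", "pso", pb = TRUE),
    r("Loewe2016c", "Loewe2016", "pso+trr", "hybrid", grad = TRUE,
      pb = TRUE),
    r("Loewe2016d", "Loewe2016", "pso/trr", "hybrid", grad = TRUE,
      pb = TRUE),
    r("Loewe2016e", "Loewe2016", "pso/trr+trr", "hybrid", grad = TRUE,
      pb = TRUE),
    r("Moreno2016", "Moreno2016", "nelder_mead", "simplex", pb = TRUE),
    r("Cairns2017", "Cairns2017", "ga", "genetic_algorithm", pb = TRUE),
    r("Jedrzejewski-Szmek2018", "JedrzejewskiSzmek2018", "cmaes", "other",
      pb = TRUE),
    r("Beattie2018", "Beattie2018", "cmaes", "other", lg = TRUE,
      pb = TRUE, rb = TRUE),
    r("Clerx2019", "Clerx2019", "cmaes", "other", lg = TRUE, pb = TRUE,
      rb = TRUE),
    r("Clausen2020", "Clausen2020", "pso+nelder_mead", "hybrid",
      pb = TRUE),
    r("Smirnov2020", "Smirnov2020", "ga", "genetic_algorithm", sc = TRUE,
      pb = TRUE),
    r("Cabo2022", "Cabo2022", "pso", "pso", pb = TRUE),
    r("Kohjitani2022", "Kohjitani2022", "pattern_search", "other",
      sc = TRUE)
  )
  reg$implemented <- vapply(reg$optimiser, optimiser_id_implemented, TRUE)
  reg$duplicate_of <- NA_character_
  reg
}

#' Look up one approach
#'
#' @param name Approach name as in [approach_registry()].
#' @param hyperparameters Optional optimiser hyperparameter overrides.
#' @return A list of class `approach_spec`: registry row fields plus a
#'   [modification()].
#' @export
approach_spec <- function(name, hyperparameters = list()) {
  reg <- approach_registry()
  row <- reg[reg$name == name, ]
  if (nrow(row) != 1) stop("unknown approach: ", name, call. = FALSE)
  structure(list(
    name = row$name, optimiser = row$optimiser, category = row$category,
    uses_gradient = row$uses_gradient, implemented = row$implemented,
    modification = modification(
      log_transform = row$log_transform,
      scale_transform = row$scale_transform,
      parameter_bounds = row$parameter_bounds,
      rate_bounds = row$rate_bounds,
      hyperparameters = hyperparameters)
  ), class = "approach_spec")
}

# genetic algorithms get the lower evaluation cap
max_evals_for <- function(category) {
  if (identical(category, "genetic_algorithm")) 1e4 else 2.5e4
}

#' Run one approach from one start
#'
#' Builds the tracked black box for the approach's modification, runs its
#' optimiser from the given model-space start, and summarises the run.
#' Harness termination (success threshold, stagnation over 2500 model
#' solves, evaluation cap) is enforced at every evaluation; an
#' optimiser-internal stop is recorded with the optimiser's own status.
#' Fully deterministic for a given seed.
#'
#' @param spec An [approach_spec()] (or approach name).
#' @param problem A benchmark problem.
#' @param start Model-space starting parameter vector (from
#'   [sample_initial_parameters()]).
#' @param seed Integer seed for any optimiser randomness.
#' @param time_ratio FEs charged per gradient solve (default: the
#'   finite-difference equivalent `n_parameters + 1`; see [time_ratio()]).
#' @param keep_records Keep per-evaluation records on the result.
#' @return A one-row `run_result` tibble (see [summarise_run()]), with the
#'   tracker attached as attribute `tracker`.
#' @export
run_approach <- function(spec, problem, start, seed = 1L,
                         time_ratio = n_parameters(problem) + 1,
                         keep_records = FALSE) {
  if (is.character(spec)) spec <- approach_spec(spec)
  if (!optimiser_id_implemented(spec$optimiser)) {
    stop("optimiser '", spec$optimiser, "' for approach ", spec$name,
         " is not implemented", call. = FALSE)
  }
  if (length(start) != n_parameters(problem)) {
    stop("start vector length does not match the problem dimension",
         call. = FALSE)
  }
  mod <- spec$modification
  tracker <- new_tracker(
    termination_spec(problem$cost_threshold,
                     max_evaluations = max_evals_for(spec$category)),
    keep_records = keep_records)
  mp <- modified_problem(problem, mod, tracker)
  x0 <- to_search_space(start, mod, problem)
  with_seed(seed, {
    tryCatch(
      run_optimiser_id(spec$optimiser, mp, x0,
                       mod$hyperparameters),
      chanbench_terminate = function(c) NULL)
  })
  if (tracker$status == "running") tracker$status <- "optimiser_converged"
  out <- summarise_run(tracker, time_ratio = time_ratio)
  attr(out, "tracker") <- tracker
  out
}

#' Multistart trust-region approach
#'
#' The recommended approach: bounded trust-region reflective least squares
#' run in log-transformed search space with parameter *and* transition-rate
#' bounds, restarted from fresh draws of the problem's sampling region
#' until the success threshold is reached or the restart budget is spent.
#' Evaluation counts accumulate over restarts, so the reported converted
#' time is the total cost of the multistart procedure.
#'
#' @param problem A benchmark problem.
#' @param max_restarts Restart budget (0 = a single local run).
#' @param seed Integer seed; drives both the start draws and the runs.
#' @param time_ratio FEs charged per gradient solve.
#' @return A one-row `run_result` tibble with extra column `restarts`.
#' @export
run_new_approach <- function(problem, max_restarts = 100, seed = 1L,
                             time_ratio = n_parameters(problem) + 1) {
  mod <- modification(log_transform = TRUE, parameter_bounds = TRUE,
                      rate_bounds = TRUE)
  tracker <- new_tracker(termination_spec(problem$cost_threshold),
                         keep_records = FALSE)
  mp <- modified_problem(problem, mod, tracker)
  sub_seeds <- with_seed(seed, sample.int(2^31 - 2, max_restarts + 1))
  restarts_used <- 0L
  done <- FALSE
  for (k in seq_len(max_restarts + 1)) {
    start <- sample_initial_parameters(problem, 1, sub_seeds[k])[1, ]
    x0 <- to_search_space(start, mod, problem)
    res <- with_seed(sub_seeds[k], {
      tryCatch({ opt_trr(mp, x0); NULL },
               chanbench_terminate = function(c) c)
    })
    restarts_used <- k - 1L
    if (!is.null(res)) {
      # harness termination: stop multistart only on success or budget
      if (tracker$status == "success" ||
          conditionMessage(res) == "success") { done <- TRUE; break }
      if (conditionMessage(res) == "max_iterations") { done <- TRUE; break }
      # stagnation of a local run: reset its window and restart
      tracker$status <- "running"
      tracker$n_hist <- 0L
    }
  }
  if (tracker$status == "running") {
    tracker$status <- if (tracker$best_cost < problem$cost_threshold) {
      "success"
    } else "budget_exhausted"
  }
  out <- summarise_run(tracker, time_ratio = time_ratio)
  out$restarts <- restarts_used
  attr(out, "tracker") <- tracker
  out
}
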