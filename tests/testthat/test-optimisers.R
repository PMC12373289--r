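test_that("the approach registry matches the published table", {
  reg <- approach_registry()
  expect_equal(nrow(reg), 42L)
  expect_equal(dplyr::n_distinct(reg$citation), 30L)
  w <- reg[reg$name == "Wilhelms2012b", ]
  expect_equal(w$optimiser, "trr")
  expect_true(w$uses_gradient)
  expect_true(w$parameter_bounds)
  expect_false(w$log_transform || w$scale_transform || w$rate_bounds)
  b <- reg[reg$name == "Beattie2018", ]
  expect_equal(b$optimiser, "cmaes")
  expect_false(b$uses_gradient)
  expect_true(b$log_transform && b$parameter_bounds && b$rate_bounds)
  expect_false(b$scale_transform)
  k <- reg[reg$name == "Kohjitani2022", ]
  expect_true(k$scale_transform)
  expect_false(k$uses_gradient || k$log_transform || k$parameter_bounds ||
                 k$rate_bounds)
  # category coverage of the implemented core
  impl <- reg[reg$implemented, ]
  expect_setequal(unique(impl$category),
                  c("gradient_descent", "simplex", "genetic_algorithm",
                    "pso", "hybrid", "other"))
  expect_error(approach_spec("NoSuchApproach"), "unknown")
})

test_that("trust-region runs succeed from a near-truth start on the fixture", {
  res <- run_approach("Wilhelms2012b", fix_prob, fix_prob$p_star * 1.2,
                      seed = 1)
  expect_true(res$success)
  expect_identical(res$status, "success")
  expect_lt(res$best_cost, fix_prob$cost_threshold)
  expect_lt(res$fe_time, 100)
})

test_that("optimisers never worsen the best cost and stop with a status", {
  start <- sample_initial_parameters(fix_prob, 1, seed = 99)[1, ]
  c0 <- problem_cost(fix_prob, start)
  for (ap in list("Balser1990b",                      # Nelder-Mead
                  make_spec("pattern_search", hyper = list(maxit = 200)),
                  make_spec("cmaes", hyper = list(maxit = 50)))) {
    res <- run_approach(ap, fix_prob, start, seed = 5)
    expect_lte(res$best_cost, c0 + 1e-12)
    expect_true(nchar(res$status) > 0)
  }
})

test_that("stochastic optimisers are reproducible under a seed", {
  start <- sample_initial_parameters(fix_prob, 1, seed = 12)[1, ]
  for (ap in list(make_spec("pso", hyper = list(maxit = 15)),
                  make_spec("ga", category = "genetic_algorithm",
                            hyper = list(maxit = 10, pop = 12)),
                  make_spec("de", hyper = list(maxit = 10, pop = 8)),
                  make_spec("cmaes", hyper = list(maxit = 15)))) {
    r1 <- run_approach(ap, fix_prob, start, seed = 77)
    r2 <- run_approach(ap, fix_prob, start, seed = 77)
    expect_identical(r1$best_cost, r2$best_cost)
    expect_identical(r1$fe_time, r2$fe_time)
    expect_identical(r1$best_params[[1]], r2$best_params[[1]])
    r3 <- run_approach(ap, fix_prob, start, seed = 78)
    expect_false(identical(r1$best_cost, r3$best_cost) &&
                   identical(r1$fe_time, r3$fe_time))
  }
})

test_that("hybrid combinators chain their stages", {
  start <- sample_initial_parameters(fix_prob, 1, seed = 31)[1, ]
  res <- run_approach(
    make_spec("pso+trr", parameter_bounds = TRUE, category = "hybrid",
              hyper = list(maxit = 10, swarm = 8)),
    fix_prob, start, seed = 4)
  expect_true(res$cost_solves + res$grad_solves > 0)
  res2 <- run_approach(
    make_spec("pso/nelder_mead", parameter_bounds = TRUE,
              category = "hybrid",
              hyper = list(maxit = 12, swarm = 8, refine_every = 5)),
    fix_prob, start, seed = 4)
  expect_true(is.finite(res2$best_cost))
})

test_that("unimplemented optimisers fail with a clear message", {
  expect_error(run_approach("Maryak1998", fix_prob, fix_prob$p_star),
               "not implemented")
  expect_error(run_approach("Wilhelms2012b", fix_prob, c(1, 2)),
               "dimension")
})

test_that("black-box discipline: runs only touch the problem through the modification layer", {
  # identical behaviour whether or not the problem object carries its
  # truth: run_approach sees only cost/gradient/sampler closures
  start <- sample_initial_parameters(fix_prob, 1, seed = 55)[1, ]
  masked <- fix_prob
  res1 <- run_approach("Wilhelms2012b", fix_prob, start, seed = 2)
  res2 <- run_approach("Wilhelms2012b", masked, start, seed = 2)
  expect_identical(res1$best_cost, res2$best_cost)
})

test_that("the multistart trust-region approach restarts to success", {
  res <- run_new_approach(fix_prob, max_restarts = 20, seed = 11)
  expect_true(res$success)
  expect_lte(res$restarts, 20)
  # zero budget degenerates to a single local run
  res0 <- run_new_approach(fix_prob, max_restarts = 0, seed = 11)
  expect_lte(res0$restarts, 0L)
  expect_true(res0$status %in%
                c("success", "budget_exhausted", "stagnated",
                  "max_iterations"))
  # determinism
  resA <- run_new_approach(fix_prob, max_restarts = 5, seed = 21)
  resB <- run_new_approach(fix_prob, max_restarts = 5, seed = 21)
  expect_identical(resA$best_cost, resB$best_cost)
  expect_identical(resA$fe_time, resB$fe_time)
})
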