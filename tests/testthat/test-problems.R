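test_that("problems expose their documented dimensionality", {
  expect_equal(n_parameters(build_problem("staircase_hh")), 9)
  expect_equal(n_parameters(build_problem("staircase_mm")), 15)
  expect_equal(n_parameters(build_problem("loewe_ikr")), 12)
  expect_equal(n_parameters(build_problem("loewe_ikur")), 25)
  expect_equal(n_parameters(build_problem("moreno_ina")), 16)
  expect_equal(n_parameters(fix_prob), 3)
  expect_error(build_problem("nonsense"))
})

test_that("noise-free problems have zero cost at the truth, noisy ones sit at the noise floor", {
  for (nm in c("loewe_ikr", "loewe_ikur", "moreno_ina")) {
    pr <- build_problem(nm)
    expect_lt(problem_cost(pr, pr$p_star), 1e-9)
  }
  for (nm in c("staircase_hh", "staircase_mm")) {
    pr <- build_problem(nm)
    c0 <- problem_cost(pr, pr$p_star)
    # RMSE at truth is the realised noise RMS, close to sigma
    expect_equal(c0, pr$sigma, tolerance = 0.05)
    expect_lt(c0, pr$cost_threshold)
  }
})

test_that("noisy data are deterministic in the seed and have centred noise", {
  pr <- build_problem("staircase_hh")
  d1 <- generate_data(pr, seed = pr$data_seed)
  d2 <- generate_data(pr, seed = pr$data_seed)
  expect_identical(d1, d2)
  d3 <- generate_data(pr, seed = pr$data_seed + 1)
  expect_false(identical(d1, d3))
  clean <- solve_model(pr$model, pr$protocol, pr$p_star)$current
  noise <- d1 - clean
  n <- length(noise)
  expect_lt(abs(mean(noise)), 3 * pr$sigma / sqrt(n))
  expect_equal(stats::sd(noise), pr$sigma, tolerance = 0.1)
})

test_that("out-of-bounds proposals are penalised without a model solve", {
  pr <- build_problem("staircase_hh")  # bounds always enforced
  tracker <- new_tracker(termination_spec(pr$cost_threshold))
  bad <- pr$p_star
  bad[1] <- pr$upper[1] * 2
  cst <- problem_cost(pr, bad, modification(), tracker)
  expect_gte(cst, 1e5)
  expect_equal(tracker$n_cost, 0L)
  expect_equal(tracker$n_oob, 1L)
  # inside bounds the solve is counted (and, at the truth, the success
  # termination condition fires immediately)
  caught <- tryCatch({
    problem_cost(pr, pr$p_star, modification(), tracker)
    NULL
  }, chanbench_terminate = function(c) c)
  expect_s3_class(caught, "chanbench_terminate")
  expect_equal(tracker$n_cost, 1L)
  expect_error(problem_cost(pr, c(NA, pr$p_star[-1])), "non-finite")
})

test_that("cost is non-negative and invariant to the approach's transforms", {
  set.seed(42)
  for (k in 1:5) {
    p <- sample_initial_parameters(fix_prob, 1, seed = k)[1, ]
    c_plain <- problem_cost(fix_prob, p)
    expect_gte(c_plain, 0)
    for (mod in list(modification(log_transform = TRUE),
                     modification(scale_transform = TRUE),
                     modification(log_transform = TRUE,
                                  scale_transform = TRUE))) {
      x <- to_search_space(p, mod, fix_prob)
      expect_equal(problem_cost(fix_prob,
                                from_search_space(x, mod, fix_prob)),
                   c_plain, tolerance = 1e-12)
    }
  }
})

test_that("simulation failure maps to a large finite cost", {
  # inside-bounds but dynamically absurd parameters on an unbounded problem
  pr <- build_problem("loewe_ikr")
  bad <- pr$p_star
  bad[12] <- -1  # negative time-constant scale -> unsolvable dynamics
  cst <- problem_cost(pr, bad)
  expect_true(is.finite(cst))
  expect_gte(cst, 1e5)
})

test_that("the cost gradient matches finite differences on the fixture", {
  p <- fix_prob$p_star * c(1.3, 0.9, 1.2)
  g <- problem_gradient(fix_prob, p)
  fd <- numeric(3)
  for (i in 1:3) {
    h <- 1e-6 * abs(p[i])
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    fd[i] <- (problem_cost(fix_prob, pp) - problem_cost(fix_prob, pm)) /
      (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-3)
  # at the exact noise-free minimum the gradient vanishes
  expect_lt(sqrt(sum(problem_gradient(fix_prob, fix_prob$p_star)^2)), 1e-6)
})

test_that("initial-parameter sampling respects its region and its seed", {
  mor <- build_problem("moreno_ina")
  s <- sample_initial_parameters(mor, 200, seed = 7)
  rel <- sweep(s, 2, mor$p_star, "/")
  expect_true(all(rel > 0.75 & rel < 1.25))

  sc <- build_problem("staircase_hh")
  s2 <- sample_initial_parameters(sc, 200, seed = 7)
  for (k in seq_len(nrow(s2))) {
    expect_true(all(s2[k, ] > sc$lower & s2[k, ] < sc$upper))
    expect_identical(penalty(s2[k, ], rates = sc$rates), 0)
  }
  expect_identical(sample_initial_parameters(sc, 20, seed = 3),
                   sample_initial_parameters(sc, 20, seed = 3))
  expect_false(identical(sample_initial_parameters(sc, 20, seed = 3),
                         sample_initial_parameters(sc, 20, seed = 4)))
})

test_that("summary statistics are self-consistent and behave like channel physiology", {
  mor <- build_problem("moreno_ina")
  ss <- compute_summary_statistics(mor$model, mor$p_star)
  expect_equal(ss$value, mor$data$value, tolerance = 1e-12)
  act <- ss$value[ss$curve == "activation"]
  # activation rises with voltage (allow tiny numerical wiggle)
  expect_true(all(diff(act) > -1e-8))
  inact <- ss$value[ss$curve == "inactivation"]
  expect_true(all(inact >= 0 & inact <= 1 + 1e-12))
  rec <- ss$value[ss$curve == "recovery"]
  expect_true(all(rec >= 0 & rec <= 1 + 1e-9))
  # recovery approaches completeness as the interval grows
  expect_true(all(diff(rec) > -1e-8))
  expect_gt(rec[length(rec)], 0.95)
  expect_true(all(ss$value[ss$curve == "decay_t50"] > 0))
})
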