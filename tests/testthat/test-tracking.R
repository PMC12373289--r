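test_that("the tracker keeps counters and a monotone best cost", {
  tr <- new_tracker(termination_spec(1e-8))
  record_quiet(tr, c(1, 2), cost = 5)
  record_quiet(tr, c(1, 2), cost = 7)          # worse: best unchanged
  expect_equal(tr$best_cost, 5)
  expect_equal(tr$n_cost, 2L)
  record_quiet(tr, c(1, 2), cost = 9, in_bounds = FALSE, solved = FALSE)
  expect_equal(tr$n_cost, 2L)                  # no model solve
  expect_equal(tr$n_oob, 1L)
  record_quiet(tr, c(1, 2), cost = 4, with_sensitivities = TRUE)
  expect_equal(tr$n_grad, 1L)
  expect_equal(tr$n_cost, 2L)
  expect_equal(tr$best_cost, 4)
  rec <- tracker_records(tr)
  expect_true(all(diff(rec$best_cost) <= 0))
})

test_that("success fires exactly when the best cost crosses the threshold", {
  tr <- new_tracker(termination_spec(0.1))
  record_quiet(tr, 1, cost = 0.5)
  expect_equal(check_termination(tr), "running")
  expect_identical(tr$status, "running")
  # the first record below threshold raises the termination condition
  caught <- tryCatch({
    record_evaluation(tr, 1, cost = 0.05)
    NULL
  }, chanbench_terminate = function(c) c)
  expect_s3_class(caught, "chanbench_terminate")
  expect_identical(conditionMessage(caught), "success")
  expect_identical(tr$status, "success")
  expect_equal(tr$n_cost, 2L)
})

test_that("stagnation needs a full window of model solves", {
  spec <- termination_spec(1e-12, stagnation_window = 50,
                           improvement_epsilon = 1e-7)
  tr <- new_tracker(spec, keep_records = FALSE)
  for (k in 1:49) record_quiet(tr, 1, cost = 1 - k * 1e-9)
  expect_equal(check_termination(tr), "running")
  record_quiet(tr, 1, cost = 1 - 50e-9)
  expect_identical(tr$status, "stagnated")
  # steady improvement above epsilon keeps the run alive
  tr2 <- new_tracker(spec, keep_records = FALSE)
  for (k in 1:120) record_quiet(tr2, 1, cost = 10 - k * 0.001)
  expect_identical(tr2$status, "running")
  # out-of-bounds records do not advance the stagnation window
  tr3 <- new_tracker(spec, keep_records = FALSE)
  record_quiet(tr3, 1, cost = 1)
  for (k in 1:200) {
    record_quiet(tr3, 1, cost = 2e5, in_bounds = FALSE, solved = FALSE)
  }
  expect_identical(tr3$status, "running")
})

test_that("the evaluation cap terminates long runs", {
  tr <- new_tracker(termination_spec(1e-12, max_evaluations = 10),
                    keep_records = FALSE)
  for (k in 1:9) record_quiet(tr, 1, cost = 10 - k)
  expect_identical(tr$status, "running")
  record_quiet(tr, 1, cost = 0.5)
  expect_identical(tr$status, "max_iterations")
})

test_that("run summaries convert gradient solves into function evaluations", {
  tr <- new_tracker(termination_spec(1e-3), keep_records = FALSE)
  for (k in 1:100) record_quiet(tr, 1, cost = 10)
  for (k in 1:10) record_quiet(tr, 1, cost = 10, with_sensitivities = TRUE)
  out <- summarise_run(tr, time_ratio = 8.77)
  expect_equal(out$fe_time, 100 + 8.77 * 10)
  expect_equal(out$cost_solves, 100L)
  expect_equal(out$grad_solves, 10L)
  expect_false(out$success)
  out2 <- summarise_run(tr, time_ratio = 5)
  expect_equal(out2$fe_time, 150)
  # with no gradient solves the converted time is the cost-solve count
  tr2 <- new_tracker(termination_spec(1e-3), keep_records = FALSE)
  for (k in 1:7) record_quiet(tr2, 1, cost = 10)
  expect_equal(summarise_run(tr2, time_ratio = 8.77)$fe_time, 7)
})
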