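run_rows <- function(success, fe_time) {
  tibble::tibble(success = success, fe_time = fe_time)
}

test_that("expected run time follows its algebra", {
  all_s <- run_rows(rep(TRUE, 4), rep(500, 4))
  expect_equal(expected_run_time(all_s)$ert, 500)
  mixed <- run_rows(c(TRUE, rep(FALSE, 3)), c(100, 200, 200, 200))
  est <- expected_run_time(mixed)
  expect_equal(est$p_hat, 0.25)
  expect_equal(est$ert, 100 + 200 * 0.75 / 0.25)  # 700
  none <- run_rows(rep(FALSE, 3), c(10, 20, 30))
  expect_identical(expected_run_time(none)$ert, Inf)
  expect_error(expected_run_time(run_rows(logical(), numeric())))
  # ERT decreases as the success rate rises at fixed times
  erts <- vapply(1:9, function(x) {
    expected_run_time(run_rows(c(rep(TRUE, x), rep(FALSE, 10 - x)),
                               rep(100, 10)))$ert
  }, 0)
  expect_true(all(diff(erts) < 0))
  g <- glance(expected_run_time(mixed))
  expect_equal(g$ert, 700)
  td <- tidy(expected_run_time(mixed))
  expect_equal(td$estimate[td$term == "ert"], 700)
})

test_that("time ratios reproduce the published conversion arithmetic", {
  expect_equal(time_ratio(0.00619, 0.372, 25), 26.0, tolerance = 5e-3)
  expect_equal(time_ratio(0.0575, 2.53, 16), 17.0, tolerance = 5e-3)
  expect_equal(time_ratio(0.00613, 0.0537, 9), 8.77, tolerance = 5e-3)
  # the override for simultaneous-perturbation gradient estimates
  expect_identical(time_ratio(0.00613, 0.0537, 9, is_spsa = TRUE), 2)
})

test_that("bootstrapped ERTs are finite, seeded, and Jeffreys-calibrated", {
  none <- run_rows(rep(FALSE, 10), rep(100, 10))
  bs <- bootstrap_ert(none, n_boot = 2000, seed = 5)
  expect_true(all(is.finite(bs) & bs > 0))
  expect_identical(bs, bootstrap_ert(none, n_boot = 2000, seed = 5))
  expect_false(identical(bs, bootstrap_ert(none, n_boot = 2000, seed = 6)))

  # with all times equal, ERT = T/p, so the implied success-rate draws
  # can be recovered and compared with the Beta(x+0.5, n-x+0.5) posterior
  mixed <- run_rows(c(rep(TRUE, 5), rep(FALSE, 5)), rep(100, 10))
  bs2 <- bootstrap_ert(mixed, n_boot = 1e4, seed = 9)
  p_draws <- 100 / bs2
  expect_equal(mean(p_draws), 5.5 / 11, tolerance = 0.02)
  ks <- stats::ks.test(p_draws, stats::pbeta, 5.5, 5.5)
  expect_gt(ks$p.value, 0.01)
})

test_that("all-pairs comparison equals the brute-force count", {
  a <- c(1, 2, 3)
  expect_equal(compare_approaches(a, a)$fraction_a_better, 0.5)
  expect_false(compare_approaches(a, a)$a_significant)
  b <- c(10, 20, 30)
  cmp <- compare_approaches(a, b)
  expect_equal(cmp$fraction_a_better, 1)
  expect_true(cmp$a_significant)
  expect_true(compare_approaches(b, a)$b_significant)
  set.seed(3)
  x <- stats::rlnorm(100, 3, 1)
  y <- stats::rlnorm(100, 3.5, 1)
  y[1:5] <- x[1:5]  # force some ties
  brute <- 0
  for (i in seq_along(x)) {
    for (j in seq_along(y)) {
      brute <- brute + (x[i] < y[j]) + 0.5 * (x[i] == y[j])
    }
  }
  expect_equal(compare_approaches(x, y)$fraction_a_better,
               brute / (length(x) * length(y)))
})

test_that("head-to-head runs share starts and detects separations", {
  # synthetic runners: A succeeds fast, B always fails slowly
  seen_a <- list(); seen_b <- list()
  fast <- function(problem, start, seed) {
    seen_a[[length(seen_a) + 1]] <<- start
    run_rows(TRUE, 50)
  }
  slow <- function(problem, start, seed) {
    seen_b[[length(seen_b) + 1]] <<- start
    run_rows(FALSE, 5000)
  }
  out <- head_to_head(fast, slow, fix_prob, batch_size = 5, seed = 2,
                      max_batches = 4, n_boot = 500)
  expect_identical(out$winner, "A")
  expect_identical(seen_a, seen_b)
  # identical approaches stay undecided
  out2 <- head_to_head(fast, fast, fix_prob, batch_size = 5, seed = 2,
                       max_batches = 3, n_boot = 500)
  expect_identical(out2$winner, "undecided")
  expect_equal(out2$fraction_a_better, 0.5, tolerance = 0.05)
})
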