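test_that("search-space transforms round-trip exactly", {
  pr <- fix_prob
  none <- modification()
  expect_identical(to_search_space(pr$p_star, none, pr), pr$p_star)
  scale <- modification(scale_transform = TRUE)
  expect_equal(to_search_space(pr$p_star, scale, pr), rep(1, 3))
  set.seed(11)
  for (k in 1:20) {
    p <- pr$p_star * exp(stats::runif(3, -2, 2))
    for (mod in list(modification(log_transform = TRUE),
                     modification(scale_transform = TRUE),
                     modification(log_transform = TRUE,
                                  scale_transform = TRUE))) {
      x <- to_search_space(p, mod, pr)
      expect_equal(from_search_space(x, mod, pr), p, tolerance = 1e-12)
    }
  }
  expect_error(to_search_space(c(-1, 0.1, 0.5),
                               modification(log_transform = TRUE), pr),
               "positive")
})

test_that("the penalty reproduces its analytic cases", {
  lower <- c(0, 0)
  upper <- c(1, 1)
  expect_identical(penalty(c(0.5, 0.5), lower, upper), 0)
  # one parameter above its upper bound by e - 1: 1e5 * (1 + ln(e)) = 2e5
  expect_equal(penalty(c(0.5, 1 + (exp(1) - 1)), lower, upper), 2e5)
  # one rate below its lower bound by e - 1, parameters inside
  r <- rate_expr("constant", 3)
  p3 <- c(0.5, 0.5, r$lb - (exp(1) - 1))
  expect_equal(penalty(p3, c(lower, -10), c(upper, 10), list(r)), 2e5)
  # boundary equality counts as a violation (Heaviside at zero is one)
  expect_equal(penalty(c(1, 0.5), lower, upper), 1e5)
  expect_equal(penalty(c(0, 0.5), lower, upper), 1e5)
})

test_that("the penalty jumps at the bound and grows with the violation", {
  lower <- 0; upper <- 1
  inside <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(vapply(inside, function(p) penalty(p, lower, upper), 0) ==
                    0))
  viol <- seq(0, 5, by = 0.25)
  pens <- vapply(viol, function(d) penalty(1 + d, lower, upper), 0)
  expect_true(all(pens >= 1e5))
  expect_true(all(diff(pens) >= 0))
  # same growth below the lower bound (terms are symmetric)
  pens_lo <- vapply(viol, function(d) penalty(-d, lower, upper), 0)
  expect_equal(pens_lo, pens)
})

test_that("penalty subgradient matches finite differences off the bound", {
  lower <- c(0, 0); upper <- c(1, 1)
  r <- rate_expr("pos_exp", 1, 2, lb = 1e-5, ub = 1e-2)
  p <- c(2, 0.1)  # above upper box bound and above the rate upper bound
  g <- chanbench:::penalty_gradient(p, lower, upper, list(r))
  for (i in 1:2) {
    h <- 1e-7
    pp <- p; pp[i] <- pp[i] + h
    pm <- p; pm[i] <- pm[i] - h
    fd <- (penalty(pp, lower, upper, list(r)) -
             penalty(pm, lower, upper, list(r))) / (2 * h)
    expect_equal(g[i], fd, tolerance = 1e-4)
  }
  expect_equal(chanbench:::penalty_gradient(c(0.5, 0.5), lower, upper,
                                            list()),
               c(0, 0))
})

test_that("in_bounds is exactly the zero set of the penalty", {
  for (nm in c("staircase_hh", "staircase_mm", "loewe_ikr", "loewe_ikur",
               "moreno_ina", "fixture_hh")) {
    pr <- build_problem(nm)
    mod <- modification(parameter_bounds = TRUE, rate_bounds = TRUE)
    bc <- check_bounds(pr$p_star, mod, pr)
    # the truth must be reachable under full bounds
    expect_true(bc$in_bounds)
    expect_identical(bc$penalty, 0)
  }
  pr <- fix_prob
  mod <- modification(parameter_bounds = TRUE, rate_bounds = TRUE)
  at_bound <- pr$p_star
  at_bound[2] <- pr$upper[2]
  expect_false(check_bounds(at_bound, mod, pr)$in_bounds)
  # rate-bound-only violation with the parameter box satisfied
  fast <- pr$p_star
  fast[1] <- 900
  fast[2] <- 0.3  # max rate 900 * exp(18) >> 1e3, both params in box
  expect_true(all(fast > pr$lower & fast < pr$upper))
  bc <- check_bounds(fast, mod, pr)
  expect_false(bc$in_bounds)
  expect_gte(bc$penalty, 1e5)
  # without rate bounds the same point is acceptable
  expect_true(check_bounds(fast, modification(parameter_bounds = TRUE),
                           pr)$in_bounds)
})
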