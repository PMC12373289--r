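test_that("protocols validate their invariants and partition sampling times", {
  expect_error(voltage_protocol(data.frame(duration_ms = c(10, -1),
                                           voltage_mV = c(0, 0))),
               "strictly positive")
  expect_error(voltage_protocol(data.frame(duration_ms = 10,
                                           voltage_mV = 0),
                                sampling_times = c(5, 20)),
               "exceed")
  expect_error(voltage_protocol(data.frame(duration_ms = 10,
                                           voltage_mV = 0),
                                sampling_times = c(5, 5)),
               "increasing")
  p <- two_step_protocol()
  expect_equal(protocol_total_ms(p), 450)
  expect_equal(protocol_voltage_at(p, c(10, 60, 260)), c(-80, 20, -40))
  # every sampling time lands in exactly one step
  tab <- chanbench:::protocol_step_table(p)
  idx <- sort(unlist(lapply(tab, `[[`, "which")))
  expect_equal(idx, seq_along(protocol_sampling_times(p)))
})

test_that("protocol CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  p <- two_step_protocol()
  write_protocol_csv(p, path)
  q <- read_protocol_csv(path)
  expect_equal(q$duration_ms, p$duration_ms)
  expect_equal(q$voltage_mV, p$voltage_mV)
  expect_equal(protocol_sampling_times(q), protocol_sampling_times(p))
})

test_that("rate expressions evaluate and maximise analytically", {
  pos <- rate_expr("pos_exp", 1, 2)
  neg <- rate_expr("neg_exp", 3, 4)
  p <- c(2, 0.03, 5, 0.01)
  expect_equal(rate_value(pos, p, 10), 2 * exp(0.3))
  expect_equal(max_rate(pos, p), 2 * exp(60 * 0.03))
  expect_equal(max_rate(neg, p), 5 * exp(120 * 0.01))
  expect_equal(max_rate(rate_expr("constant", 1), p), 2)
  # general rate: grid maximum agrees with a 10x finer grid
  gen <- rate_expr("general", fun = function(p, V) {
    p[1] * exp(-((V - 7) / 40)^2)
  })
  fine <- max(gen$fun(p, seq(-120, 60, by = 0.1)))
  expect_equal(max_rate(gen, p), fine, tolerance = 1e-6)
  # parameter derivatives match finite differences
  for (r in list(pos, neg)) {
    g <- chanbench:::rate_grad(r, p, -30)
    for (i in 1:4) {
      h <- 1e-7 * max(abs(p[i]), 1)
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- pm[i] - h
      expect_equal(g[i],
                   (rate_value(r, pp, -30) - rate_value(r, pm, -30)) /
                     (2 * h),
                   tolerance = 1e-5)
    }
  }
})

test_that("timescale limits of 1 min and 1 us give the standard rate bounds", {
  rb <- rate_bounds_from_timescales()
  expect_equal(unname(rb["lb"]), 1 / 60000)
  expect_equal(unname(rb["ub"]), 1000)
})

test_that("HH analytic solver honours gate fixed points and closed forms", {
  # constant-rate gate: alpha, beta independent of V
  m <- hh_model(
    gates = list(hh_gate(alpha = rate_expr("constant", 1),
                         beta = rate_expr("constant", 2))),
    gfun = function(p, V) p[3], e_rev = -88)
  p <- c(0.2, 0.3, 1.5)
  x_inf <- 0.2 / 0.5
  tau <- 1 / 0.5
  prot <- voltage_protocol(data.frame(duration_ms = 50, voltage_mV = 20),
                           sampling_times = c(1, 5, 20, 50))
  # starting at steady state the trace is exactly constant
  sol <- solve_hh_analytic(m, prot, p)
  expect_equal(sol$current, rep(p[3] * x_inf * (20 + 88), 4))
  # textbook relaxation from a different initial state: fix x0 by
  # prepending a long step at a voltage with the same rates (same x_inf),
  # so instead check the closed form through the ODE solver from truth
  sol_ode <- solve_ode(m, prot, p)
  expect_equal(sol_ode$current, sol$current, tolerance = 1e-6)
})

test_that("HH gate relaxation follows x_inf - (x_inf - x0) exp(-t/tau)", {
  # two steps with V-dependent rates: the second step relaxes from the
  # first step's end value with the second step's x_inf and tau
  m <- small_hh
  p <- small_hh_p
  prot <- voltage_protocol(data.frame(duration_ms = c(400, 100),
                                      voltage_mV = c(-80, 20)),
                           sampling_times = c(400, 410, 450, 500))
  sol <- solve_hh_analytic(m, prot, p)
  a <- function(V) p[1] * exp(p[2] * V)
  b <- function(V) p[3] * exp(-p[4] * V)
  xinf <- function(V) a(V) / (a(V) + b(V))
  tau <- function(V) 1 / (a(V) + b(V))
  # long first step -> gate effectively at steady state of -80
  x0 <- xinf(-80) + (xinf(-80) - xinf(-80)) # = xinf(-80)
  xt <- function(t) xinf(20) - (xinf(20) - x0) * exp(-t / tau(20))
  expected <- p[5] * xt(c(10, 50, 100)) * (20 + 88)
  expect_equal(sol$current[2:4], expected, tolerance = 1e-6)
  # gates stay within [0, 1] for non-negative rates
  full <- solve_hh_analytic(m, two_step_protocol(), p)
  open <- full$current / (p[5] *
    (protocol_voltage_at(two_step_protocol(),
                         full$time) + 88))
  expect_true(all(open >= -1e-12 & open <= 1 + 1e-12))
})

test_that("analytic and adaptive-ODE solvers agree within tolerance", {
  st <- solver_settings(abs_tol = 1e-8, rel_tol = 1e-8)
  for (case in list(list(m = small_hh, p = small_hh_p),
                    list(m = small_markov, p = small_hh_p))) {
    ana <- solve_model(case$m, two_step_protocol(), case$p)
    ode <- solve_ode(case$m, two_step_protocol(), case$p, st)
    bound <- 10 * (st$abs_tol + st$rel_tol * max(abs(ana$current)))
    expect_lt(max(abs(ana$current - ode$current)), bound)
  }
  # staircase HH problem model at truth
  pr <- build_problem("staircase_hh")
  ana <- solve_model(pr$model, pr$protocol, pr$p_star)
  ode <- solve_ode(pr$model, pr$protocol, pr$p_star, st)
  bound <- 10 * (st$abs_tol + st$rel_tol * max(abs(ana$current)))
  expect_lt(max(abs(ana$current - ode$current)), bound)
})

test_that("tightening ODE tolerances shrinks the solver error", {
  ana <- solve_model(small_hh, two_step_protocol(), small_hh_p)
  loose <- solve_ode(small_hh, two_step_protocol(), small_hh_p,
                     solver_settings(1e-6, 1e-6))
  tight <- solve_ode(small_hh, two_step_protocol(), small_hh_p,
                     solver_settings(1e-7, 1e-7))
  err_loose <- max(abs(loose$current - ana$current))
  err_tight <- max(abs(tight$current - ana$current))
  expect_lt(err_tight, err_loose + 1e-12)
})

test_that("absurd parameters signal failure instead of crashing", {
  # overflowing rates: non-finite model quantities become failure signals
  p_overflow <- c(1e300, 10, 0.08, 0.04, 0.7)
  expect_true(is_sim_failure(solve_hh_analytic(small_hh,
                                               two_step_protocol(),
                                               p_overflow)))
  expect_true(is_sim_failure(solve_ode(small_markov, two_step_protocol(),
                                       p_overflow)))
  expect_true(is_sim_failure(solve_markov_analytic(small_markov,
                                                   two_step_protocol(),
                                                   p_overflow)))
  # merely extreme rates (1e12 ms^-1) must not crash either: every solver
  # returns a finite trace or a failure signal
  p_stiff <- c(1e12, 10, 0.08, 0.04, 0.7)
  for (sol in list(solve_hh_analytic(small_hh, two_step_protocol(),
                                     p_stiff),
                   solve_ode(small_markov, two_step_protocol(), p_stiff),
                   solve_markov_analytic(small_markov, two_step_protocol(),
                                         p_stiff))) {
    expect_true(is_sim_failure(sol) || all(is.finite(sol$current)))
  }
})

test_that("2-state Markov model reproduces the single-gate HH solution", {
  a <- solve_hh_analytic(small_hh, two_step_protocol(), small_hh_p)
  b <- solve_markov_analytic(small_markov, two_step_protocol(), small_hh_p)
  expect_equal(b$current, a$current, tolerance = 1e-12)
})

test_that("Markov occupancies are conserved and stay in [0, 1]", {
  pr <- build_problem("staircase_mm")
  sol <- solve_markov_analytic(pr$model, pr$protocol, pr$p_star)
  expect_lt(max(abs(colSums(sol$states) - 1)), 1e-10)
  expect_true(all(sol$states >= -1e-10 & sol$states <= 1 + 1e-10))
})

test_that("a state with no exit transitions keeps occupancy one", {
  m <- markov_model(
    2, list(list(from = 2, to = 1, rate = rate_expr("constant", 1))),
    open_state = 1, gfun = function(p, V) 1, e_rev = 0)
  # all mass starts in the open state (state 1 absorbs)
  sol <- solve_markov_analytic(m, two_step_protocol(), c(0.5),
                               x0 = c(1, 0))
  expect_equal(sol$states[1, ], rep(1, ncol(sol$states)))
})

test_that("sensitivities match central finite differences", {
  fd_check <- function(model, p, solver, tol) {
    s <- solve_with_sensitivities(model, two_step_protocol(), p)
    for (i in seq_along(p)) {
      h <- 1e-6 * abs(p[i])
      pp <- p; pp[i] <- pp[i] + h
      pm <- p; pm[i] <- pm[i] - h
      fd <- (solver(model, two_step_protocol(), pp)$current -
               solver(model, two_step_protocol(), pm)$current) / (2 * h)
      denom <- max(abs(fd), 1e-12)
      expect_lt(max(abs(s$sensitivities[, i] - fd)) / denom, tol)
    }
  }
  fd_check(small_hh, small_hh_p, solve_hh_analytic, 1e-3)
  fd_check(small_markov, small_hh_p, solve_markov_analytic, 1e-3)
})

test_that("conductance sensitivity is I/g and unused parameters get zeros", {
  # add a dummy sixth parameter that the model never reads
  p <- c(small_hh_p, 123)
  s <- solve_with_sensitivities(small_hh, two_step_protocol(), p)
  expect_equal(s$sensitivities[, 5], s$current / p[5], tolerance = 1e-9)
  expect_equal(s$sensitivities[, 6], rep(0, length(s$current)))
})
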