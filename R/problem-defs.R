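# --- Benchmark problem definitions -----------------------------------------
#
# Five benchmark problems spanning the recurring difficulties of cardiac
# channel fitting -- fast/slow channels (IKr, IKur, INa), Hodgkin-Huxley and
# Markov formulations, trace and summary-statistic costs, noisy and
# noise-free data, 9 to 25 parameters, and wide or narrow sampling regions --
# plus a 3-parameter fixture for fast tests. Success thresholds were derived
# with cost_slices()/cost_threshold() (minimum cost at one-at-a-time +/-5%
# perturbations of the truth) and are stored as problem constants.

# desk-scale staircase-style protocol: hyperpolarising reference step, then
# ascending depolarising staircase with repolarising dips
staircase_protocol <- function(dt = 1) {
  up <- c(-60, -40, -20, 0, 20, 40)
  steps <- rbind(
    data.frame(duration_ms = c(250, 50, 200), voltage_mV = c(-80, -120, -80)),
    do.call(rbind, lapply(up, function(v) {
      data.frame(duration_ms = c(500, 100), voltage_mV = c(v, v - 20))
    })),
    data.frame(duration_ms = c(100, 100), voltage_mV = c(-120, -80))
  )
  voltage_protocol(steps, dt = dt)
}

step_protocol <- function(v_test, dt = 1) {
  voltage_protocol(data.frame(duration_ms = c(100, 500, 500),
                              voltage_mV = c(-80, v_test, -40)), dt = dt)
}

# success thresholds from the +/-5% one-at-a-time slice procedure
.cost_thresholds <- list(
  staircase_hh = 0.0155566,
  staircase_mm = 0.0058059,
  loewe_ikr = 6.46356e-5,
  loewe_ikur = 7.66327e-6,
  moreno_ina = 6.64093e-4,
  fixture_hh = 0.33738
)

staircase_hh_model <- function() {
  # two-gate (activation x inactivation) IKr model; A exp(+/-bV) rates
  a_gate <- hh_gate(alpha = rate_expr("pos_exp", 1, 2),
                    beta = rate_expr("neg_exp", 3, 4))
  r_gate <- hh_gate(alpha = rate_expr("neg_exp", 7, 8),
                    beta = rate_expr("pos_exp", 5, 6))
  hh_model(gates = list(a_gate, r_gate),
           gfun = function(p, V) p[9], e_rev = -88)
}

build_staircase_hh <- function() {
  p_star <- c(2.26e-4, 0.0699, 3.45e-5, 0.05462,
              0.0873, 8.91e-3, 5.15e-3, 0.03158, 0.1524)
  a_idx <- c(1, 3, 5, 7)
  b_idx <- c(2, 4, 6, 8)
  lower <- numeric(9); upper <- numeric(9)
  lower[a_idx] <- 1e-7; upper[a_idx] <- 1e3
  lower[b_idx] <- 1e-7; upper[b_idx] <- 0.4
  lower[9] <- p_star[9] / 10; upper[9] <- p_star[9] * 10
  sampling <- vector("list", 9)
  for (i in a_idx) sampling[[i]] <- list(kind = "log_uniform_box")
  for (i in b_idx) sampling[[i]] <- list(kind = "uniform_box")
  sampling[[9]] <- list(kind = "log_uniform_factor", lo = 0.1, hi = 10)
  new_benchmark_problem(
    name = "staircase_hh", model = staircase_hh_model(),
    protocol = staircase_protocol(), p_star = p_star,
    sampling = sampling, lower = lower, upper = upper,
    log_idx = c(a_idx, 9), sigma = 0.01558, data_seed = 20260101L,
    cost_threshold = .cost_thresholds$staircase_hh,
    n_run_default = 10L, force_bounds = TRUE,
    sampling_reject_rates = TRUE)
}

staircase_mm_model <- function() {
  # five-state IKr Markov chain C1-C2-C3-O-I with one voltage-independent
  # transition pair
  tr <- list(
    list(from = 1, to = 2, rate = rate_expr("pos_exp", 1, 2)),
    list(from = 2, to = 1, rate = rate_expr("neg_exp", 3, 4)),
    list(from = 2, to = 3, rate = rate_expr("constant", 5)),
    list(from = 3, to = 2, rate = rate_expr("constant", 6)),
    list(from = 3, to = 4, rate = rate_expr("pos_exp", 7, 8)),
    list(from = 4, to = 3, rate = rate_expr("neg_exp", 9, 10)),
    list(from = 4, to = 5, rate = rate_expr("pos_exp", 11, 12)),
    list(from = 5, to = 4, rate = rate_expr("neg_exp", 13, 14))
  )
  markov_model(5, tr, open_state = 4,
               gfun = function(p, V) p[15], e_rev = -88,
               state_names = c("C1", "C2", "C3", "O", "I"))
}

build_staircase_mm <- function() {
  p_star <- c(0.022348, 0.01176, 0.047002, 0.0631,
              0.023761, 0.036778,
              0.013733, 0.038198, 6.89e-5, 0.04178,
              0.090821, 0.023391, 0.006497, 0.03268,
              0.1524)
  a_idx <- c(1, 3, 5, 6, 7, 9, 11, 13)
  b_idx <- c(2, 4, 8, 10, 12, 14)
  lower <- numeric(15); upper <- numeric(15)
  lower[a_idx] <- 1e-7; upper[a_idx] <- 1e3
  lower[b_idx] <- 1e-7; upper[b_idx] <- 0.4
  lower[15] <- p_star[15] / 10; upper[15] <- p_star[15] * 10
  sampling <- vector("list", 15)
  for (i in a_idx) sampling[[i]] <- list(kind = "log_uniform_box")
  for (i in b_idx) sampling[[i]] <- list(kind = "uniform_box")
  sampling[[15]] <- list(kind = "log_uniform_factor", lo = 0.1, hi = 10)
  new_benchmark_problem(
    name = "staircase_mm", model = staircase_mm_model(),
    protocol = staircase_protocol(), p_star = p_star,
    sampling = sampling, lower = lower, upper = upper,
    log_idx = c(a_idx, 15), sigma = 0.005767, data_seed = 20260102L,
    cost_threshold = .cost_thresholds$staircase_mm,
    n_run_default = 50L, force_bounds = TRUE,
    sampling_reject_rates = TRUE)
}

# singularity-safe x * a / (1 - exp(-x/s)) style rate pieces
.lin_exp_pos <- function(a, x, s) {
  u <- x / s
  out <- ifelse(abs(u) < 1e-7, a * s, a * x / (1 - exp(-u)))
  out
}
.lin_exp_neg <- function(a, x, s) {
  u <- x / s
  ifelse(abs(u) < 1e-7, a * s, a * x / (exp(u) - 1))
}

loewe_ikr_model <- function() {
  alpha <- function(p, V) .lin_exp_pos(p[1], V + p[2], p[3])
  beta <- function(p, V) .lin_exp_neg(p[4], V - p[5], p[6])
  xr <- hh_gate(
    ss_fun = function(p, V) 1 / (1 + exp(-(V + p[7]) / p[8])),
    tau_fun = function(p, V) 1 / (p[12] * (alpha(p, V) + beta(p, V))))
  hh_model(
    gates = list(xr),
    instant = list(function(p, V) 1 / (1 + exp((V + p[9]) / p[10]))),
    gfun = function(p, V) p[11], e_rev = -88,
    rates = list(
      rate_expr("general", fun = function(p, V) p[12] * alpha(p, V)),
      rate_expr("general", fun = function(p, V) p[12] * beta(p, V))
    ))
}

loewe_bounds <- function(p_star, mult_idx, add_idx, offset = 60) {
  lower <- numeric(length(p_star)); upper <- numeric(length(p_star))
  lower[mult_idx] <- p_star[mult_idx] * 0.1
  upper[mult_idx] <- p_star[mult_idx] * 10
  lower[add_idx] <- p_star[add_idx] - offset
  upper[add_idx] <- p_star[add_idx] + offset
  sampling <- vector("list", length(p_star))
  for (i in mult_idx) {
    sampling[[i]] <- list(kind = "log_uniform_factor", lo = 0.1, hi = 10)
  }
  for (i in add_idx) {
    sampling[[i]] <- list(kind = "uniform_offset", width = offset)
  }
  list(lower = lower, upper = upper, sampling = sampling)
}

build_loewe_ikr <- function() {
  p_star <- c(0.0003, 14.1, 5, 7.3898e-5, 3.3328, 5.1237,
              14.1, 6.5, 15, 22.4, 0.029411765, 1)
  mult_idx <- c(1, 3, 4, 6, 8, 10, 11, 12)
  add_idx <- c(2, 5, 7, 9)
  b <- loewe_bounds(p_star, mult_idx, add_idx)
  new_benchmark_problem(
    name = "loewe_ikr", model = loewe_ikr_model(),
    protocol = step_protocol(20), p_star = p_star,
    sampling = b$sampling, lower = b$lower, upper = b$upper,
    log_idx = mult_idx, sigma = 0, data_seed = 20260103L,
    cost_threshold = .cost_thresholds$loewe_ikr,
    n_run_default = 10L)
}

loewe_ikur_model <- function() {
  a_ua <- function(p, V) {
    p[1] / (exp(-(V + p[2]) / p[3]) + exp(-(V - p[4]) / p[5]))
  }
  b_ua <- function(p, V) p[6] / (p[7] + exp((V + p[8]) / p[9]))
  a_ui <- function(p, V) p[13] / (p[14] + exp(-(V - p[15]) / p[16]))
  b_ui <- function(p, V) p[17] * exp((V - p[18]) / p[19])
  ua <- hh_gate(
    ss_fun = function(p, V) 1 / (1 + exp(-(V + p[11]) / p[12])),
    tau_fun = function(p, V) 1 / (p[10] * (a_ua(p, V) + b_ua(p, V))),
    exponent = 3L)
  ui <- hh_gate(
    ss_fun = function(p, V) 1 / (1 + exp((V - p[20]) / p[21])),
    tau_fun = function(p, V) 1 / (p[10] * (a_ui(p, V) + b_ui(p, V))))
  hh_model(
    gates = list(ua, ui),
    gfun = function(p, V) p[22] + p[23] / (1 + exp(-(V - p[24]) / p[25])),
    e_rev = -88,
    rates = list(
      rate_expr("general", fun = function(p, V) p[10] * a_ua(p, V)),
      rate_expr("general", fun = function(p, V) p[10] * b_ua(p, V)),
      rate_expr("general", fun = function(p, V) p[10] * a_ui(p, V)),
      rate_expr("general", fun = function(p, V) p[10] * b_ui(p, V))
    ))
}

build_loewe_ikur <- function() {
  p_star <- c(0.65, 10, 8.5, 30, 59,
              0.65, 2.5, 82, 17,
              3,
              30.3, 9.6,
              1, 21, 185, 28,
              1, 158, 16,
              99.45, 27.48,
              0.005, 0.05, 15, 13)
  mult_idx <- c(1, 3, 5, 6, 7, 9, 10, 12, 13, 14, 16, 17, 19, 21, 22, 23, 25)
  add_idx <- c(2, 4, 8, 11, 15, 18, 20, 24)
  b <- loewe_bounds(p_star, mult_idx, add_idx)
  new_benchmark_problem(
    name = "loewe_ikur", model = loewe_ikur_model(),
    protocol = step_protocol(30), p_star = p_star,
    sampling = b$sampling, lower = b$lower, upper = b$upper,
    log_idx = mult_idx, sigma = 0, data_seed = 20260104L,
    cost_threshold = .cost_thresholds$loewe_ikur,
    n_run_default = 100L)
}

moreno_ina_model <- function() {
  # five-state INa-like chain C3-C2-C1-O-IF; the two fast deactivation
  # rates carry the relaxed 1e7 ms^-1 upper rate bound (their maxima at
  # the true parameters exceed 1e3 ms^-1, yet the truth must stay
  # accessible under rate bounds)
  tr <- list(
    list(from = 1, to = 2, rate = rate_expr("pos_exp", 1, 2)),
    list(from = 2, to = 1, rate = rate_expr("neg_exp", 3, 4, ub = 1e7)),
    list(from = 2, to = 3, rate = rate_expr("pos_exp", 5, 6)),
    list(from = 3, to = 2, rate = rate_expr("neg_exp", 7, 8, ub = 1e7)),
    list(from = 3, to = 4, rate = rate_expr("pos_exp", 9, 10)),
    list(from = 4, to = 3, rate = rate_expr("neg_exp", 11, 12)),
    list(from = 4, to = 5, rate = rate_expr("pos_exp", 13, 14)),
    list(from = 5, to = 4, rate = rate_expr("neg_exp", 15, 16))
  )
  markov_model(5, tr, open_state = 4,
               gfun = function(p, V) 1, e_rev = 65,
               state_names = c("C3", "C2", "C1", "O", "IF"))
}

build_moreno_ina <- function() {
  p_star <- c(8, 0.04, 3, 0.05,
              12, 0.035, 4, 0.06,
              20, 0.03, 0.8, 0.055,
              2, 0.008, 0.02, 0.03)
  lower <- p_star * 0.75
  upper <- p_star * 1.25
  sampling <- rep(list(list(kind = "uniform_fraction", frac = 0.25)), 16)
  new_benchmark_problem(
    name = "moreno_ina", model = moreno_ina_model(),
    protocol = step_protocol(-10), p_star = p_star,
    sampling = sampling, lower = lower, upper = upper,
    log_idx = c(1, 3, 5, 7, 9, 11, 13, 15), sigma = 0,
    data_seed = 20260105L, cost_kind = "summary_stats",
    cost_threshold = .cost_thresholds$moreno_ina,
    n_run_default = 10L)
}

fixture_hh_model <- function() {
  gate <- hh_gate(alpha = rate_expr("pos_exp", 1, 2),
                  beta = rate_expr("general",
                                   fun = function(p, V) {
                                     0.08 * exp(-0.045 * V)
                                   }))
  hh_model(gates = list(gate), gfun = function(p, V) p[3], e_rev = -88)
}

build_fixture_hh <- function() {
  p_star <- c(0.03, 0.06, 0.5)
  lower <- c(1e-7, 1e-7, 0.05)
  upper <- c(1e3, 0.4, 5)
  sampling <- list(list(kind = "log_uniform_box"),
                   list(kind = "uniform_box"),
                   list(kind = "log_uniform_factor", lo = 0.1, hi = 10))
  prot <- voltage_protocol(data.frame(duration_ms = c(100, 300, 300),
                                      voltage_mV = c(-80, 20, -50)))
  new_benchmark_problem(
    name = "fixture_hh", model = fixture_hh_model(),
    protocol = prot, p_star = p_star,
    sampling = sampling, lower = lower, upper = upper,
    log_idx = c(1, 3), sigma = 0, data_seed = 20260106L,
    cost_threshold = .cost_thresholds$fixture_hh,
    n_run_default = 10L, sampling_reject_rates = TRUE)
}

#' Build a benchmark problem by name
#'
#' The five benchmark problems plus a fast 3-parameter fixture:
#'
#' * `staircase_hh` -- IKr, two-gate Hodgkin-Huxley model, staircase-style
#'   protocol, noisy trace, 9 parameters, wide (rate-bound-constrained)
#'   sampling region.
#' * `staircase_mm` -- IKr, five-state Markov model, same protocol and
#'   noise treatment, 15 parameters.
#' * `loewe_ikr` -- IKr, Hodgkin-Huxley formulation with linear-exponential
#'   rates and an instantaneous rectification gate, simple step protocol,
#'   noise-free trace, 12 parameters.
#' * `loewe_ikur` -- IKur, two-gate (cubed activation) Hodgkin-Huxley
#'   formulation with voltage-dependent conductance, noise-free trace,
#'   25 parameters.
#' * `moreno_ina` -- INa, five-state Markov model, summary-statistic cost
#'   (steady-state activation/inactivation, recovery, time to 50% decay),
#'   16 parameters, narrow (+/-25%) sampling region.
#' * `fixture_hh` -- 3-parameter single-gate toy problem for fast tests.
#'
#' Problem data are regenerated deterministically from a stored seed at
#' construction; the staircase problems always enforce parameter and rate
#' bounds regardless of the approach's modification.
#'
#' @param name Problem name (see above).
#' @return A `benchmark_problem`.
#' @examples
#' prob <- build_problem("fixture_hh")
#' problem_cost(prob, prob$p_star)  # ~0: noise-free truth
#' @export
build_problem <- function(name = c("staircase_hh", "staircase_mm",
                                   "loewe_ikr", "loewe_ikur",
                                   "moreno_ina", "fixture_hh")) {
  name <- match.arg(name)
  switch(name,
    staircase_hh = build_staircase_hh(),
    staircase_mm = build_staircase_mm(),
    loewe_ikr = build_loewe_ikr(),
    loewe_ikur = build_loewe_ikur(),
    moreno_ina = build_moreno_ina(),
    fixture_hh = build_fixture_hh())
}
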