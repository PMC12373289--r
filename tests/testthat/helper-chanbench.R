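# shared fixtures, built once per test run

fix_prob <- build_problem("fixture_hh")

two_step_protocol <- function(dt = 1) {
  voltage_protocol(data.frame(duration_ms = c(50, 200, 200),
                              voltage_mV = c(-80, 20, -40)), dt = dt)
}

# single-gate HH model with both rates parametric; 5 parameters
small_hh <- hh_model(
  gates = list(hh_gate(alpha = rate_expr("pos_exp", 1, 2),
                       beta = rate_expr("neg_exp", 3, 4))),
  gfun = function(p, V) p[5], e_rev = -88)
small_hh_p <- c(0.03, 0.05, 0.08, 0.04, 0.7)

# the same kinetics as a 2-state Markov scheme
small_markov <- markov_model(
  2,
  list(list(from = 1, to = 2, rate = rate_expr("pos_exp", 1, 2)),
       list(from = 2, to = 1, rate = rate_expr("neg_exp", 3, 4))),
  open_state = 2, gfun = function(p, V) p[5], e_rev = -88)

# ad-hoc approach spec (an optimiser id plus modification flags)
make_spec <- function(optimiser, ..., category = "gradient_descent",
                      hyper = list()) {
  structure(list(name = paste0("adhoc_", optimiser), optimiser = optimiser,
                 category = category, uses_gradient = TRUE,
                 implemented = TRUE,
                 modification = modification(..., hyperparameters = hyper)),
            class = "approach_spec")
}

new_approach_spec <- function(hyper = list()) {
  make_spec("trr", log_transform = TRUE, parameter_bounds = TRUE,
            rate_bounds = TRUE, hyper = hyper)
}

# record evaluations without tripping over the termination condition
record_quiet <- function(tracker, ...) {
  tryCatch(record_evaluation(tracker, ...),
           chanbench_terminate = function(c) invisible(NULL))
}
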