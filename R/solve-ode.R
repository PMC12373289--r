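#' Adaptive ODE solver settings
#'
#' @param abs_tol,rel_tol Absolute and relative tolerances of the adaptive
#'   integrator; both must be positive. Defaults 1e-8/1e-8 keep solver noise
#'   well below the benchmark success thresholds; problems may override.
#' @param sensitivities Solve the forward sensitivity system as well.
#' @return An object of class `solver_settings`.
#' @export
solver_settings <- function(abs_tol = 1e-8, rel_tol = 1e-8,
                            sensitivities = FALSE) {
  stopifnot(abs_tol > 0, rel_tol > 0)
  structure(list(abs_tol = abs_tol, rel_tol = rel_tol,
                 sensitivities = sensitivities),
            class = "solver_settings")
}

#' Adaptive-ODE forward solve of a channel model
#'
#' Integrates the model's gating/occupancy ODEs step by step over the
#' piecewise-constant protocol with `deSolve`'s `lsoda`, restarting the
#' integrator at each voltage discontinuity. Agrees with the analytic
#' solvers within a tolerance-scaled error on analytically solvable models.
#' Integrator failures (e.g. at absurd parameter values) are returned as a
#' simulation-failure signal, not an error.
#'
#' @param model An [hh_model()] or [markov_model()].
#' @param protocol A [voltage_protocol()].
#' @param params Model parameter vector.
#' @param settings A [solver_settings()].
#' @return A list with `time` and `current`, or a simulation-failure signal.
#' @export
solve_ode <- function(model, protocol, params, settings = solver_settings()) {
  UseMethod("solve_ode")
}

#' @export
solve_ode.hh_model <- function(model, protocol, params,
                               settings = solver_settings()) {
  st <- protocol_sampling_times(protocol)
  nt <- length(st)
  steps <- protocol_step_table(protocol)
  ngate <- length(model$gates)

  v0 <- steps[[1]]$voltage
  x <- vapply(model$gates, function(g) gate_ss_tau(g, params, v0)$ss, 0)
  if (any(!is.finite(x))) return(sim_failure(nt))

  gate_vals <- matrix(NA_real_, nt, ngate)
  v_out <- numeric(nt)
  for (stp in steps) {
    V <- stp$voltage
    sstau <- lapply(model$gates, gate_ss_tau, params = params, V = V)
    ss <- vapply(sstau, `[[`, 0, "ss")
    tau <- vapply(sstau, `[[`, 0, "tau")
    if (any(!is.finite(ss)) || any(!is.finite(tau)) || any(tau <= 0)) {
      return(sim_failure(nt))
    }
    rhs <- function(t, y, parms) list((ss - y) / tau)
    tout <- sort(unique(c(0, stp$t_local, stp$duration)))
    sol <- tryCatch(
      deSolve::lsoda(x, tout, rhs, parms = NULL,
                     rtol = settings$rel_tol, atol = settings$abs_tol),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(tout) || any(!is.finite(sol))) {
      return(sim_failure(nt, "ODE integration failed"))
    }
    if (length(stp$t_local)) {
      idx <- match(stp$t_local, tout)
      gate_vals[stp$which, ] <- sol[idx, -1, drop = FALSE]
      v_out[stp$which] <- V
    }
    x <- as.numeric(sol[nrow(sol), -1])
  }
  expo <- vapply(model$gates, function(g) g$exponent, 0L)
  open_dyn <- Reduce(`*`, lapply(seq_len(ngate),
                                 function(i) gate_vals[, i]^expo[i]))
  inst_vals <- lapply(model$instant, function(f) f(params, v_out))
  open_inst <- if (length(inst_vals)) Reduce(`*`, inst_vals) else rep(1, nt)
  current <- model$gfun(params, v_out) * open_dyn * open_inst *
    (v_out - model$e_rev)
  if (any(!is.finite(current))) return(sim_failure(sum(!is.finite(current))))
  list(time = st, current = current)
}

#' @export
solve_ode.markov_model <- function(model, protocol, params,
                                   settings = solver_settings()) {
  st <- protocol_sampling_times(protocol)
  nt <- length(st)
  n <- model$n_states
  steps <- protocol_step_table(protocol)

  Q0 <- markov_Q(model, params, steps[[1]]$voltage)
  if (any(!is.finite(Q0))) return(sim_failure(nt))
  x <- markov_steady_state(Q0)
  if (is.null(x)) return(sim_failure(nt))

  states <- matrix(NA_real_, n, nt)
  v_out <- numeric(nt)
  for (stp in steps) {
    Q <- markov_Q(model, params, stp$voltage)
    if (any(!is.finite(Q))) return(sim_failure(nt))
    rhs <- function(t, y, parms) list(as.numeric(Q %*% y))
    tout <- sort(unique(c(0, stp$t_local, stp$duration)))
    sol <- tryCatch(
      deSolve::lsoda(x, tout, rhs, parms = NULL,
                     rtol = settings$rel_tol, atol = settings$abs_tol),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(tout) || any(!is.finite(sol))) {
      return(sim_failure(nt, "ODE integration failed"))
    }
    if (length(stp$t_local)) {
      idx <- match(stp$t_local, tout)
      states[, stp$which] <- t(sol[idx, -1, drop = FALSE])
      v_out[stp$which] <- stp$voltage
    }
    x <- as.numeric(sol[nrow(sol), -1])
  }
  current <- model$gfun(params, v_out) * states[model$open_state, ] *
    (v_out - model$e_rev)
  if (any(!is.finite(current))) return(sim_failure(sum(!is.finite(current))))
  list(time = st, current = current, states = states)
}

#' Forward solve with parameter sensitivities
#'
#' Returns the current trace together with the matrix of partial
#' derivatives of the current with respect to every model parameter
#' (times x parameters). Hodgkin-Huxley models differentiate the per-step
#' analytic gate solution; Markov models integrate the forward sensitivity
#' system alongside the occupancies. The harness records such solves as
#' gradient solves, which are more expensive than plain cost solves.
#'
#' @inheritParams solve_ode
#' @return A list with `time`, `current` and `sensitivities`, or a
#'   simulation-failure signal.
#' @export
solve_with_sensitivities <- function(model, protocol, params,
                                     settings = solver_settings()) {
  if (inherits(model, "hh_model")) {
    solve_hh_analytic(model, protocol, params, with_sensitivities = TRUE)
  } else {
    solve_markov_sensitivities(model, protocol, params, settings)
  }
}

#' Default forward solve of a channel model
#'
#' Dispatches to the analytic per-step solver appropriate for the model
#' class (the fast path used for cost evaluations).
#'
#' @inheritParams solve_ode
#' @return A list with `time` and `current`, or a simulation-failure signal.
#' @export
solve_model <- function(model, protocol, params) {
  if (inherits(model, "hh_model")) {
    solve_hh_analytic(model, protocol, params)
  } else {
    solve_markov_analytic(model, protocol, params)
  }
}
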