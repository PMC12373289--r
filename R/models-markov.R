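#' Markov channel models
#'
#' A Markov model describes the channel as a continuous-time linear ODE over
#' discrete conformational-state occupancies, `dx/dt = Q(V) x`, where the
#' generator `Q` collects voltage-dependent transition rates: for a
#' transition from state `i` to state `j` with rate `r`, `Q[j, i] += r` and
#' `Q[i, i] -= r`, so columns sum to zero and total occupancy is conserved.
#' The current is `I = g(V) * x[open] * (V - E_rev)`.
#'
#' @param n_states Number of conformational states.
#' @param transitions List of `list(from =, to =, rate = rate_expr)`.
#'   One-directional; supply both directions explicitly.
#' @param open_state Index of the conducting state.
#' @param gfun Conductance `function(params, V)`, mS.
#' @param e_rev Reversal potential, mV.
#' @param state_names Optional character names.
#' @return An object of class `markov_model`.
#' @export
markov_model <- function(n_states, transitions, open_state, gfun, e_rev,
                         state_names = NULL) {
  stopifnot(n_states >= 2, open_state >= 1, open_state <= n_states)
  for (tr in transitions) {
    stopifnot(tr$from != tr$to, inherits(tr$rate, "rate_expr"))
  }
  rates <- lapply(transitions, function(tr) tr$rate)
  structure(list(n_states = n_states, transitions = transitions,
                 open_state = open_state, gfun = gfun, e_rev = e_rev,
                 state_names = state_names, rates = rates),
            class = c("markov_model", "channel_model"))
}

# generator matrix Q(V); columns sum to zero
markov_Q <- function(model, params, V) {
  n <- model$n_states
  Q <- matrix(0, n, n)
  for (tr in model$transitions) {
    r <- rate_value(tr$rate, params, V)
    Q[tr$to, tr$from] <- Q[tr$to, tr$from] + r
    Q[tr$from, tr$from] <- Q[tr$from, tr$from] - r
  }
  Q
}

# dQ/dp as a list of n x n matrices (analytic through rate_grad)
markov_dQ <- function(model, params, V) {
  n <- model$n_states
  np <- length(params)
  dQ <- lapply(seq_len(np), function(i) matrix(0, n, n))
  for (tr in model$transitions) {
    dr <- rate_grad(tr$rate, params, V)
    for (i in which(dr != 0)) {
      dQ[[i]][tr$to, tr$from] <- dQ[[i]][tr$to, tr$from] + dr[i]
      dQ[[i]][tr$from, tr$from] <- dQ[[i]][tr$from, tr$from] - dr[i]
    }
  }
  dQ
}

# stationary distribution of Q (occupancies summing to 1)
markov_steady_state <- function(Q) {
  n <- nrow(Q)
  A <- rbind(Q[-n, , drop = FALSE], rep(1, n))
  b <- c(rep(0, n - 1), 1)
  x <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(x) || any(!is.finite(x))) return(NULL)
  x
}

#' Analytic solution of a Markov model over a step protocol
#'
#' Within each constant-voltage step the occupancy vector is propagated by
#' the matrix-exponential solution of the constant-coefficient linear ODE,
#' evaluated through an eigendecomposition of the generator (with a dense
#' matrix-exponential fallback when the eigenbasis is ill-conditioned).
#' Decompositions are cached per step voltage within one trace solve, since
#' protocols revisit voltages. States are initialised at the stationary
#' distribution of the first step's voltage unless `x0` is given.
#'
#' @param model A [markov_model()].
#' @param protocol A [voltage_protocol()].
#' @param params Model parameter vector.
#' @param x0 Optional initial occupancy vector (summing to 1).
#' @return A list with `time`, `current`, and `states` (states x times
#'   matrix); or a simulation-failure signal.
#' @export
solve_markov_analytic <- function(model, protocol, params, x0 = NULL) {
  st <- protocol_sampling_times(protocol)
  nt <- length(st)
  steps <- protocol_step_table(protocol)
  n <- model$n_states

  cache <- new.env(parent = emptyenv())
  decomp <- function(V) {
    key <- format(V, digits = 15)
    if (!is.null(cache[[key]])) return(cache[[key]])
    Q <- markov_Q(model, params, V)
    if (any(!is.finite(Q))) return(NULL)
    d <- tryCatch({
      e <- eigen(Q)
      Sinv <- solve(e$vectors)
      if (any(!is.finite(Mod(Sinv)))) NULL
      else list(Q = Q, vals = e$values, S = e$vectors, Sinv = Sinv)
    }, error = function(e) NULL)
    # defective / ill-conditioned eigenbasis: fall back to dense expm
    if (is.null(d)) d <- list(Q = Q, vals = NULL, S = NULL, Sinv = NULL)
    cache[[key]] <- d
    d
  }
  propagate <- function(d, x, times) {
    # occupancies at `times` (relative to step start), columns per time
    if (!is.null(d$vals)) {
      w <- d$Sinv %*% x
      E <- exp(outer(d$vals, times))
      out <- Re(d$S %*% (E * as.vector(w)))
    } else {
      out <- matrix(NA_real_, n, length(times))
      for (k in seq_along(times)) {
        out[, k] <- as.numeric(
          Matrix::expm(d$Q * times[k]) %*% x)
      }
    }
    out
  }

  if (is.null(x0)) {
    d0 <- decomp(steps[[1]]$voltage)
    if (is.null(d0)) return(sim_failure(nt))
    x0 <- markov_steady_state(d0$Q)
    if (is.null(x0)) return(sim_failure(nt))
  }
  x <- x0
  states <- matrix(NA_real_, n, nt)
  v_out <- numeric(nt)

  for (stp in steps) {
    d <- decomp(stp$voltage)
    if (is.null(d)) return(sim_failure(nt))
    if (length(stp$t_local)) {
      vals <- propagate(d, x, stp$t_local)
      states[, stp$which] <- vals
      v_out[stp$which] <- stp$voltage
    }
    x <- as.numeric(propagate(d, x, stp$duration))
    if (any(!is.finite(x)) || abs(sum(x) - 1) > 1e-6) {
      return(sim_failure(nt, "occupancy propagation failed"))
    }
  }
  if (any(!is.finite(states))) return(sim_failure(sum(!is.finite(states[1, ]))))

  gcond <- model$gfun(params, v_out)
  current <- gcond * states[model$open_state, ] * (v_out - model$e_rev)
  if (any(!is.finite(current))) {
    return(sim_failure(sum(!is.finite(current))))
  }
  list(time = st, current = current, states = states)
}

# Forward sensitivities for a Markov model: the augmented linear system
#   dx/dt  = Q x
#   ds_k/dt = Q s_k + (dQ/dp_k) x
# integrated per step with an adaptive ODE solver (dQ/dp_k is constant
# within a step). Initial sensitivities are those of the stationary
# distribution at the holding potential: Q s0 + dQ x0 = 0 with sum(s0) = 0.
solve_markov_sensitivities <- function(model, protocol, params,
                                       settings = solver_settings()) {
  st <- protocol_sampling_times(protocol)
  nt <- length(st)
  np <- length(params)
  n <- model$n_states
  steps <- protocol_step_table(protocol)

  v0 <- steps[[1]]$voltage
  Q0 <- markov_Q(model, params, v0)
  x0 <- markov_steady_state(Q0)
  if (is.null(x0)) return(sim_failure(nt))
  dQ0 <- markov_dQ(model, params, v0)
  A <- rbind(Q0[-n, , drop = FALSE], rep(1, n))
  S0 <- matrix(0, n, np)
  for (k in seq_len(np)) {
    b <- c(-(dQ0[[k]] %*% x0)[-n], 0)
    s <- tryCatch(solve(A, b), error = function(e) NULL)
    if (is.null(s)) return(sim_failure(nt))
    S0[, k] <- s
  }

  y <- c(x0, as.vector(S0))
  states <- matrix(NA_real_, n, nt)
  sens_states <- array(NA_real_, c(n, np, nt))
  v_out <- numeric(nt)

  for (stp in steps) {
    V <- stp$voltage
    Q <- markov_Q(model, params, V)
    dQ <- markov_dQ(model, params, V)
    rhs <- function(t, y, parms) {
      x <- y[1:n]
      S <- matrix(y[-(1:n)], n, np)
      dS <- Q %*% S
      for (k in seq_len(np)) dS[, k] <- dS[, k] + dQ[[k]] %*% x
      list(c(Q %*% x, as.vector(dS)))
    }
    tout <- sort(unique(c(0, stp$t_local, stp$duration)))
    sol <- tryCatch(
      deSolve::lsoda(y, tout, rhs, parms = NULL,
                     rtol = settings$rel_tol, atol = settings$abs_tol),
      warning = function(w) NULL, error = function(e) NULL)
    if (is.null(sol) || nrow(sol) < length(tout) ||
        any(!is.finite(sol))) {
      return(sim_failure(nt, "ODE integration failed"))
    }
    if (length(stp$t_local)) {
      idx <- match(stp$t_local, tout)
      for (j in seq_along(idx)) {
        row <- sol[idx[j], -1]
        states[, stp$which[j]] <- row[1:n]
        sens_states[, , stp$which[j]] <- matrix(row[-(1:n)], n, np)
      }
      v_out[stp$which] <- V
    }
    y <- sol[nrow(sol), -1]
  }

  gcond <- model$gfun(params, v_out)
  drive <- v_out - model$e_rev
  xo <- states[model$open_state, ]
  current <- gcond * xo * drive
  sens <- matrix(0, nt, np)
  for (k in seq_len(np)) {
    sens[, k] <- gcond * sens_states[model$open_state, k, ] * drive
  }
  # conductance parameter dependence, per distinct step voltage
  for (V in unique(v_out)) {
    sel <- v_out == V
    dg <- fun_grad_p(model$gfun, params, V)
    sens[sel, ] <- sens[sel, ] +
      outer(xo[sel] * drive[sel], dg)
  }
  if (any(!is.finite(current)) || any(!is.finite(sens))) {
    return(sim_failure(nt))
  }
  list(time = st, current = current, states = states, sensitivities = sens)
}
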