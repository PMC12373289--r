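#' Hodgkin-Huxley channel models
#'
#' A Hodgkin-Huxley model expresses the open probability of a channel as a
#' product of independent gating variables, each obeying
#' `dx/dt = (x_inf(V) - x) / tau(V)`, raised to small integer exponents,
#' optionally multiplied by instantaneous (algebraic) gates. The observed
#' current is `I = g(V) * prod(gates) * (V - E_rev)`.
#'
#' A gate is specified either through forward/backward transition rates
#' (`alpha` towards open, `beta` towards closed), giving
#' `x_inf = alpha/(alpha+beta)` and `tau = 1/(alpha+beta)`, or directly
#' through steady-state and time-constant functions of `(params, V)`.
#'
#' @param alpha,beta [rate_expr()] objects (rate-pair form).
#' @param ss_fun,tau_fun Functions `(params, V) -> scalar` (direct form).
#' @param exponent Positive integer exponent of the gate.
#' @return `hh_gate()` returns an object of class `hh_gate`.
#' @export
hh_gate <- function(alpha = NULL, beta = NULL, ss_fun = NULL, tau_fun = NULL,
                    exponent = 1L) {
  rate_form <- !is.null(alpha)
  if (rate_form) {
    stopifnot(inherits(alpha, "rate_expr"), inherits(beta, "rate_expr"))
  } else {
    stopifnot(is.function(ss_fun), is.function(tau_fun))
  }
  stopifnot(exponent >= 1)
  structure(list(alpha = alpha, beta = beta, ss_fun = ss_fun,
                 tau_fun = tau_fun, exponent = as.integer(exponent),
                 rate_form = rate_form),
            class = "hh_gate")
}

#' @rdname hh_gate
#' @param gates List of `hh_gate` objects (dynamic gates).
#' @param instant List of functions `(params, V) -> open fraction` applied
#'   instantaneously (no dynamics), e.g. inward rectification.
#' @param gfun Conductance as `function(params, V)`, mS. Voltage-dependent
#'   conductances are allowed.
#' @param e_rev Reversal potential, mV.
#' @param rates List of [rate_expr()] used for rate-bound checks; defaults
#'   to the alpha/beta rates of all rate-form gates.
#' @export
hh_model <- function(gates, instant = list(), gfun, e_rev, rates = NULL) {
  stopifnot(length(gates) >= 1, is.function(gfun))
  if (is.null(rates)) {
    rates <- unlist(lapply(gates, function(g) {
      if (g$rate_form) list(g$alpha, g$beta) else list()
    }), recursive = FALSE)
  }
  structure(list(gates = gates, instant = instant, gfun = gfun,
                 e_rev = e_rev, rates = rates),
            class = c("hh_model", "channel_model"))
}

# steady state / time constant of a gate at fixed voltage
gate_ss_tau <- function(gate, params, V) {
  if (gate$rate_form) {
    a <- rate_value(gate$alpha, params, V)
    b <- rate_value(gate$beta, params, V)
    list(ss = a / (a + b), tau = 1 / (a + b))
  } else {
    list(ss = gate$ss_fun(params, V), tau = gate$tau_fun(params, V))
  }
}

# d(ss)/dp and d(tau)/dp at fixed voltage
gate_ss_tau_grad <- function(gate, params, V) {
  if (gate$rate_form) {
    a <- rate_value(gate$alpha, params, V)
    b <- rate_value(gate$beta, params, V)
    da <- rate_grad(gate$alpha, params, V)
    db <- rate_grad(gate$beta, params, V)
    s <- a + b
    list(dss = (da * b - a * db) / s^2, dtau = -(da + db) / s^2)
  } else {
    np <- length(params)
    dss <- numeric(np); dtau <- numeric(np)
    for (i in seq_len(np)) {
      h <- 1e-6 * max(abs(params[i]), 1)
      pp <- params; pp[i] <- pp[i] + h
      pm <- params; pm[i] <- pm[i] - h
      dss[i] <- (gate$ss_fun(pp, V) - gate$ss_fun(pm, V)) / (2 * h)
      dtau[i] <- (gate$tau_fun(pp, V) - gate$tau_fun(pm, V)) / (2 * h)
    }
    list(dss = dss, dtau = dtau)
  }
}

# numeric gradient of a scalar function (params, V) -> value
fun_grad_p <- function(f, params, V) {
  np <- length(params)
  g <- numeric(np)
  for (i in seq_len(np)) {
    h <- 1e-6 * max(abs(params[i]), 1)
    pp <- params; pp[i] <- pp[i] + h
    pm <- params; pm[i] <- pm[i] - h
    g[i] <- (f(pp, V) - f(pm, V)) / (2 * h)
  }
  g
}

# Simulation failure is a signalled state, not an error: optimisers must be
# able to rank failed evaluations, so the cost layer maps this to a large
# finite cost.
sim_failure <- function(n_failed, reason = "non-finite model output") {
  structure(list(n_failed = n_failed, reason = reason), class = "sim_failure")
}

#' Did a forward solve fail?
#' @param x Result of a solver call.
#' @return Logical.
#' @export
is_sim_failure <- function(x) inherits(x, "sim_failure")

#' Analytic per-step solution of a Hodgkin-Huxley model
#'
#' Within each constant-voltage step every gate follows the closed form
#' `x(t) = x_inf - (x_inf - x0) exp(-t/tau)` exactly; gate values are
#' continuous across step boundaries. Gates are initialised at their steady
#' state for the first step's voltage (holding potential).
#'
#' @param model An [hh_model()].
#' @param protocol A [voltage_protocol()].
#' @param params Model parameter vector.
#' @param with_sensitivities If `TRUE`, also return the matrix of partial
#'   derivatives of the current with respect to each parameter, obtained by
#'   differentiating the per-step closed form (exact up to the accuracy of
#'   the per-step `x_inf`/`tau` parameter derivatives).
#' @return A list with `time` (ms), `current` (same length), and, when
#'   requested, `sensitivities` (times x parameters matrix); or a
#'   simulation-failure signal (see [is_sim_failure()]).
#' @export
solve_hh_analytic <- function(model, protocol, params,
                              with_sensitivities = FALSE) {
  st <- protocol_sampling_times(protocol)
  nt <- length(st)
  np <- length(params)
  steps <- protocol_step_table(protocol)
  ngate <- length(model$gates)

  v0 <- steps[[1]]$voltage
  x <- vapply(model$gates, function(g) gate_ss_tau(g, params, v0)$ss, 0)
  if (any(!is.finite(x))) return(sim_failure(nt))
  S <- if (with_sensitivities) {
    lapply(seq_len(ngate), function(i) {
      gr <- gate_ss_tau_grad(model$gates[[i]], params, v0)
      gr$dss  # steady-state initialisation: s0 = d(x_inf)/dp at V0
    })
  } else NULL

  gate_vals <- matrix(NA_real_, nt, ngate)
  gate_sens <- if (with_sensitivities) {
    lapply(seq_len(ngate), function(i) matrix(NA_real_, nt, np))
  } else NULL
  v_out <- numeric(nt)

  for (stp in steps) {
    V <- stp$voltage
    tl <- stp$t_local
    for (gi in seq_len(ngate)) {
      g <- model$gates[[gi]]
      sstau <- gate_ss_tau(g, params, V)
      ss <- sstau$ss; tau <- sstau$tau
      if (!is.finite(ss) || !is.finite(tau) || tau <= 0) {
        return(sim_failure(nt))
      }
      decay_end <- exp(-stp$duration / tau)
      if (length(tl)) {
        dec <- exp(-tl / tau)
        gate_vals[stp$which, gi] <- ss + (x[gi] - ss) * dec
      }
      if (with_sensitivities) {
        gr <- gate_ss_tau_grad(g, params, V)
        s0 <- S[[gi]]
        if (length(tl)) {
          dec <- exp(-tl / tau)
          # d/dp of x(t) = ss + (x0 - ss) e^{-t/tau}
          gate_sens[[gi]][stp$which, ] <-
            outer(1 - dec, gr$dss) + outer(dec, s0) +
            (x[gi] - ss) * outer(dec * tl / tau^2, gr$dtau)
        }
        S[[gi]] <- gr$dss + (s0 - gr$dss) * decay_end +
          (x[gi] - ss) * decay_end * (stp$duration / tau^2) * gr$dtau
      }
      x[gi] <- ss + (x[gi] - ss) * decay_end
    }
    if (length(tl)) v_out[stp$which] <- V
  }

  expo <- vapply(model$gates, function(g) g$exponent, 0L)
  open_dyn <- Reduce(`*`, lapply(seq_len(ngate),
                                 function(i) gate_vals[, i]^expo[i]))
  inst_vals <- lapply(model$instant, function(f) f(params, v_out))
  open_inst <- if (length(inst_vals)) Reduce(`*`, inst_vals) else rep(1, nt)
  gcond <- model$gfun(params, v_out)
  current <- gcond * open_dyn * open_inst * (v_out - model$e_rev)
  if (any(!is.finite(current))) {
    return(sim_failure(sum(!is.finite(current))))
  }
  out <- list(time = st, current = current)

  if (with_sensitivities) {
    sens <- matrix(0, nt, np)
    drive <- v_out - model$e_rev
    for (gi in seq_len(ngate)) {
      others <- Reduce(`*`, c(list(rep(1, nt)),
        lapply(setdiff(seq_len(ngate), gi),
               function(j) gate_vals[, j]^expo[j])))
      pref <- gcond * open_inst * drive * others *
        expo[gi] * gate_vals[, gi]^(expo[gi] - 1L)
      sens <- sens + pref * gate_sens[[gi]]
    }
    # conductance and instantaneous-gate parameter dependence (per distinct
    # step voltage; functions of params at fixed V)
    vs <- unique(v_out)
    dG <- matrix(0, nt, np)
    dInst <- matrix(0, nt, np)
    for (V in vs) {
      sel <- v_out == V
      dG[sel, ] <- matrix(fun_grad_p(model$gfun, params, V),
                          sum(sel), np, byrow = TRUE)
      if (length(model$instant)) {
        di <- numeric(np)
        fv <- vapply(model$instant, function(f) f(params, V), 0)
        for (ii in seq_along(model$instant)) {
          gi2 <- fun_grad_p(model$instant[[ii]], params, V)
          di <- di + gi2 * prod(fv[-ii])
        }
        dInst[sel, ] <- matrix(di, sum(sel), np, byrow = TRUE)
      }
    }
    sens <- sens + (open_dyn * open_inst * drive) * dG +
      (gcond * open_dyn * drive) * dInst
    if (any(!is.finite(sens))) return(sim_failure(nt))
    out$sensitivities <- sens
  }
  out
}
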