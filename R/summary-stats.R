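#' Summary-statistic curves for fast sodium-channel Markov models
#'
#' Computes the four voltage-clamp summary curves used by the
#' summary-statistic benchmark problem, each from a standard two-pulse or
#' step protocol family:
#'
#' * steady-state activation: normalised peak open occupancy during a test
#'   pulse from hyperpolarised rest, across test voltages;
#' * steady-state inactivation (availability): normalised peak current at a
#'   fixed test pulse after equilibration at a range of prepulse voltages;
#' * recovery from inactivation: ratio of the peak responses of two
#'   identical depolarising pulses separated by a recovery interval at the
#'   holding potential, across interval lengths;
#' * time to 50% decay: time from the peak of the test-pulse current until
#'   it first falls to half the peak, across test voltages.
#'
#' All protocols initialise at the stationary distribution of the holding
#' potential, so the curves are exact functionals of the model and
#' parameters (no protocol-length truncation error at the resting state).
#'
#' @param model A [markov_model()].
#' @param params Parameter vector.
#' @param holding_mV Holding potential (default -120 mV).
#' @param dt Sampling interval during test pulses, ms.
#' @return A tibble with columns `curve`, `x`, `value`; steady-state and
#'   recovery values lie in \[0, 1\], decay times are positive (ms). On
#'   simulation failure, a failure signal (see [is_sim_failure()]).
#' @export
compute_summary_statistics <- function(model, params, holding_mV = -120,
                                       dt = 0.05) {
  ssa_v <- seq(-60, 20, by = 10)
  ssi_v <- seq(-120, -40, by = 10)
  rfi_dt <- c(1, 3, 10, 30, 100, 300, 1000)
  dec_v <- seq(-20, 20, by = 10)
  test_v <- -10
  pulse_ms <- 25

  hold_ss <- function(V) {
    Q <- markov_Q(model, params, V)
    if (any(!is.finite(Q))) return(NULL)
    markov_steady_state(Q)
  }
  pulse_open <- function(x0, V, dur = pulse_ms) {
    prot <- voltage_protocol(
      tibble::tibble(duration_ms = dur, voltage_mV = V), dt = dt)
    sol <- solve_markov_analytic(model, prot, params, x0 = x0)
    if (is_sim_failure(sol)) return(sol)
    list(time = sol$time, open = sol$states[model$open_state, ])
  }

  x_hold <- hold_ss(holding_mV)
  if (is.null(x_hold)) return(sim_failure(1))

  # steady-state activation: peak open occupancy vs test voltage
  ssa <- numeric(length(ssa_v))
  for (i in seq_along(ssa_v)) {
    po <- pulse_open(x_hold, ssa_v[i])
    if (is_sim_failure(po)) return(po)
    ssa[i] <- max(po$open)
  }
  if (max(ssa) <= 0) return(sim_failure(1, "no activation"))
  ssa <- ssa / max(ssa)

  # steady-state inactivation: availability after prepulse equilibration
  ssi <- numeric(length(ssi_v))
  for (i in seq_along(ssi_v)) {
    x0 <- hold_ss(ssi_v[i])
    if (is.null(x0)) return(sim_failure(1))
    po <- pulse_open(x0, test_v)
    if (is_sim_failure(po)) return(po)
    ssi[i] <- max(po$open)
  }
  if (max(ssi) <= 0) return(sim_failure(1, "no availability"))
  ssi <- ssi / max(ssi)

  # recovery from inactivation: paired-pulse peak ratio vs interval
  p1 <- pulse_open(x_hold, test_v)
  if (is_sim_failure(p1)) return(p1)
  peak1 <- max(p1$open)
  if (peak1 <= 0) return(sim_failure(1, "no first-pulse response"))
  # state at the end of the first pulse
  end1 <- solve_markov_analytic(
    model,
    voltage_protocol(tibble::tibble(duration_ms = pulse_ms,
                                    voltage_mV = test_v),
                     sampling_times = pulse_ms),
    params, x0 = x_hold)
  if (is_sim_failure(end1)) return(end1)
  x_end1 <- end1$states[, 1]
  rfi <- numeric(length(rfi_dt))
  for (i in seq_along(rfi_dt)) {
    rec <- solve_markov_analytic(
      model,
      voltage_protocol(tibble::tibble(duration_ms = rfi_dt[i],
                                      voltage_mV = holding_mV),
                       sampling_times = rfi_dt[i]),
      params, x0 = x_end1)
    if (is_sim_failure(rec)) return(rec)
    p2 <- pulse_open(rec$states[, 1], test_v)
    if (is_sim_failure(p2)) return(p2)
    rfi[i] <- max(p2$open) / peak1
  }

  # time to 50% decay of the test-pulse current after its peak
  t50 <- numeric(length(dec_v))
  for (i in seq_along(dec_v)) {
    po <- pulse_open(x_hold, dec_v[i], dur = 50)
    if (is_sim_failure(po)) return(po)
    k <- which.max(po$open)
    pk <- po$open[k]
    if (pk <= 0) return(sim_failure(1, "no decay peak"))
    after <- which(po$open[seq(k, length(po$open))] <= pk / 2)
    if (!length(after)) return(sim_failure(1, "no 50% decay within pulse"))
    t50[i] <- po$time[k + after[1] - 1L] - po$time[k]
  }

  tibble::tibble(
    curve = rep(c("activation", "inactivation", "recovery", "decay_t50"),
                c(length(ssa_v), length(ssi_v), length(rfi_dt),
                  length(dec_v))),
    x = c(ssa_v, ssi_v, rfi_dt, dec_v),
    value = c(ssa, ssi, rfi, t50)
  )
}
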