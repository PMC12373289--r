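#' Voltage-dependent transition rates
#'
#' Transition rates (units ms^-1) between channel states or gate
#' configurations. The two common parametric forms are `A * exp(b * V)`
#' (`"pos_exp"`) and `A * exp(-b * V)` (`"neg_exp"`), with `A >= 0` in
#' ms^-1 and `b >= 0` in mV^-1; `"constant"` rates are voltage independent;
#' `"general"` rates are arbitrary functions of `(params, V)`.
#'
#' For the exponential kinds, `a_index` / `b_index` give the positions of
#' `A` and `b` in the problem's parameter vector, so that rate bounds can be
#' evaluated for any proposed parameters.
#'
#' @param kind One of `"pos_exp"`, `"neg_exp"`, `"constant"`, `"general"`.
#' @param a_index,b_index Parameter indices for `A` and `b` (exp kinds);
#'   `a_index` alone for `"constant"`.
#' @param fun For `"general"`: `function(params, V)` returning the rate,
#'   vectorised over `V`.
#' @param lb,ub Bounds on the maximum of the rate over the physiological
#'   voltage range, used when rate bounds are enabled. Defaults correspond
#'   to timescales between 1 minute and 1 microsecond.
#' @param label Optional name for reporting.
#' @return An object of class `rate_expr`.
#' @seealso [max_rate()], [rate_bounds_from_timescales()]
#' @export
rate_expr <- function(kind = c("pos_exp", "neg_exp", "constant", "general"),
                      a_index = NULL, b_index = NULL, fun = NULL,
                      lb = 1.67e-5, ub = 1e3, label = NULL) {
  kind <- match.arg(kind)
  if (kind %in% c("pos_exp", "neg_exp")) {
    stopifnot(is.numeric(a_index), is.numeric(b_index))
  } else if (kind == "constant") {
    stopifnot(is.numeric(a_index))
  } else {
    stopifnot(is.function(fun))
  }
  structure(list(kind = kind, a_index = a_index, b_index = b_index,
                 fun = fun, lb = lb, ub = ub, label = label),
            class = "rate_expr")
}

#' Evaluate a rate expression
#'
#' @param rate A [rate_expr()].
#' @param params Model parameter vector.
#' @param V Voltage(s), mV.
#' @return Rate value(s), ms^-1.
#' @export
rate_value <- function(rate, params, V) {
  switch(rate$kind,
    pos_exp = params[rate$a_index] * exp(params[rate$b_index] * V),
    neg_exp = params[rate$a_index] * exp(-params[rate$b_index] * V),
    constant = rep(params[rate$a_index], length(V)),
    general = rate$fun(params, V)
  )
}

#' Maximum transition rate over the physiological voltage range
#'
#' The maximum of a transition rate over V in \[-120, 60\] mV. For the
#' monotone exponential kinds this is the analytic endpoint value
#' (`A exp(60 b)` for `A exp(bV)`; `A exp(120 b)` for `A exp(-bV)` when
#' `b >= 0`); `"constant"` rates return `A`; `"general"` rates are maximised
#' on a 181-point 1 mV grid.
#'
#' @inheritParams rate_value
#' @param v_range Voltage range searched, mV.
#' @return The maximum rate, ms^-1.
#' @export
max_rate <- function(rate, params, v_range = c(-120, 60)) {
  unname(switch(rate$kind,
    pos_exp = ,
    neg_exp = {
      A <- params[rate$a_index]
      b <- params[rate$b_index]
      # sign of b decides which endpoint wins; covers b < 0 proposals too
      v <- if (rate$kind == "pos_exp") {
        if (b >= 0) v_range[2] else v_range[1]
      } else {
        if (b >= 0) v_range[1] else v_range[2]
      }
      rate_value(rate, params, v)
    },
    constant = params[rate$a_index],
    general = max(rate$fun(params, seq(v_range[1], v_range[2], by = 1)))
  ))
}

#' Rate bounds implied by timescale limits
#'
#' Converts timescale limits on channel transitions into bounds on the
#' maximum transition rate: a slowest allowed timescale (default 1 minute)
#' gives the lower rate bound and a fastest allowed timescale (default
#' 1 microsecond) the upper rate bound.
#'
#' @param slowest_ms Slowest allowed timescale, ms (default one minute).
#' @param fastest_ms Fastest allowed timescale, ms (default one microsecond).
#' @return Named numeric vector with elements `lb` and `ub`, ms^-1.
#' @examples
#' rate_bounds_from_timescales()  # c(lb = 1.67e-5, ub = 1e3)
#' @export
rate_bounds_from_timescales <- function(slowest_ms = 60e3, fastest_ms = 1e-3) {
  c(lb = 1 / slowest_ms, ub = 1 / fastest_ms)
}

# d(rate)/d(params) at a single voltage; analytic for parametric kinds,
# central differences for general rates.
rate_grad <- function(rate, params, V) {
  g <- numeric(length(params))
  switch(rate$kind,
    pos_exp = {
      A <- params[rate$a_index]; b <- params[rate$b_index]
      g[rate$a_index] <- exp(b * V)
      g[rate$b_index] <- A * V * exp(b * V)
    },
    neg_exp = {
      A <- params[rate$a_index]; b <- params[rate$b_index]
      g[rate$a_index] <- exp(-b * V)
      g[rate$b_index] <- -A * V * exp(-b * V)
    },
    constant = {
      g[rate$a_index] <- 1
    },
    general = {
      for (i in seq_along(params)) {
        h <- 1e-6 * max(abs(params[i]), 1)
        pp <- params; pp[i] <- pp[i] + h
        pm <- params; pm[i] <- pm[i] - h
        g[i] <- (rate$fun(pp, V) - rate$fun(pm, V)) / (2 * h)
      }
    }
  )
  g
}
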