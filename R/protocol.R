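#' Voltage-clamp step protocols
#'
#' A voltage protocol is an ordered table of piecewise-constant voltage
#' steps, plus the times at which the simulated current is sampled. All
#' durations and times are in milliseconds, voltages in millivolts.
#'
#' @param steps A data frame (or tibble) with columns `duration_ms`
#'   (strictly positive) and `voltage_mV`, one row per step, in order.
#' @param sampling_times Strictly increasing numeric vector of times (ms) at
#'   which the current is reported. Must not exceed the total protocol
#'   duration. Defaults to a uniform grid `seq(dt, total, by = dt)`.
#' @param dt Sampling interval (ms) used when `sampling_times` is missing.
#'
#' @return An object of class `voltage_protocol`: a tibble of steps with
#'   attributes `sampling_times` and `total_ms`.
#' @examples
#' p <- voltage_protocol(data.frame(duration_ms = c(100, 400),
#'                                  voltage_mV  = c(-80, 20)))
#' protocol_voltage_at(p, c(50, 150))
#' @export
voltage_protocol <- function(steps, sampling_times = NULL, dt = 1) {
  steps <- tibble::as_tibble(steps)
  stopifnot(all(c("duration_ms", "voltage_mV") %in% names(steps)),
            nrow(steps) >= 1L)
  if (any(!is.finite(steps$duration_ms)) || any(steps$duration_ms <= 0)) {
    stop("step durations must be strictly positive and finite", call. = FALSE)
  }
  total <- sum(steps$duration_ms)
  if (is.null(sampling_times)) {
    sampling_times <- seq(dt, total, by = dt)
  }
  sampling_times <- as.numeric(sampling_times)
  if (length(sampling_times) == 0 || any(diff(sampling_times) <= 0)) {
    stop("sampling_times must be non-empty and strictly increasing",
         call. = FALSE)
  }
  if (max(sampling_times) > total + 1e-9) {
    stop("sampling_times exceed the total protocol duration", call. = FALSE)
  }
  structure(steps,
            sampling_times = sampling_times,
            total_ms = total,
            class = c("voltage_protocol", class(steps)))
}

#' @rdname voltage_protocol
#' @param protocol A `voltage_protocol`.
#' @export
protocol_sampling_times <- function(protocol) attr(protocol, "sampling_times")

#' @rdname voltage_protocol
#' @export
protocol_total_ms <- function(protocol) attr(protocol, "total_ms")

#' @rdname voltage_protocol
#' @param times Numeric vector of times (ms).
#' @export
protocol_voltage_at <- function(protocol, times) {
  ends <- cumsum(protocol$duration_ms)
  idx <- findInterval(times, c(0, ends[-length(ends)]), left.open = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(protocol)] <- nrow(protocol)
  protocol$voltage_mV[idx]
}

# Step boundaries and, for each step, the sampling times falling inside
# (t0, t1]. Times are returned relative to the start of the step.
protocol_step_table <- function(protocol) {
  ends <- cumsum(protocol$duration_ms)
  starts <- c(0, ends[-length(ends)])
  st <- protocol_sampling_times(protocol)
  idx <- findInterval(st, starts, left.open = FALSE)
  idx[idx > nrow(protocol)] <- nrow(protocol)
  lapply(seq_len(nrow(protocol)), function(k) {
    sel <- idx == k
    list(voltage = protocol$voltage_mV[k],
         duration = protocol$duration_ms[k],
         t_local = st[sel] - starts[k],
         which = which(sel))
  })
}

#' Read / write a protocol as CSV
#'
#' The CSV has columns `duration_ms` and `voltage_mV`; sampling times are an
#' optional third column `sampling_time_ms` (padded with `NA`), otherwise a
#' uniform `dt` grid is used on read.
#'
#' @param path File path.
#' @inheritParams voltage_protocol
#' @return `read_protocol_csv()` returns a `voltage_protocol`;
#'   `write_protocol_csv()` returns `path` invisibly.
#' @export
read_protocol_csv <- function(path, dt = 1) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  st <- NULL
  if ("sampling_time_ms" %in% names(df)) {
    st <- df$sampling_time_ms[!is.na(df$sampling_time_ms)]
    if (length(st) == 0) st <- NULL
  }
  steps <- df[!is.na(df$duration_ms), c("duration_ms", "voltage_mV")]
  voltage_protocol(steps, sampling_times = st, dt = dt)
}

#' @rdname read_protocol_csv
#' @param protocol A `voltage_protocol`.
#' @export
write_protocol_csv <- function(protocol, path) {
  st <- protocol_sampling_times(protocol)
  n <- max(nrow(protocol), length(st))
  pad <- function(x) c(x, rep(NA, n - length(x)))
  readr::write_csv(tibble::tibble(
    duration_ms = pad(protocol$duration_ms),
    voltage_mV = pad(protocol$voltage_mV),
    sampling_time_ms = pad(st)
  ), path)
  invisible(path)
}

#' @exportS3Method ggplot2::autoplot
autoplot.voltage_protocol <- function(object, ...) {
  ends <- cumsum(object$duration_ms)
  starts <- c(0, ends[-length(ends)])
  df <- tibble::tibble(
    t = as.vector(rbind(starts, ends)),
    v = rep(object$voltage_mV, each = 2)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$v)) +
    ggplot2::geom_path() +
    ggplot2::labs(x = "Time (ms)", y = "Voltage (mV)")
}
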