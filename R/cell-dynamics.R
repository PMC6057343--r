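#' Advance a cell state by one forward-Euler step
#'
#' Integrates the two-variable quadratic model one step of length `dt`. The
#' voltage equation may optionally be integrated in several equal substeps
#' (the network simulator uses two substeps of `dt/2`, a standard stability
#' measure for this model family); the recovery equation always takes a
#' single step of `dt`. After the update, if `v` has reached `v_peak` the
#' event rule is applied: `event_flag` is set, `v` is reset to `c` and `u`
#' is incremented by `d`, so the returned voltage is always strictly below
#' `v_peak`.
#'
#' @param state a [cell_state()].
#' @param params a [cell_params()].
#' @param I_ext external input current for this step.
#' @param dt step duration (> 0).
#' @param v_substeps number of Euler substeps for the voltage equation
#'   (default 1, i.e. a plain Euler step).
#' @return The advanced `cell_state`.
#' @examples
#' s <- step_cell(cell_state(-60, 0), neuron_params(), I_ext = 100, dt = 1)
#' s$v  # -59: one Euler step of the quadratic model
#' @export
step_cell <- function(state, params, I_ext, dt = 1, v_substeps = 1L) {
  if (!inherits(state, "cell_state")) stop("state must be a cell_state")
  if (!inherits(params, "cell_params")) stop("params must be cell_params")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  if (state$v >= params$v_peak)
    stop("state voltage must be below v_peak before a step")
  v <- state$v
  u <- state$u
  h <- dt / v_substeps
  for (s in seq_len(v_substeps)) {
    v <- v + h * (params$k * (v - params$v_r) * (v - params$v_t) - u + I_ext) /
      params$C
  }
  u <- u + dt * params$a * (params$b * (v - params$v_r) - u)
  if (!is.finite(v) || !is.finite(u))
    stop(sprintf(
      "non-finite state after step (dt = %g, I_ext = %g): integration blew up",
      dt, I_ext))
  if (v >= params$v_peak) {
    cell_state(v = params$c, u = u + params$d, event_flag = TRUE)
  } else {
    cell_state(v = v, u = u, event_flag = FALSE)
  }
}

#' Simulate a cell under a constant-current injection protocol
#'
#' Integrates a single cell from rest with a square current pulse: `I` is
#' applied on `[t_on, t_off)` and zero elsewhere. This is the protocol used
#' to validate the astrocyte parameter set: with `I = 4` applied from step
#' 100 to step 1000 the astrocyte produces no release events, matching the
#' behaviour of biological astrocytes under the same stimulation, whereas
#' much stronger currents do eventually drive it over threshold.
#'
#' The recorded voltage at an event step is capped at `v_peak` (the
#' conventional way spike traces are drawn) while the internal state follows
#' the reset rule.
#'
#' @inheritParams step_cell
#' @param I current amplitude during the pulse.
#' @param t_on,t_off pulse onset and offset times, `0 <= t_on <= t_off <=
#'   duration`.
#' @param duration total simulated time.
#' @param v_substeps Euler substeps for the voltage equation (default 2, as
#'   in the network simulator).
#' @return A list of class `cell_trace` with elements `time`, `v` (recorded
#'   voltage trace), `event_times`, `n_events`, and the inputs echoed back.
#' @examples
#' tr <- simulate_constant_current(astrocyte_params(), I = 4,
#'                                 t_on = 100, t_off = 1000, duration = 1000)
#' tr$n_events  # 0: the astrocyte stays silent under this protocol
#' @export
simulate_constant_current <- function(params, I, t_on = 100, t_off = 1000,
                                      duration = 1000, dt = 1,
                                      v_substeps = 2L) {
  if (!inherits(params, "cell_params")) stop("params must be cell_params")
  if (!(t_on >= 0 && t_on <= t_off && t_off <= duration))
    stop("need 0 <= t_on <= t_off <= duration")
  n <- as.integer(round(duration / dt))
  time <- (seq_len(n) - 1L) * dt
  I_vec <- ifelse(time >= t_on & time < t_off, I, 0)
  out <- simulate_cell_cpp(unlist(params[c("C", "v_r", "v_t", "k", "a", "b",
                                           "c", "d", "v_peak")]),
                           I_vec, dt, as.integer(v_substeps))
  structure(list(time = time, v = out$v,
                 event_times = out$event_times,
                 n_events = length(out$event_times),
                 params = params, I = I, t_on = t_on, t_off = t_off,
                 duration = duration, dt = dt),
            class = "cell_trace")
}

#' @export
print.cell_trace <- function(x, ...) {
  cat(sprintf(
    "Constant-current trace: I = %g on [%g, %g), %g steps of dt = %g\n",
    x$I, x$t_on, x$t_off, length(x$time), x$dt))
  cat(sprintf("  events: %d;  final v: %.4f\n", x$n_events, tail(x$v, 1)))
  invisible(x)
}

#' @export
plot.cell_trace <- function(x, ...) {
  graphics::plot(x$time, x$v, type = "l", xlab = "time (steps)",
                 ylab = "v", ...)
  if (x$n_events > 0)
    graphics::points(x$event_times, rep(x$params$v_peak, x$n_events),
                     pch = 3)
  invisible(x)
}
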