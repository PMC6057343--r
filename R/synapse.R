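#' Alpha-function transmission kernel
#'
#' Signal propagation along every pathway in the model -- synaptic
#' neurotransmitter, astrocytic IP3, potassium and glial glutamate -- is an
#' alpha function of the time elapsed since the source cell reached
#' `v_peak`:
#' \deqn{f(t) = (t/\lambda)\, e^{(\lambda - t)/\lambda},}
#' which rises from 0, peaks at exactly 1 when \eqn{t = \lambda}, and decays
#' with time constant \eqn{\lambda}. Larger \eqn{\lambda} means slower,
#' longer-lasting transmission: synaptic lines use \eqn{\lambda = 125},
#' the potassium pathway \eqn{\lambda = 100}, and the slow astrocytic
#' glutamate and IP3 pathways \eqn{\lambda = 1000}.
#'
#' @param t time elapsed since the release event, `t >= 0` (vectorised).
#' @param lam the kernel time constant \eqn{\lambda > 0}.
#' @return Kernel value(s), nonnegative, equal to 1 at `t = lam`.
#' @examples
#' alpha_value(125, lam = 125)       # 1
#' alpha_value(250, lam = 125)       # 2 * exp(-1)
#' @export
alpha_value <- function(t, lam) {
  if (any(lam <= 0)) stop("lam must be > 0")
  if (any(t < 0)) stop("negative elapsed time: caller bug")
  (t / lam) * exp((lam - t) / lam)
}

#' Transmission lines: event-driven alpha-kernel superposition
#'
#' A transmission line records the times at which its source cell reached
#' `v_peak` and reports, at any time `t`, the superposition of one alpha
#' kernel per recorded event. If a new event occurs while earlier kernels
#' are still decaying, its kernel is simply added -- transmission is linear.
#' Kernels older than `cutoff * lam` are ignored when evaluating the output;
#' at the default cutoff of 10 the neglected tail is below 1.3e-3 of the
#' kernel peak.
#'
#' @param lam kernel time constant \eqn{\lambda}.
#' @param pathway optional label, one of `"synaptic"`, `"IP3"`, `"K+"`,
#'   `"glutamate"` or `""`.
#' @param cutoff kernels older than `cutoff * lam` are dropped from the
#'   output sum; `Inf` disables the cutoff.
#' @return `transmission_line()` returns an object of class
#'   `transmission_line` with no events.
#' @examples
#' line <- transmission_line(lam = 125)
#' line <- add_event(line, 0)
#' line <- add_event(line, 50)
#' line_output(line, 100)  # alpha_value(100, 125) + alpha_value(50, 125)
#' @export
transmission_line <- function(lam, pathway = "", cutoff = 10) {
  if (!is.numeric(lam) || length(lam) != 1L || lam <= 0)
    stop("lam must be a single positive number")
  if (!pathway %in% c("", "synaptic", "IP3", "K+", "glutamate"))
    stop("unknown pathway label: ", pathway)
  structure(list(lam = lam, pathway = pathway, cutoff = cutoff,
                 event_times = numeric(0)),
            class = "transmission_line")
}

#' @rdname transmission_line
#' @param line a `transmission_line`.
#' @param t event time; events must arrive in nondecreasing order.
#' @return `add_event()` returns the line with the event appended.
#' @export
add_event <- function(line, t) {
  if (!inherits(line, "transmission_line")) stop("not a transmission_line")
  n <- length(line$event_times)
  if (n > 0L && t < line$event_times[n])
    stop("out-of-order event time: ", t, " < ", line$event_times[n])
  line$event_times <- c(line$event_times, t)
  line
}

#' @rdname transmission_line
#' @return `line_output()` returns the summed kernel amplitude at time `t`
#'   (vectorised over `t`); zero when no event has occurred at or before `t`.
#' @export
line_output <- function(line, t) {
  if (!inherits(line, "transmission_line")) stop("not a transmission_line")
  vapply(t, function(tt) {
    dt <- tt - line$event_times
    dt <- dt[dt > 0 & dt <= line$cutoff * line$lam]
    if (length(dt) == 0L) return(0)
    sum(alpha_value(dt, line$lam))
  }, numeric(1))
}

#' Accumulated line output over a time window
#'
#' Left-Riemann sum of [line_output()] over `[t0, t1)` with step `dt`. This
#' is the integrated presynaptic signal consumed by the learning rule (its
#' `I_K` input). For a single kernel the exact integral over `[0, Inf)` is
#' \eqn{\lambda e}.
#'
#' @param line a [transmission_line()].
#' @param t0,t1 integration window, `t0 <= t1`.
#' @param dt Riemann step.
#' @return The accumulated signal (nonnegative).
#' @export
integrated_output <- function(line, t0, t1, dt = 1) {
  if (t0 > t1) stop("need t0 <= t1")
  if (t0 == t1) return(0)
  ts <- seq(t0, t1 - dt / 2, by = dt)
  sum(line_output(line, ts)) * dt
}
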