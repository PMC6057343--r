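#' Cell parameter sets for the two-variable quadratic spiking model
#'
#' The simulator expresses every cell -- neuron or astrocyte -- in the
#' Izhikevich simple-model form
#' \deqn{C \dot v = k (v - v_r)(v - v_t) - u + I, \qquad
#'       \dot u = a (b (v - v_r) - u),}
#' with a hard reset: when \eqn{v \ge v_{peak}} the cell emits an event and
#' \eqn{v \leftarrow c}, \eqn{u \leftarrow u + d}. For a neuron the event is
#' an action potential; for an astrocyte it is interpreted as a glutamate
#' release event (astrocytes do not spike under physiological currents, and
#' the threshold is only reachable under strong drive).
#'
#' `neuron_params()` returns the cortical pyramidal (regular spiking)
#' parameter set. `astrocyte_params()` returns a parameter set optimised so
#' that the steady-state current-voltage relation of the same equations is
#' approximately linear, the defining electrophysiological signature of
#' astrocytes. Astrocyte parameter values are scale-free: they do not carry
#' the membrane-capacitance etc. interpretation the symbols have for neurons,
#' and `v` abstractly tracks intracellular calcium rather than sodium-driven
#' membrane potential.
#'
#' @param C positive scale on the voltage equation (capacitance-like).
#' @param v_r resting potential: the voltage at which both the quadratic term
#'   and the recovery drive vanish.
#' @param v_t instantaneous threshold parameter of the quadratic term.
#' @param k gain of the quadratic voltage term.
#' @param a recovery time constant (rate at which `u` tracks its target).
#' @param b coupling from voltage to the recovery target `b * (v - v_r)`.
#' @param c reset potential applied after an event.
#' @param d increment added to `u` after an event.
#' @param v_peak event threshold: crossing it triggers the reset rule.
#' @return An object of class `cell_params`: a named list of the nine
#'   constants.
#' @examples
#' neuron_params()
#' astrocyte_params()
#' cell_params(C = 50, v_r = -65, v_t = -45, k = 1, a = 0.02, b = 0.2,
#'             c = -65, d = 8, v_peak = 30)
#' @export
cell_params <- function(C, v_r, v_t, k, a, b, c, d, v_peak) {
  p <- list(C = C, v_r = v_r, v_t = v_t, k = k, a = a, b = b,
            c = c, d = d, v_peak = v_peak)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("cell parameter '", nm, "' must be a single finite number",
           call. = FALSE)
  }
  if (p$C <= 0) stop("C must be > 0", call. = FALSE)
  if (p$a <= 0) stop("a must be > 0", call. = FALSE)
  if (p$v_r >= p$v_peak) stop("v_r must be below v_peak", call. = FALSE)
  structure(p, class = "cell_params")
}

#' @rdname cell_params
#' @export
neuron_params <- function() {
  cell_params(C = 100, v_r = -60, v_t = -40, k = 0.7,
              a = 0.03, b = -2, c = -50, d = 100, v_peak = 35)
}

#' @rdname cell_params
#' @export
astrocyte_params <- function() {
  cell_params(C = 6, v_r = -70, v_t = 1429.164, k = 2.77e-5,
              a = 0.03, b = -6.5e-4, c = -50, d = 100, v_peak = 35)
}

#' @export
print.cell_params <- function(x, ...) {
  cat("Two-variable quadratic cell model parameters\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Instantaneous state of one cell
#'
#' @param v membrane potential (calcium-like variable for astrocytes).
#' @param u recovery current.
#' @param event_flag whether the cell crossed `v_peak` on the last step.
#' @return An object of class `cell_state`.
#' @seealso [step_cell()]
#' @export
cell_state <- function(v, u = 0, event_flag = FALSE) {
  stopifnot(is.numeric(v), length(v) == 1L, is.numeric(u), length(u) == 1L)
  structure(list(v = v, u = u, event_flag = isTRUE(event_flag)),
            class = "cell_state")
}

#' Resting state for a parameter set
#'
#' @param params a [cell_params()] object.
#' @return A `cell_state` at `v = v_r`, `u = 0`, which is a fixed point of
#'   the dynamics at zero input.
#' @export
rest_state <- function(params) cell_state(v = params$v_r, u = 0)
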