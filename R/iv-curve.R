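#' Steady-state current-voltage (I-V) curve of a cell model
#'
#' Setting both time derivatives of the two-variable model to zero gives the
#' closed-form steady-state input current required to hold the membrane at
#' voltage `v`:
#' \deqn{I_{ss}(v) = (v - v_r)\,[\,b - k (v - v_t)\,].}
#' For the neuron parameter set this curve is the familiar N-shaped quadratic;
#' for the astrocyte parameter set it is approximately linear over the whole
#' physiological range, which is the property the astrocyte parameters were
#' fitted to reproduce.
#'
#' @param params a [cell_params()] object.
#' @param v_grid strictly increasing voltages, all below `v_peak`.
#' @return An `iv_curve`: a data.frame with columns `voltage` and `current`.
#' @examples
#' iv <- steady_state_iv(astrocyte_params(), seq(-200, 30, by = 1))
#' linearity_r2(iv)  # >= 0.99
#' @export
steady_state_iv <- function(params, v_grid) {
  if (!inherits(params, "cell_params")) stop("params must be cell_params")
  if (!is.numeric(v_grid) || length(v_grid) < 1L || anyNA(v_grid))
    stop("v_grid must be numeric and non-missing")
  if (is.unsorted(v_grid, strictly = TRUE))
    stop("v_grid must be strictly increasing")
  if (any(v_grid >= params$v_peak))
    stop("all grid voltages must lie below v_peak")
  I <- (v_grid - params$v_r) * (params$b - params$k * (v_grid - params$v_t))
  iv_curve(v_grid, I)
}

#' Construct an I-V curve container
#'
#' @param voltage strictly increasing membrane potentials.
#' @param current matching steady-state input currents.
#' @return A data.frame of class `iv_curve`.
#' @export
iv_curve <- function(voltage, current) {
  if (length(voltage) != length(current))
    stop("voltage and current must have equal length")
  if (is.unsorted(voltage, strictly = TRUE))
    stop("voltages must be strictly increasing")
  structure(data.frame(voltage = voltage, current = current),
            class = c("iv_curve", "data.frame"))
}

#' Coefficient of determination of a linear fit to an I-V curve
#'
#' Fits current on voltage by ordinary least squares and returns r-squared.
#' An astrocyte steady-state curve is nearly perfectly linear (r^2 >= 0.99
#' over voltages in \[-200, 30\]); a neuron curve, being N-shaped, is
#' materially less so.
#'
#' @param curve an [iv_curve()] with at least 3 points.
#' @return r-squared in \[0, 1\].
#' @export
linearity_r2 <- function(curve) {
  if (!inherits(curve, "iv_curve")) stop("curve must be an iv_curve")
  if (nrow(curve) < 3L) stop("need at least 3 points")
  if (stats::var(curve$current) == 0 || stats::var(curve$voltage) == 0)
    stop("degenerate (constant) curve: r^2 undefined")
  # for a simple OLS regression, r^2 is the squared correlation
  stats::cor(curve$voltage, curve$current)^2
}

#' Read / write an I-V curve as two-column delimited text
#'
#' The on-disk format is tab-separated text with a one-line header
#' `voltage<TAB>current`.
#'
#' @param curve an [iv_curve()].
#' @param path file path.
#' @return `write_iv_curve()` returns `path` invisibly; `read_iv_curve()`
#'   returns an `iv_curve`.
#' @export
write_iv_curve <- function(curve, path) {
  if (!inherits(curve, "iv_curve")) stop("curve must be an iv_curve")
  utils::write.table(as.data.frame(curve), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_iv_curve
#' @export
read_iv_curve <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("voltage", "current") %in% names(df)))
    stop("expected columns 'voltage' and 'current' in ", path)
  iv_curve(df$voltage, df$current)
}
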