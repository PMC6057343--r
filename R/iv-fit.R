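#' Fit cell-model parameters to a target I-V curve by least squares
#'
#' Estimates parameters of the two-variable quadratic cell model whose
#' steady-state current-voltage relation best matches a target curve, by
#' minimising the mean squared error between \eqn{I_{ss}(v)} and the target
#' currents on the target voltages. This is the procedure used to derive the
#' astrocyte parameter set from a measured (linear) glial I-V relation.
#'
#' Only `k`, `b` and `v_t` shape the steady-state curve (`C` and `a` set
#' timescales and drop out of the steady state, and `c`, `d`, `v_peak` only
#' govern the reset), so those three are the default free set. `v_r` is
#' pinned to the target's zero-current voltage (found by linear
#' interpolation) because the steady-state current vanishes identically at
#' `v = v_r`. The search is a derivative-free Nelder-Mead simplex; `b` and
#' `k * v_t` trade off along a near-flat valley, so the meaningful result of
#' the fit is the curve, not the raw parameter vector -- compare fits with
#' [predict.iv_fit()] or `fitted()`, not `coef()`.
#'
#' @param target an [iv_curve()] with at least as many points as free
#'   parameters plus one.
#' @param free character vector naming the free parameters, a non-empty
#'   subset of `c("k", "b", "v_t")`.
#' @param init a [cell_params()] giving starting values (and the values of
#'   all pinned parameters). Default: the astrocyte preset.
#' @param control passed to [stats::optim()]; `maxit` defaults to 2000 and
#'   `reltol` to 1e-12.
#' @return An object of class `iv_fit` with components `params` (the fitted
#'   `cell_params`), `free`, `mse`, `mse_init`, `convergence` (0 means the
#'   simplex converged), `target` and `fitted`.
#' @examples
#' target <- steady_state_iv(astrocyte_params(), seq(-200, 30, by = 5))
#' fit <- fit_iv_params(target)
#' fit$mse  # ~ 0: self-consistent recovery
#' @export
fit_iv_params <- function(target, free = c("k", "b", "v_t"),
                          init = astrocyte_params(), control = list()) {
  if (!inherits(target, "iv_curve")) stop("target must be an iv_curve")
  if (!all(is.finite(target$voltage)) || !all(is.finite(target$current)))
    stop("target curve must be finite")
  allowed <- c("k", "b", "v_t")
  if (length(free) == 0L || !all(free %in% allowed))
    stop("free must be a non-empty subset of ",
         paste(allowed, collapse = ", "))
  if (nrow(target) < length(free) + 1L)
    stop("target is underdetermined: need more points than free parameters")
  if (diff(range(target$voltage)) == 0)
    stop("target has zero voltage span")
  if (!inherits(init, "cell_params")) stop("init must be cell_params")

  params <- init
  params$v_r <- .zero_current_voltage(target, fallback = init$v_r)

  iss <- function(p, v) (v - p$v_r) * (p$b - p$k * (v - p$v_t))
  objective <- function(theta) {
    p <- params
    p[free] <- as.list(theta)
    mean((iss(p, target$voltage) - target$current)^2)
  }
  mse_init <- objective(unlist(params[free]))
  ctrl <- utils::modifyList(list(maxit = 2000, reltol = 1e-12), control)
  # parscale keeps the simplex steps commensurate with parameter magnitudes
  if (is.null(ctrl$parscale))
    ctrl$parscale <- pmax(abs(unlist(params[free])), 1e-6)
  opt <- stats::optim(unlist(params[free]), objective,
                      method = "Nelder-Mead", control = ctrl)
  if (opt$value > mse_init) {  # never report worse than the start
    opt$par <- unlist(params[free])
    opt$value <- mse_init
  }
  params[free] <- as.list(opt$par)
  structure(list(params = params, free = free, mse = opt$value,
                 mse_init = mse_init, convergence = opt$convergence,
                 target = target,
                 fitted = iss(params, target$voltage)),
            class = "iv_fit")
}

# Voltage at which the target current crosses zero, by linear interpolation;
# falls back when the target never changes sign.
.zero_current_voltage <- function(target, fallback) {
  s <- sign(target$current)
  idx <- which(s[-1] * s[-length(s)] <= 0)
  if (length(idx) == 0L) return(fallback)
  i <- idx[1]
  v1 <- target$voltage[i]; v2 <- target$voltage[i + 1]
  c1 <- target$current[i]; c2 <- target$current[i + 1]
  if (c2 == c1) return(v1)
  v1 - c1 * (v2 - v1) / (c2 - c1)
}

#' @export
print.iv_fit <- function(x, ...) {
  cat("Steady-state I-V parameter fit (Nelder-Mead, mean squared error)\n")
  cat("  free parameters:", paste(x$free, collapse = ", "), "\n")
  cat(sprintf("  MSE: %.6g (initial %.6g)%s\n", x$mse, x$mse_init,
              if (x$convergence != 0) "  [optimizer did not converge]"
              else ""))
  print(unlist(x$params[c("v_r", x$free)]))
  invisible(x)
}

#' @export
coef.iv_fit <- function(object, ...) unlist(object$params[object$free])

#' @export
fitted.iv_fit <- function(object, ...) object$fitted

#' @export
residuals.iv_fit <- function(object, ...) object$target$current - object$fitted

#' Predict steady-state currents from a fitted I-V model
#'
#' @param object an `iv_fit`.
#' @param voltage voltages at which to evaluate the fitted steady-state
#'   curve; defaults to the target's voltages.
#' @param ... unused.
#' @return Numeric vector of currents.
#' @export
predict.iv_fit <- function(object, voltage = object$target$voltage, ...) {
  p <- object$params
  (voltage - p$v_r) * (p$b - p$k * (voltage - p$v_t))
}
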