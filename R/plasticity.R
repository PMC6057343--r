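#' Reinforcement-learning constants
#'
#' Bundles the constants of the dopamine-modulated three-factor learning
#' rule. Defaults are the values used for the classification experiments:
#'
#' * `alpha_w = 5e-10` -- LTP rate (strong pre, strong post, dopamine above
#'   baseline).
#' * `beta_w = 2e-10` -- LTD rate for a dopamine dip (strong pre and post,
#'   dopamine below baseline).
#' * `gamma_w = 5e-13` -- LTD rate for weak postsynaptic activation
#'   (between the AMPA and NMDA thresholds).
#' * `theta_nmda = 500`, `theta_ampa = 150` -- postsynaptic activation
#'   thresholds for NMDA and AMPA receptor engagement; the rule requires
#'   `theta_nmda > theta_ampa`, and weights are frozen entirely when
#'   activation is below `theta_ampa`.
#' * `w_max = 2000` -- maximum synaptic strength (the LTP term carries a
#'   soft bound `w_max - w`; updates are additionally clipped to
#'   `[0, w_max]`).
#' * `eta = 0.075` -- learning rate of the predicted-reward tracker.
#' * `d_base = 0.2` -- baseline dopamine level, chosen as the release-level
#'   at zero reward-prediction error so that dopamine above/below baseline
#'   coincides with positive/negative RPE.
#'
#' @param alpha_w,beta_w,gamma_w nonnegative learning rates.
#' @param theta_nmda,theta_ampa activation thresholds,
#'   `theta_nmda > theta_ampa`.
#' @param w_max maximum weight, > 0.
#' @param eta predicted-reward learning rate.
#' @param d_base baseline dopamine in \[0, 1\].
#' @return An object of class `learning_params`.
#' @export
learning_params <- function(alpha_w = 5e-10, beta_w = 2e-10,
                            gamma_w = 5e-13, theta_nmda = 500,
                            theta_ampa = 150, w_max = 2000,
                            eta = 0.075, d_base = 0.2) {
  p <- list(alpha_w = alpha_w, beta_w = beta_w, gamma_w = gamma_w,
            theta_nmda = theta_nmda, theta_ampa = theta_ampa,
            w_max = w_max, eta = eta, d_base = d_base)
  if (any(vapply(p, function(x) !is.numeric(x) || length(x) != 1L ||
                   !is.finite(x), logical(1))))
    stop("all learning parameters must be single finite numbers")
  if (alpha_w < 0 || beta_w < 0 || gamma_w < 0 || eta < 0)
    stop("rates must be >= 0")
  if (w_max <= 0) stop("w_max must be > 0")
  if (theta_nmda <= theta_ampa)
    stop("theta_nmda must exceed theta_ampa")
  if (d_base < 0 || d_base > 1) stop("d_base must be in [0, 1]")
  structure(p, class = "learning_params")
}

#' @export
print.learning_params <- function(x, ...) {
  cat("Dopamine-modulated reinforcement learning constants\n")
  print(unlist(x), ...)
  invisible(x)
}

#' Half-wave rectification
#'
#' `[x]+`: returns 0 for negative values and the value itself otherwise.
#' Every gating factor of the learning rule passes through this.
#'
#' @param x numeric (vectorised).
#' @return `pmax(x, 0)`.
#' @export
rectify <- function(x) pmax(x, 0)

#' Three-factor dopamine-gated weight update
#'
#' Updates synaptic strength(s) from integrated presynaptic drive `I_K`,
#' integrated positive postsynaptic voltage `S_J`, and the trial's dopamine
#' level `D`:
#' \deqn{\Delta w = \alpha_w I_K [S_J - \theta_{NMDA}]^+ [D - D_{base}]^+
#'   (w_{max} - w) - \beta_w I_K [S_J - \theta_{NMDA}]^+ [D_{base} - D]^+ w
#'   - \gamma_w I_K [\theta_{NMDA} - S_J]^+ [S_J - \theta_{AMPA}]^+ w.}
#' Because `theta_nmda > theta_ampa`, at most one of the three terms is
#' active for any `(S_J, D)` pair: LTP when the postsynaptic cell was
#' strongly active and dopamine rose above baseline, dopamine-dip LTD when
#' it was strongly active but dopamine dipped, and slow LTD when activation
#' fell between the two receptor thresholds. Below `theta_ampa` the weight
#' is untouched. The result is clipped to `[0, w_max]`.
#'
#' Arguments are vectorised with the usual recycling, so a whole column of a
#' weight matrix can be updated in one call.
#'
#' @param w current weight(s) in `[0, w_max]`.
#' @param I_K integrated presynaptic line output(s), >= 0.
#' @param S_J integrated positive postsynaptic voltage(s), >= 0.
#' @param D dopamine level in \[0, 1\].
#' @param p a [learning_params()].
#' @return Updated weight(s), in `[0, w_max]`.
#' @export
update_weight <- function(w, I_K, S_J, D, p = learning_params()) {
  if (!inherits(p, "learning_params")) stop("p must be learning_params")
  if (any(w < 0) || any(w > p$w_max)) stop("w must be in [0, w_max]")
  if (any(I_K < 0) || any(S_J < 0)) stop("I_K and S_J must be >= 0")
  if (any(D < 0) || any(D > 1)) stop("D must be in [0, 1]")
  dw <- p$alpha_w * I_K * rectify(S_J - p$theta_nmda) *
          rectify(D - p$d_base) * (p$w_max - w) -
        p$beta_w * I_K * rectify(S_J - p$theta_nmda) *
          rectify(p$d_base - D) * w -
        p$gamma_w * I_K * rectify(p$theta_nmda - S_J) *
          rectify(S_J - p$theta_ampa) * w
  pmin(pmax(w + dw, 0), p$w_max)
}

#' Phasic dopamine release as a function of reward-prediction error
#'
#' Piecewise-linear, continuous, nondecreasing map from RPE to a dopamine
#' level in \[0, 1\]: saturated at 1 for RPE > 1, zero (a full dip) for
#' RPE < -0.25, and `0.8 * RPE + 0.2` in between. At zero prediction error
#' the release is the 0.2 baseline.
#'
#' @param RPE reward-prediction error(s) (vectorised).
#' @return Dopamine level(s) in \[0, 1\].
#' @export
dopamine <- function(RPE) {
  ifelse(RPE > 1, 1,
         ifelse(RPE < -0.25, 0, 0.8 * RPE + 0.2))
}

#' Reward-prediction error
#'
#' @param R obtained reward.
#' @param P predicted reward.
#' @return `R - P`.
#' @export
rpe <- function(R, P) R - P

#' Reward from a trial outcome
#'
#' @param outcome one of `"correct"` (+1), `"incorrect"` (-1), `"absent"`
#'   (0, no feedback).
#' @return The scalar reward.
#' @export
reward <- function(outcome = c("correct", "incorrect", "absent")) {
  switch(match.arg(outcome), correct = 1, incorrect = -1, absent = 0)
}

#' Predicted-reward tracker
#'
#' Exponentially-weighted running estimate of reward:
#' `P <- P + eta * (R - P)`. Under a constant reward it converges
#' geometrically with ratio `1 - eta`; with rewards in `[-1, 1]` and `P`
#' started there, `P` stays in `[-1, 1]`.
#'
#' @param state a `reward_state` as returned by `reward_state()`.
#' @param R the reward obtained on this trial.
#' @param eta learning rate in \[0, 1\].
#' @return The advanced `reward_state` (trial index incremented).
#' @export
update_predicted_reward <- function(state, R, eta = 0.075) {
  if (!inherits(state, "reward_state")) stop("state must be a reward_state")
  if (eta < 0 || eta > 1) stop("eta must be in [0, 1]")
  reward_state(P = state$P + eta * (R - state$P), n = state$n + 1L)
}

#' @rdname update_predicted_reward
#' @param P predicted reward.
#' @param n trial index.
#' @export
reward_state <- function(P = 0, n = 0L) {
  structure(list(P = P, n = as.integer(n)), class = "reward_state")
}
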