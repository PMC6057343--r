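#' Configuration of a learning session
#'
#' Bundles every constant of a classification session: the architecture,
#' trial protocol, noise level, learning constants, cell presets, stimulus
#' encoding and the master seed. The task is fixed by the geometry: the
#' first half of the input grid belongs to category 1 and the second half
#' to category 2, and the network must learn the mapping by reinforcement.
#'
#' @param architecture `"bipartite"` or `"tripartite"`.
#' @param n_trials number of trials in the session.
#' @param block_size trials per accuracy block; `final accuracy` is the
#'   mean correctness over the last block.
#' @param noise_sd per-step Gaussian voltage noise on neurons (the
#'   experiments use 0, 0.65, 0.85 and 1.25).
#' @param seed master seed; spawns independent child streams for the
#'   initial weights, the stimulus sequence and the per-trial simulation,
#'   so sessions differing only in noise level share stimuli and weights.
#' @param n_pre,n_post layer sizes.
#' @param duration,stim_on,stim_off,dt,v_substeps trial integration
#'   protocol: the stimulus is on during `[stim_on, stim_off)` (~900 steps,
#'   mirroring the single-cell validation protocol) and the trial runs on
#'   for one full glutamate kernel length past stimulus offset, so the slow
#'   astrocytic pathways can express before the trial ends.
#' @param fixed_weight gain of the non-plastic astrocyte-pathway
#'   connections.
#' @param init_weight_range uniform draw bounds for the initial plastic
#'   weights (see [build_network()]).
#' @param neuron,astrocyte,learning,encoding model constants.
#' @return An object of class `session_config`.
#' @export
session_config <- function(architecture = c("bipartite", "tripartite"),
                           n_trials = 500L, block_size = 50L,
                           noise_sd = 0, seed = 1L,
                           n_pre = 10L, n_post = 2L,
                           duration = 2000, stim_on = 100, stim_off = 1100,
                           dt = 1, v_substeps = 2L, fixed_weight = 0.71,
                           init_weight_range = c(10, 40),
                           neuron = neuron_params(),
                           astrocyte = astrocyte_params(),
                           learning = learning_params(),
                           encoding = stimulus_encoding()) {
  architecture <- match.arg(architecture)
  if (!(n_trials >= block_size && block_size >= 1L))
    stop("need n_trials >= block_size >= 1")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (length(encoding$coordinates) != n_pre)
    stop("encoding must have one coordinate per presynaptic neuron")
  structure(list(architecture = architecture,
                 n_trials = as.integer(n_trials),
                 block_size = as.integer(block_size),
                 noise_sd = noise_sd, seed = as.integer(seed),
                 n_pre = as.integer(n_pre), n_post = as.integer(n_post),
                 duration = duration, stim_on = stim_on,
                 stim_off = stim_off, dt = dt,
                 v_substeps = as.integer(v_substeps),
                 fixed_weight = fixed_weight,
                 init_weight_range = init_weight_range,
                 neuron = neuron, astrocyte = astrocyte,
                 learning = learning, encoding = encoding),
            class = "session_config")
}

#' @export
print.session_config <- function(x, ...) {
  cat(sprintf(
    "Session config: %s, %d trials (blocks of %d), noise sd %g, seed %d\n",
    x$architecture, x$n_trials, x$block_size, x$noise_sd, x$seed))
  invisible(x)
}

#' Run one reinforcement-learning classification session
#'
#' Executes `n_trials` trials. On each trial one input location is selected
#' uniformly at random, encoded through the Gaussian receptive fields and
#' presented to the network; the winner-take-all response is compared with
#' the category rule (first half of the grid maps to postsynaptic neuron 1,
#' second half to neuron 2); reward +1/-1 drives the reward-prediction
#' error, phasic dopamine and the predicted-reward tracker; and all plastic
#' weights are updated by the three-factor dopamine-gated rule using the
#' trial's `I_K` and `S_J`.
#'
#' Membrane variables and transmission lines are reset between trials;
#' trials are independent stimulus presentations except for the weights and
#' the predicted reward, which carry the learning.
#'
#' @param cfg a [session_config()].
#' @return An object of class `astro_session`: per-trial records
#'   (data.frame `trials` with stimulus, target, winner, correctness, R,
#'   RPE, D, P), the blocked `accuracy_curve`, `final_accuracy` (mean over
#'   the last block), initial/final weights and per-block weight snapshots.
#' @examples
#' \donttest{
#' res <- run_session(session_config("tripartite", n_trials = 100,
#'                                   block_size = 20, seed = 1))
#' res$final_accuracy
#' }
#' @export
run_session <- function(cfg) {
  if (!inherits(cfg, "session_config")) stop("cfg must be a session_config")
  seeds <- derive_child_seeds(cfg$seed, 3L)
  weight_stream <- rng_stream(seeds[1])
  stim_stream <- rng_stream(seeds[2])
  trial_stream <- rng_stream(seeds[3])

  net <- stream_eval(weight_stream, function()
    build_network(cfg$architecture, seed = NULL, n_pre = cfg$n_pre,
                  n_post = cfg$n_post, fixed_weight = cfg$fixed_weight,
                  init_weight_range = cfg$init_weight_range,
                  neuron = cfg$neuron, astrocyte = cfg$astrocyte,
                  learning = cfg$learning))
  stim_seq <- stream_eval(stim_stream, function()
    sample.int(cfg$n_pre, cfg$n_trials, replace = TRUE))

  weights_init <- net$weights
  p <- cfg$learning
  P <- 0                     # predicted reward starts neutral
  half <- cfg$n_pre / 2
  n_blocks <- cfg$n_trials %/% cfg$block_size
  snapshots <- vector("list", n_blocks)

  trials <- data.frame(trial = seq_len(cfg$n_trials), stimulus = stim_seq,
                       target = NA_integer_, winner = NA_integer_,
                       correct = NA, R = NA_real_, RPE = NA_real_,
                       D = NA_real_, P = NA_real_)
  for (n in seq_len(cfg$n_trials)) {
    loc <- stim_seq[n]
    amps <- encode_stimulus(cfg$encoding, loc)
    tr <- tryCatch(
      stream_eval(trial_stream, function()
        simulate_trial(net, amps, noise_sd = cfg$noise_sd,
                       duration = cfg$duration, dt = cfg$dt,
                       stim_on = cfg$stim_on, stim_off = cfg$stim_off,
                       v_substeps = cfg$v_substeps)),
      error = function(e) stop("trial ", n, " failed: ", conditionMessage(e),
                               call. = FALSE))
    target <- if (loc <= half) 1L else 2L
    correct <- tr$winner == target
    R <- reward(if (correct) "correct" else "incorrect")
    RPE <- rpe(R, P)
    D <- dopamine(RPE)
    P <- P + p$eta * (R - P)
    for (j in seq_len(cfg$n_post))
      net$weights[, j] <- update_weight(net$weights[, j], tr$I_K,
                                        tr$S_J[j], D, p)
    trials[n, c("target", "winner", "correct", "R", "RPE", "D", "P")] <-
      list(target, tr$winner, correct, R, RPE, D, P)
    if (n %% cfg$block_size == 0L)
      snapshots[[n %/% cfg$block_size]] <- net$weights
  }

  curve <- blocked_accuracy(trials$correct, cfg$block_size)
  structure(list(config = cfg, trials = trials,
                 accuracy_curve = curve,
                 final_accuracy = curve[length(curve)],
                 weights_init = weights_init,
                 weights_final = net$weights,
                 weight_snapshots = snapshots),
            class = "astro_session")
}

#' Blocked accuracy curve
#'
#' Mean correctness per consecutive block of trials. When `block_size`
#' divides the number of trials, the mean of the curve equals the overall
#' accuracy exactly.
#'
#' @param correct logical vector of per-trial correctness.
#' @param block_size trials per block.
#' @return Numeric vector of block accuracies.
#' @export
blocked_accuracy <- function(correct, block_size) {
  n_blocks <- length(correct) %/% block_size
  vapply(seq_len(n_blocks), function(b)
    mean(correct[((b - 1) * block_size + 1):(b * block_size)]),
    numeric(1))
}

#' @export
print.astro_session <- function(x, ...) {
  cat(sprintf("%s session: %d trials, noise sd %g, seed %d\n",
              x$config$architecture, x$config$n_trials, x$config$noise_sd,
              x$config$seed))
  cat(sprintf("  final-block accuracy: %.3f (first block %.3f)\n",
              x$final_accuracy, x$accuracy_curve[1]))
  invisible(x)
}

#' @export
summary.astro_session <- function(object, ...) {
  cat(sprintf("%s network, %d trials (blocks of %d), noise sd %g, seed %d\n",
              object$config$architecture, object$config$n_trials,
              object$config$block_size, object$config$noise_sd,
              object$config$seed))
  cat("block accuracies:\n")
  print(round(object$accuracy_curve, 3))
  cat(sprintf("overall accuracy %.3f; final-block accuracy %.3f\n",
              mean(object$trials$correct), object$final_accuracy))
  cat(sprintf("predicted reward at session end: %.3f\n",
              object$trials$P[nrow(object$trials)]))
  invisible(object)
}

#' @export
plot.astro_session <- function(x, ...) {
  b <- seq_along(x$accuracy_curve) * x$config$block_size
  graphics::plot(b, x$accuracy_curve, type = "b", ylim = c(0, 1),
                 xlab = "trial", ylab = "block accuracy",
                 main = sprintf("%s network (noise sd %g)",
                                x$config$architecture, x$config$noise_sd),
                 ...)
  graphics::abline(h = 0.5, lty = 3)
  invisible(x)
}
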