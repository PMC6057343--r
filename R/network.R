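#' Gaussian receptive-field stimulus encoding
#'
#' Input neurons sit at fixed coordinates on a one-dimensional grid (5, 15,
#' ..., 95 by default). On each trial one location is selected and a current
#' of `peak_amplitude` is injected through a Gaussian filter centred there:
#' neuron `i` receives
#' `peak_amplitude * exp(-(c_i - c_sel)^2 / (2 * filter_sd^2))`, so the
#' selected neuron receives the full amplitude and its neighbours
#' progressively less.
#'
#' @param coordinates strictly increasing, evenly spaced grid positions.
#' @param filter_sd standard deviation of the Gaussian filter.
#' @param peak_amplitude current injected at the selected location.
#' @return An object of class `stimulus_encoding`.
#' @export
stimulus_encoding <- function(coordinates = seq(5, 95, by = 10),
                              filter_sd = 30, peak_amplitude = 70) {
  if (length(coordinates) < 1L || is.unsorted(coordinates, strictly = TRUE))
    stop("coordinates must be strictly increasing")
  if (length(coordinates) > 2L &&
      stats::var(diff(coordinates)) > 1e-12)
    stop("coordinates must be evenly spaced")
  if (filter_sd <= 0) stop("filter_sd must be > 0")
  structure(list(coordinates = coordinates, filter_sd = filter_sd,
                 peak_amplitude = peak_amplitude),
            class = "stimulus_encoding")
}

#' @rdname stimulus_encoding
#' @param enc a `stimulus_encoding`.
#' @param selected_index index (1-based) of the selected grid location.
#' @return `encode_stimulus()` returns the per-neuron current amplitudes.
#' @export
encode_stimulus <- function(enc, selected_index) {
  if (!inherits(enc, "stimulus_encoding")) stop("enc must be a stimulus_encoding")
  n <- length(enc$coordinates)
  if (!selected_index %in% seq_len(n)) stop("invalid selected_index")
  d <- enc$coordinates - enc$coordinates[selected_index]
  enc$peak_amplitude * exp(-d^2 / (2 * enc$filter_sd^2))
}

#' Build a bipartite or tripartite network
#'
#' Assembles a fully connected feed-forward network of `n_pre` presynaptic
#' and `n_post` postsynaptic neurons with one plastic synapse per pair. In
#' the tripartite architecture each postsynaptic neuron additionally has one
#' astrocyte that receives IP3 lines from all presynaptic neurons and a K+
#' line from its own postsynaptic neuron, and feeds glutamate back into that
#' neuron's synapses; all astrocyte-pathway connections carry the fixed
#' (non-plastic) weight.
#'
#' Initial plastic weights are drawn uniformly from `init_weight_range`;
#' with the same `seed` the bipartite and tripartite variants get identical
#' weight matrices, which is what makes matched-architecture comparisons
#' meaningful. The default range places the initial postsynaptic drive in
#' the regime where the learning rule's activation thresholds discriminate
#' the winner from the loser (see the package vignette); weights then have
#' ample headroom below `w_max` for potentiation.
#'
#' @param architecture `"bipartite"` or `"tripartite"`.
#' @param seed integer seed for the initial weight draw (`NULL` uses the
#'   current RNG state).
#' @param n_pre,n_post presynaptic and postsynaptic neuron counts.
#' @param fixed_weight gain on all astrocyte-pathway connections.
#' @param neuron,astrocyte [cell_params()] presets.
#' @param learning a [learning_params()] (supplies `w_max`).
#' @param weights optional explicit `n_pre x n_post` initial weight matrix,
#'   overriding the random draw.
#' @param init_weight_range lower and upper bound of the uniform initial
#'   weight draw (absolute units, within `[0, w_max]`).
#' @param lambda named list of kernel time constants for the four pathways
#'   (`syn`, `ip3`, `k`, `glu`).
#' @return An object of class `network_spec`.
#' @examples
#' net <- build_network("tripartite", seed = 7)
#' dim(net$weights)  # 10 x 2
#' @export
build_network <- function(architecture = c("bipartite", "tripartite"),
                          seed = NULL, n_pre = 10L, n_post = 2L,
                          fixed_weight = 0.71,
                          neuron = neuron_params(),
                          astrocyte = astrocyte_params(),
                          learning = learning_params(),
                          weights = NULL,
                          init_weight_range = c(10, 40),
                          lambda = list(syn = 125, ip3 = 1000, k = 100,
                                        glu = 1000)) {
  architecture <- match.arg(architecture)
  stopifnot(n_pre >= 1L, n_post >= 1L)
  if (is.null(weights)) {
    draw <- function() matrix(stats::runif(n_pre * n_post,
                                           init_weight_range[1],
                                           init_weight_range[2]),
                              n_pre, n_post)
    weights <- if (is.null(seed)) draw() else with_preserved_seed(seed, draw)
  } else {
    weights <- as.matrix(weights)
    if (!all(dim(weights) == c(n_pre, n_post)))
      stop("weights must be an n_pre x n_post matrix")
  }
  if (any(weights < 0) || any(weights > learning$w_max))
    stop("weights must lie in [0, w_max]")
  structure(list(architecture = architecture, n_pre = as.integer(n_pre),
                 n_post = as.integer(n_post),
                 n_astro = if (architecture == "tripartite")
                   as.integer(n_post) else 0L,
                 weights = weights, fixed_weight = fixed_weight,
                 neuron = neuron, astrocyte = astrocyte,
                 learning = learning, lambda = lambda),
            class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("%s network: %d presynaptic, %d postsynaptic neurons, %d astrocyte(s)\n",
              x$architecture, x$n_pre, x$n_post, x$n_astro))
  cat(sprintf("  %d plastic synapses in [%.1f, %.1f]; fixed weight %.3g\n",
              length(x$weights), min(x$weights), max(x$weights),
              x$fixed_weight))
  invisible(x)
}

.cell_par_vec <- function(p)
  unlist(p[c("C", "v_r", "v_t", "k", "a", "b", "c", "d", "v_peak")])

#' Simulate a single network trial
#'
#' Runs the network for `duration` steps from rest (all membrane variables
#' at their resting values, all transmission lines empty), with the given
#' per-presynaptic-neuron stimulus currents applied during
#' `[stim_on, stim_off)`. Each step: presynaptic neurons integrate their
#' stimulus and their threshold events feed the synaptic (and, in
#' tripartite networks, IP3) lines; postsynaptic neurons integrate the
#' weighted synaptic drive plus any astrocytic glutamate entering their
#' synapses; astrocytes integrate the fixed-weight IP3 and K+ drive and
#' release glutamate on threshold events. Independent Gaussian perturbations
#' of standard deviation `noise_sd` are added to every neuron's (never an
#' astrocyte's) voltage at every step.
#'
#' The trial summary quantities consumed by the learning rule are `I_K`
#' (per-synapse integrated presynaptic line output) and `S_J` (per
#' postsynaptic neuron, the integral of its positive voltage). The winner
#' is the postsynaptic neuron with the largest `S_J`.
#'
#' @param net a [build_network()] spec.
#' @param stimulus per-presynaptic-neuron current amplitudes (e.g. from
#'   [encode_stimulus()]).
#' @param noise_sd standard deviation of the per-step voltage noise.
#' @param duration number of time steps in the trial.
#' @param dt integration step.
#' @param stim_on,stim_off stimulus window.
#' @param v_substeps Euler substeps for the voltage equation.
#' @param glu_in_cleft if `TRUE` (default) astrocytic glutamate enters the
#'   synaptic cleft of the astrocyte's synapses (and is therefore amplified
#'   by the plastic weights); if `FALSE` only the weak direct path to the
#'   postsynaptic membrane remains.
#' @param record if `TRUE`, full voltage traces and postsynaptic input
#'   currents are kept (for single-synapse style figures).
#' @return An object of class `trial_record`: a list with `stimulus`,
#'   `I_K`, `S_J`, `winner`, event-time vectors `pre_events`,
#'   `post_events`, `astro_events`, and (if `record`) trace matrices.
#' @export
simulate_trial <- function(net, stimulus, noise_sd = 0, duration = 1000,
                           dt = 1, stim_on = 100, stim_off = 1000,
                           v_substeps = 2L, glu_in_cleft = TRUE,
                           record = FALSE) {
  if (!inherits(net, "network_spec")) stop("net must be a network_spec")
  if (length(stimulus) != net$n_pre)
    stop("stimulus must have one amplitude per presynaptic neuron")
  if (duration <= 0) stop("duration must be > 0")
  out <- simulate_trial_cpp(.cell_par_vec(net$neuron),
                            .cell_par_vec(net$astrocyte),
                            net$weights, net$fixed_weight,
                            as.numeric(stimulus),
                            net$architecture == "tripartite",
                            noise_sd, as.integer(round(duration / dt)), dt,
                            as.integer(v_substeps), stim_on, stim_off,
                            net$lambda$syn, net$lambda$ip3, net$lambda$k,
                            net$lambda$glu, 10, glu_in_cleft, record)
  out$stimulus <- as.numeric(stimulus)
  out$winner <- decide_winner(out$S_J)
  out$noise_sd <- noise_sd
  out$dt <- dt
  class(out) <- "trial_record"
  out
}

#' Winner-take-all readout
#'
#' The response is the postsynaptic neuron with the greatest integrated
#' positive activation; exact ties are broken uniformly at random from the
#' current RNG stream.
#'
#' @param S per-postsynaptic activations (non-empty).
#' @return The winning index (1-based).
#' @export
decide_winner <- function(S) {
  if (length(S) == 0L) stop("S must be non-empty")
  idx <- which(S == max(S))
  if (length(idx) == 1L) idx else idx[sample.int(length(idx), 1L)]
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("Network trial: winner %d; S_J = %s\n", x$winner,
              paste(signif(x$S_J, 4), collapse = ", ")))
  cat(sprintf("  presynaptic events: %s\n",
              paste(vapply(x$pre_events, length, integer(1)),
                    collapse = ", ")))
  cat(sprintf("  postsynaptic events: %s\n",
              paste(vapply(x$post_events, length, integer(1)),
                    collapse = ", ")))
  invisible(x)
}

#' Matched single-synapse runs (one presynaptic, one postsynaptic neuron)
#'
#' Reproduces the single-synapse demonstration: a constant suprathreshold
#' current drives one presynaptic neuron for 1000 steps and the
#' postsynaptic response is compared between a bipartite synapse and a
#' tripartite synapse with one astrocyte. The run extends past the stimulus
#' offset so that the astrocytic prolongation of postsynaptic activity --
#' additional spikes after the regular, presynaptically driven spikes have
#' ended -- is observable.
#'
#' @param architecture `"bipartite"` or `"tripartite"`.
#' @param seed seed for the (single) initial weight draw.
#' @param I stimulus amplitude into the presynaptic neuron.
#' @param duration,stim_on,stim_off trial protocol.
#' @param ... passed to [build_network()].
#' @return A `trial_record` with traces recorded.
#' @export
simulate_single_synapse <- function(architecture = c("bipartite",
                                                     "tripartite"),
                                    seed = NULL, I = 70, duration = 2500,
                                    stim_on = 100, stim_off = 1100,
                                    init_weight_range = c(100, 400), ...) {
  architecture <- match.arg(architecture)
  # the default weight range is the network default scaled by the usual
  # presynaptic fan-in (10), so one synapse carries the drive that ten
  # convergent synapses share in the full network
  net <- build_network(architecture, seed = seed, n_pre = 1L, n_post = 1L,
                       init_weight_range = init_weight_range, ...)
  simulate_trial(net, stimulus = I, duration = duration, stim_on = stim_on,
                 stim_off = stim_off, record = TRUE)
}
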