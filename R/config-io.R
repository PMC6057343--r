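#' Read and write session configurations as structured text (YAML)
#'
#' A configuration file holds every constant of a session -- architecture,
#' trial protocol, noise level, seed, cell parameters, learning constants
#' and stimulus encoding -- so a run is fully reproducible from the file.
#' `read_config(write_config(cfg, path))` reproduces `cfg` exactly.
#' Missing required keys are an error naming the key; unknown keys produce
#' a warning (forward compatibility) and are ignored.
#'
#' @param cfg a [session_config()].
#' @param path file path of the YAML configuration.
#' @return `write_config()` returns `path` invisibly; `read_config()`
#'   returns a `session_config`.
#' @export
write_config <- function(cfg, path) {
  if (!inherits(cfg, "session_config")) stop("cfg must be a session_config")
  x <- unclass(cfg)
  x$neuron <- unclass(x$neuron)
  x$astrocyte <- unclass(x$astrocyte)
  x$learning <- unclass(x$learning)
  x$encoding <- unclass(x$encoding)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  required <- c("architecture", "n_trials", "block_size", "noise_sd",
                "seed", "n_pre", "n_post", "duration", "stim_on",
                "stim_off", "dt", "v_substeps", "fixed_weight",
                "init_weight_range", "neuron", "astrocyte", "learning",
                "encoding")
  missing <- setdiff(required, names(x))
  if (length(missing) > 0L)
    stop("config is missing required key(s): ",
         paste(missing, collapse = ", "))
  unknown <- setdiff(names(x), required)
  if (length(unknown) > 0L) {
    warning("ignoring unknown config key(s): ",
            paste(unknown, collapse = ", "))
    x <- x[required]
  }
  session_config(architecture = x$architecture, n_trials = x$n_trials,
                 block_size = x$block_size, noise_sd = x$noise_sd,
                 seed = x$seed, n_pre = x$n_pre, n_post = x$n_post,
                 duration = x$duration, stim_on = x$stim_on,
                 stim_off = x$stim_off, dt = x$dt,
                 v_substeps = x$v_substeps,
                 fixed_weight = x$fixed_weight,
                 init_weight_range = x$init_weight_range,
                 neuron = do.call(cell_params, x$neuron),
                 astrocyte = do.call(cell_params, x$astrocyte),
                 learning = do.call(learning_params, x$learning),
                 encoding = do.call(stimulus_encoding, x$encoding))
}

#' Persist session results as delimited tabular text
#'
#' `write_results()` writes the per-trial table of an [run_session()]
#' result as tab-separated text, one row per trial; `read_results()` reads
#' it back as a data.frame.
#'
#' @param result an `astro_session`.
#' @param path output file path.
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   the per-trial data.frame.
#' @export
write_results <- function(result, path) {
  if (!inherits(result, "astro_session"))
    stop("result must be an astro_session")
  utils::write.table(result$trials, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t")
}
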