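#' Matched bipartite-vs-tripartite comparison
#'
#' Runs the two architectures on identical conditions: for each seed, both
#' sessions see the same initial weights, the same stimulus sequence and
#' the same per-trial noise stream, differing only in whether astrocytes
#' and their pathways exist. This isolates the contribution of the
#' tripartite synapse itself.
#'
#' @param cfg a [session_config()]; its `architecture` field is overridden
#'   per run.
#' @param seeds master seeds, one matched session pair per seed.
#' @param cfg2 optional second config; if supplied it must differ from
#'   `cfg` in the `architecture` field only.
#' @return An object of class `astro_comparison`: the per-seed
#'   `final_accuracy` table, per-architecture accuracy curves (averaged
#'   over seeds) and the list of fitted sessions.
#' @export
run_matched_comparison <- function(cfg, seeds = cfg$seed, cfg2 = NULL) {
  if (!inherits(cfg, "session_config")) stop("cfg must be a session_config")
  if (is.null(cfg2)) {
    cfg2 <- cfg
    cfg2$architecture <- setdiff(c("bipartite", "tripartite"),
                                 cfg$architecture)
  } else {
    a <- cfg; a$architecture <- NULL
    b <- cfg2; b$architecture <- NULL
    if (!isTRUE(all.equal(a, b)))
      stop("configs may differ only in the architecture field")
  }
  run_arch <- function(base, seed) {
    base$seed <- as.integer(seed)
    run_session(base)
  }
  sessions <- lapply(seeds, function(s)
    list(a = run_arch(cfg, s), b = run_arch(cfg2, s)))
  tab <- do.call(rbind, lapply(seq_along(seeds), function(i) {
    data.frame(seed = seeds[i],
               architecture = c(cfg$architecture, cfg2$architecture),
               final_accuracy = c(sessions[[i]]$a$final_accuracy,
                                  sessions[[i]]$b$final_accuracy))
  }))
  curves <- lapply(stats::setNames(c("a", "b"),
                                   c(cfg$architecture, cfg2$architecture)),
                   function(k)
                     rowMeans(sapply(sessions, function(s)
                       s[[k]]$accuracy_curve)))
  structure(list(table = tab, curves = curves, sessions = sessions,
                 seeds = seeds),
            class = "astro_comparison")
}

#' @export
print.astro_comparison <- function(x, ...) {
  agg <- stats::aggregate(final_accuracy ~ architecture, x$table, mean)
  cat(sprintf("Matched comparison over %d seed(s)\n", length(x$seeds)))
  for (i in seq_len(nrow(agg)))
    cat(sprintf("  %-10s mean final accuracy %.3f\n",
                agg$architecture[i], agg$final_accuracy[i]))
  invisible(x)
}

#' Noise-robustness sweep over both architectures
#'
#' Repeats the matched comparison at each voltage-noise level. Because the
#' stimulus sequence and initial weights depend only on the master seed,
#' every (architecture, noise) cell of the design sees the same stimuli for
#' a given seed, so the sweep measures the effect of noise alone.
#'
#' @param cfg a [session_config()] serving as the base.
#' @param levels noise standard deviations to test.
#' @param seeds master seeds (replicates) per level.
#' @return An object of class `astro_sweep`: a data.frame `table` with one
#'   row per (architecture, level) holding mean and sd of final accuracy
#'   and the between-architecture gap, and the per-cell accuracy values.
#' @export
run_noise_sweep <- function(cfg, levels = c(0, 0.65, 0.85, 1.25),
                            seeds = 1:10) {
  if (length(levels) < 1L || length(seeds) < 1L)
    stop("need at least one level and one seed")
  cells <- list()
  rows <- list()
  for (lv in levels) {
    c_lv <- cfg
    c_lv$noise_sd <- lv
    cmp <- run_matched_comparison(c_lv, seeds = seeds)
    for (arch in unique(cmp$table$architecture)) {
      acc <- cmp$table$final_accuracy[cmp$table$architecture == arch]
      cells[[paste(arch, lv)]] <- acc
      rows[[paste(arch, lv)]] <- data.frame(
        architecture = arch, noise_sd = lv,
        mean_accuracy = mean(acc),
        sd_accuracy = stats::sd(acc),
        n = length(acc))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  gap <- do.call(rbind, lapply(levels, function(lv) {
    tri <- tab$mean_accuracy[tab$architecture == "tripartite" &
                               tab$noise_sd == lv]
    bi <- tab$mean_accuracy[tab$architecture == "bipartite" &
                              tab$noise_sd == lv]
    data.frame(noise_sd = lv, gap = tri - bi)
  }))
  structure(list(table = tab, gap = gap, values = cells, seeds = seeds),
            class = "astro_sweep")
}

#' @export
print.astro_sweep <- function(x, ...) {
  cat(sprintf("Noise sweep, %d replicate seed(s) per cell\n",
              length(x$seeds)))
  tab <- x$table
  tab$mean_accuracy <- round(tab$mean_accuracy, 3)
  tab$sd_accuracy <- round(tab$sd_accuracy, 3)
  print(tab, row.names = FALSE)
  cat("tripartite - bipartite gap per level:\n")
  print(transform(x$gap, gap = round(gap, 3)), row.names = FALSE)
  invisible(x)
}

#' @export
plot.astro_sweep <- function(x, ...) {
  tab <- x$table
  archs <- unique(tab$architecture)
  graphics::plot(range(tab$noise_sd), c(0.4, 1), type = "n",
                 xlab = "voltage noise sd", ylab = "mean final accuracy",
                 ...)
  for (i in seq_along(archs)) {
    sub <- tab[tab$architecture == archs[i], ]
    graphics::lines(sub$noise_sd, sub$mean_accuracy, type = "b", pch = i)
  }
  graphics::legend("bottomleft", legend = archs, pch = seq_along(archs))
  invisible(x)
}
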