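# A small but complete session protocol used throughout these tests; the
# short trials keep the suite fast without changing any model mechanics.
small_cfg <- function(arch = "bipartite", seed = 1, n_trials = 60,
                      noise_sd = 0, ...) {
  session_config(arch, n_trials = n_trials, block_size = 20,
                 noise_sd = noise_sd, seed = seed, duration = 600,
                 stim_on = 100, stim_off = 500, ...)
}

test_that("sessions are deterministic given a config", {
  r1 <- run_session(small_cfg(seed = 5))
  r2 <- run_session(small_cfg(seed = 5))
  expect_identical(r1$trials, r2$trials)
  expect_identical(r1$weights_final, r2$weights_final)
})

test_that("noise conditions share stimulus sequences and initial weights", {
  quiet <- run_session(small_cfg(seed = 9, noise_sd = 0))
  noisy <- run_session(small_cfg(seed = 9, noise_sd = 0.85))
  expect_identical(quiet$trials$stimulus, noisy$trials$stimulus)
  expect_identical(quiet$weights_init, noisy$weights_init)
  other_arch <- run_session(small_cfg("tripartite", seed = 9))
  expect_identical(quiet$trials$stimulus, other_arch$trials$stimulus)
  expect_identical(quiet$weights_init, other_arch$weights_init)
})

test_that("session bookkeeping is internally consistent", {
  r <- run_session(small_cfg(seed = 2))
  expect_equal(length(r$accuracy_curve), 3)
  expect_true(all(r$accuracy_curve >= 0 & r$accuracy_curve <= 1))
  expect_equal(mean(r$accuracy_curve), mean(r$trials$correct))
  expect_equal(r$final_accuracy, mean(tail(r$trials$correct, 20)))
  expect_equal(r$trials$target, ifelse(r$trials$stimulus <= 5, 1L, 2L))
  expect_equal(r$trials$correct, r$trials$winner == r$trials$target)
  expect_equal(r$trials$R, ifelse(r$trials$correct, 1, -1))
  expect_equal(r$trials$D, dopamine(r$trials$RPE))
  # P follows its recursion against R
  eta <- r$config$learning$eta
  P_hand <- Reduce(function(P, R) P + eta * (R - P), r$trials$R,
                   accumulate = TRUE, init = 0)[-1]
  expect_equal(r$trials$P, P_hand)
  expect_true(all(r$weights_final >= 0 &
                    r$weights_final <= r$config$learning$w_max))
})

test_that("blocked accuracy averages reproduce the overall mean", {
  x <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)
  expect_equal(blocked_accuracy(x, 4), c(0.75, 0.5))
  expect_equal(mean(blocked_accuracy(x, 2)), mean(x))
})

test_that("with zero learning rates accuracy stays at chance across seeds", {
  dead <- learning_params(alpha_w = 0, beta_w = 0, gamma_w = 0)
  acc <- sapply(1:6, function(s)
    mean(run_session(small_cfg(seed = s, n_trials = 100,
                               learning = dead))$trials$correct))
  expect_gt(mean(acc), 0.3)
  expect_lt(mean(acc), 0.7)
})

test_that("matched comparison enforces its contract and is symmetric under determinism", {
  cfg <- small_cfg("tripartite", seed = 3)
  cmp <- run_matched_comparison(cfg, seeds = c(3, 4))
  expect_equal(nrow(cmp$table), 4)
  expect_setequal(unique(cmp$table$architecture),
                  c("bipartite", "tripartite"))
  # same-architecture pair must be identical
  same <- run_matched_comparison(cfg, seeds = 3, cfg2 = cfg)
  expect_equal(same$table$final_accuracy[1], same$table$final_accuracy[2])
  bad <- small_cfg("bipartite", seed = 3, n_trials = 40)
  expect_error(run_matched_comparison(cfg, seeds = 3, cfg2 = bad),
               "architecture")
})

test_that("the noise sweep reports one row per architecture and level", {
  cfg <- small_cfg(n_trials = 40)
  sw <- run_noise_sweep(cfg, levels = c(0, 0.85), seeds = c(1, 2))
  expect_equal(nrow(sw$table), 4)
  expect_equal(nrow(sw$gap), 2)
  expect_true(all(sw$table$n == 2))
  expect_true(all(sw$table$mean_accuracy >= 0 &
                    sw$table$mean_accuracy <= 1))
  # single replicate at one level reduces to a matched comparison
  sw1 <- run_noise_sweep(cfg, levels = 0, seeds = 7)
  cmp <- run_matched_comparison(cfg, seeds = 7)
  for (arch in c("bipartite", "tripartite"))
    expect_equal(sw1$table$mean_accuracy[sw1$table$architecture == arch],
                 cmp$table$final_accuracy[cmp$table$architecture == arch])
})

test_that("configs round-trip through structured text", {
  cfg <- small_cfg("tripartite", seed = 42, noise_sd = 0.65)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back, cfg)
})

test_that("config reading reports missing keys and tolerates unknown ones", {
  cfg <- small_cfg()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_config(cfg, path)
  x <- yaml::read_yaml(path)
  x$noise_sd <- NULL
  yaml::write_yaml(x, path)
  expect_error(read_config(path), "noise_sd")

  write_config(cfg, path)
  x <- yaml::read_yaml(path)
  x$future_option <- "whatever"
  yaml::write_yaml(x, path)
  expect_warning(back <- read_config(path), "future_option")
  expect_equal(back$n_trials, cfg$n_trials)
})

test_that("per-trial results round-trip through delimited text", {
  r <- run_session(small_cfg(seed = 6, n_trials = 40))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_results(r, path)
  back <- read_results(path)
  expect_equal(back$winner, r$trials$winner)
  expect_equal(back$P, r$trials$P, tolerance = 1e-12)
})
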