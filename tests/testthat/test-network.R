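test_that("Gaussian receptive-field encoding is exact at and away from the peak", {
  enc <- stimulus_encoding()
  amps <- encode_stimulus(enc, 1)
  expect_equal(amps[1], 70)                       # zero distance
  expect_equal(amps[10], 70 * exp(-90^2 / 1800))  # far edge of the grid
  # symmetry: amplitude depends only on grid distance
  amps5 <- encode_stimulus(enc, 5)
  expect_equal(amps5[5 - 2], amps5[5 + 2])
  expect_error(encode_stimulus(enc, 11), "selected_index")
})

test_that("matched seeds give identical initial weights across architectures", {
  a <- build_network("bipartite", seed = 7)
  b <- build_network("tripartite", seed = 7)
  expect_identical(a$weights, b$weights)
  expect_identical(dim(a$weights), c(10L, 2L))
  expect_identical(a$n_astro, 0L)
  expect_identical(b$n_astro, 2L)
})

test_that("the compiled trial simulator agrees with the pure-R reference", {
  for (arch in c("bipartite", "tripartite")) {
    net <- build_network(arch, seed = 5, n_pre = 3L, n_post = 2L,
                         init_weight_range = c(100, 300))
    stim <- c(70, 50, 20)
    got <- simulate_trial(net, stim, duration = 400, stim_on = 50,
                          stim_off = 350)
    want <- ref_trial(net, stim, n_steps = 400, stim_on = 50,
                      stim_off = 350)
    expect_equal(got$I_K, want$I_K, tolerance = 1e-12)
    expect_equal(got$S_J, want$S_J, tolerance = 1e-12)
    expect_equal(got$pre_events, want$pre_events)
    expect_equal(got$post_events, want$post_events)
    if (arch == "tripartite")
      expect_equal(got$astro_events, want$astro_events)
  }
})

test_that("noisy trials agree with the reference under a shared RNG stream", {
  net <- build_network("tripartite", seed = 2, n_pre = 3L, n_post = 2L,
                       init_weight_range = c(100, 300))
  stim <- c(70, 60, 30)
  set.seed(99)
  got <- simulate_trial(net, stim, noise_sd = 0.85, duration = 300,
                        stim_on = 50, stim_off = 250)
  set.seed(99)
  want <- ref_trial(net, stim, noise_sd = 0.85, n_steps = 300,
                    stim_on = 50, stim_off = 250)
  expect_equal(got$S_J, want$S_J, tolerance = 1e-12)
  expect_equal(got$pre_events, want$pre_events)
  expect_equal(got$post_events, want$post_events)
})

test_that("a silent noiseless network produces no events and zero activation", {
  net <- build_network("tripartite", seed = 1)
  tr <- simulate_trial(net, rep(0, 10), duration = 500)
  expect_true(all(lengths(tr$pre_events) == 0))
  expect_true(all(lengths(tr$post_events) == 0))
  expect_equal(tr$S_J, c(0, 0))   # resting voltage is negative throughout
  expect_true(tr$winner %in% 1:2)
})

test_that("winner selection is argmax with seed-reproducible tie-breaks", {
  expect_identical(decide_winner(c(10, 5)), 1L)
  expect_identical(decide_winner(c(0, 3)), 2L)
  set.seed(4)
  w1 <- decide_winner(c(4, 4))
  set.seed(4)
  expect_identical(decide_winner(c(4, 4)), w1)
  set.seed(10)
  draws <- replicate(50, decide_winner(c(4, 4)))
  expect_setequal(unique(draws), 1:2)   # both outcomes reachable
  expect_error(decide_winner(numeric(0)), "non-empty")
})

test_that("bipartite trials are unaffected by astrocyte-pathway settings", {
  net <- build_network("bipartite", seed = 3)
  stim <- encode_stimulus(stimulus_encoding(), 4)
  a <- simulate_trial(net, stim, duration = 600, glu_in_cleft = TRUE)
  b <- simulate_trial(net, stim, duration = 600, glu_in_cleft = FALSE)
  expect_identical(a$S_J, b$S_J)
  expect_identical(a$I_K, b$I_K)
})

test_that("the astrocyte prolongs postsynaptic activity in single-synapse runs", {
  last_events <- sapply(1:5, function(s) {
    bi <- simulate_single_synapse("bipartite", seed = s)
    tri <- simulate_single_synapse("tripartite", seed = s)
    expect_gt(length(bi$pre_events[[1]]), 0)
    c(bi = max(bi$post_events[[1]]), tri = max(tri$post_events[[1]]))
  })
  expect_true(all(last_events["tri", ] > last_events["bi", ]))
  # tripartite runs also show astrocyte release events
  tri <- simulate_single_synapse("tripartite", seed = 1)
  expect_gt(length(tri$astro_events[[1]]), 0)
})
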