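test_that("rest is a fixed point of the dynamics at zero input", {
  for (p in list(neuron_params(), astrocyte_params(),
                 cell_params(C = 50, v_r = -65, v_t = -45, k = 1, a = 0.02,
                             b = 0.2, c = -65, d = 8, v_peak = 30))) {
    s <- rest_state(p)
    for (i in 1:50) s <- step_cell(s, p, I_ext = 0)
    expect_identical(s$v, p$v_r)
    expect_identical(s$u, 0)
    expect_false(s$event_flag)
  }
})

test_that("a single Euler step matches hand arithmetic", {
  s <- step_cell(cell_state(-60, 0), neuron_params(), I_ext = 100, dt = 1)
  # dv = (k*(v-vr)*(v-vt) - u + I)/C = (0.7*0*(-20) - 0 + 100)/100 = 1
  expect_equal(s$v, -59)
  # du = a*(b*(v-vr) - u) with the updated v: 0.03*(-2*1 - 0) = -0.06
  expect_equal(s$u, 0.03 * (-2 * 1))
})

test_that("crossing v_peak applies the reset rule", {
  p <- neuron_params()
  s <- step_cell(cell_state(30, 0), p, I_ext = 5000, dt = 1)
  expect_true(s$event_flag)
  expect_equal(s$v, -50)        # reset to c
  # u takes its Euler update at the advanced voltage, then the d increment:
  # v advances to 30 + (0.7*90*70 + 5000)/100 = 124.1 before the reset
  expect_equal(s$u, 0.03 * (-2 * (124.1 + 60)) + 100)
})

test_that("voltage stays below v_peak after any step", {
  set.seed(11)
  p <- neuron_params()
  for (i in 1:200) {
    s <- cell_state(runif(1, -80, 34), runif(1, -50, 200))
    s2 <- step_cell(s, p, I_ext = runif(1, -200, 4000), dt = 1,
                    v_substeps = 2)
    expect_lt(s2$v, p$v_peak)
  }
})

test_that("constant-current traces behave at the fixed point and validate inputs", {
  tr <- simulate_constant_current(neuron_params(), I = 0, t_on = 0,
                                  t_off = 500, duration = 500)
  expect_equal(unique(tr$v), -60)
  expect_identical(tr$n_events, 0L)
  expect_error(simulate_constant_current(neuron_params(), I = 1,
                                         t_on = 300, t_off = 100),
               "t_on")
})

test_that("the astrocyte is silent under the standard injection protocol but spikes for strong currents", {
  tr <- simulate_constant_current(astrocyte_params(), I = 4, t_on = 100,
                                  t_off = 1000, duration = 1000)
  expect_identical(tr$n_events, 0L)
  strong <- simulate_constant_current(astrocyte_params(), I = 50,
                                      t_on = 100, t_off = 1000,
                                      duration = 1000)
  expect_gte(strong$n_events, 1L)
})

test_that("event counts are robust to halving the step size", {
  for (I in c(50, 100)) {
    n1 <- simulate_constant_current(neuron_params(), I, t_on = 0,
                                    t_off = 1000, duration = 1000,
                                    dt = 1)$n_events
    n2 <- simulate_constant_current(neuron_params(), I, t_on = 0,
                                    t_off = 1000, duration = 1000,
                                    dt = 0.5)$n_events
    expect_lte(abs(n1 - n2), 1)
  }
})

test_that("steady-state I-V closed form matches direct evaluation", {
  a <- astrocyte_params()
  expect_equal(steady_state_iv(a, -70)$current, 0)
  # (v - v_r) * (b - k*(v - v_t)) at v = -45
  expect_equal(steady_state_iv(a, -45)$current,
               25 * (-6.5e-4 - 2.77e-5 * (-45 - 1429.164)))
  expect_error(steady_state_iv(a, c(0, 40)), "v_peak")
  expect_error(steady_state_iv(a, c(5, 3)), "increasing")
})

test_that("simulated subthreshold equilibria agree with the closed-form curve", {
  a <- astrocyte_params()
  for (I in c(1, 2, 3)) {
    root <- uniroot(function(v) steady_state_iv(a, v)$current - I,
                    c(a$v_r, a$v_peak - 0.1))$root
    tr <- simulate_constant_current(a, I, t_on = 0, t_off = 30000,
                                    duration = 30000)
    expect_identical(tr$n_events, 0L)
    expect_lt(abs(tail(tr$v, 1) - root), 0.5)
  }
})

test_that("astrocyte I-V is near-linear, neuron I-V is not", {
  grid <- seq(-200, 30, by = 1)
  r2_astro <- linearity_r2(steady_state_iv(astrocyte_params(), grid))
  r2_neuron <- linearity_r2(steady_state_iv(neuron_params(), grid))
  expect_gte(r2_astro, 0.99)
  expect_lt(r2_neuron, r2_astro)
  expect_lt(r2_neuron, 0.9)   # N-shaped quadratic is far from a line
})

test_that("linearity_r2 validates its input", {
  expect_equal(linearity_r2(iv_curve(1:5, 2 * (1:5) + 3)), 1)
  expect_error(linearity_r2(iv_curve(1:2, 1:2)), "3 points")
  expect_error(linearity_r2(iv_curve(1:5, rep(1, 5))), "degenerate")
})

test_that("I-V curves round-trip through delimited text", {
  curve <- steady_state_iv(astrocyte_params(), seq(-100, 0, by = 10))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_iv_curve(curve, path)
  back <- read_iv_curve(path)
  expect_equal(back$voltage, curve$voltage)
  expect_equal(back$current, curve$current)
})

test_that("parameter presets match their defining constants", {
  n <- neuron_params()
  expect_equal(unclass(n)[c("C", "k", "b", "d")],
               list(C = 100, k = 0.7, b = -2, d = 100))
  a <- astrocyte_params()
  expect_equal(a$v_t, 1429.164)
  expect_equal(a$k, 2.77e-5)
  expect_error(cell_params(C = -1, v_r = -60, v_t = -40, k = 1, a = 0.1,
                           b = 1, c = -50, d = 10, v_peak = 30), "C")
})
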