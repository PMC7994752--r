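test_that("adaptive threshold update follows the forward-Euler rule", {
  ap <- adapt_params(0.9, 0.1)
  expect_equal(threshold_step(0, 0, ap, dt = 1), 0)
  expect_equal(threshold_step(1, 1, ap, dt = 1), 1) # fixed point under one spike/step
  expect_equal(threshold_step(0, 1, ap, dt = 1), 0.1)
  # vectorised over a and spikes
  expect_equal(threshold_step(c(0, 1), c(1, 1), ap, dt = 1), c(0.1, 1))
  expect_error(threshold_step(NaN, 0, ap), "non-finite")
  expect_error(threshold_step(0, 3, ap))
})

test_that("closed-form equilibria match their stated values", {
  ap <- adapt_params(0.9, 0.1)
  expect_equal(threshold_equilibrium(ap, 0), 0)
  expect_equal(threshold_equilibrium(ap, 1), 1)
  expect_equal(threshold_equilibrium(ap, 2), 2)
  expect_error(adapt_params(alpha = 1)) # no stable equilibrium
})

test_that("simulated threshold dynamics converge to the closed form", {
  # fixed-point consistency over random (alpha, beta), constant drive
  set.seed(42)
  for (i in 1:20) {
    ap <- adapt_params(alpha = runif(1, 0, 0.99), beta = runif(1, 0, 1))
    s <- sample(0:2, 1)
    a <- 0
    for (step in 1:5000) {
      a_new <- threshold_step(a, s, ap, dt = 1)
      if (abs(a_new - a) < 1e-12) break
      a <- a_new
    }
    expect_equal(a, threshold_equilibrium(ap, s), tolerance = 1e-6)
  }
})

test_that("effective threshold is the base threshold raised by gamma * a", {
  expect_equal(effective_threshold(0, neuron_params(V_th = 0.5, gamma = 1)), 0.5)
  expect_equal(effective_threshold(1, neuron_params(V_th = 0.5, gamma = 1)), 1.5)
  # gamma = 0 disables plasticity regardless of a
  expect_equal(effective_threshold(7, neuron_params(V_th = 0.5, gamma = 0)), 0.5)
  st <- neuron_state(a = 2)
  expect_equal(effective_threshold(st, neuron_params(V_th = 0.5, gamma = 1)), 2.5)
})

test_that("rest is a fixed point of the membrane dynamics without input", {
  np <- neuron_params()
  st <- neuron_state(V_f = np$V_rest)
  out <- membrane_step(st, 0, 0, np, adapt_params(), t_now = 1)
  expect_equal(out$V_f, np$V_rest)
  expect_equal(out$V_r, 0)
  expect_equal(out$S_f + out$S_r, 0)
  expect_equal(out$a, 0)
})

test_that("a suprathreshold feedforward current forces a spike and reset", {
  np <- neuron_params(V_th = 0.5, V_reset = 0, gamma = 1)
  out <- membrane_step(neuron_state(), 0.6, 0, np, adapt_params(), t_now = 1)
  expect_equal(out$S_f, 1)
  expect_equal(out$V_f, 0)       # reset
  expect_equal(out$a, 0.1)       # beta * 1 spike
  expect_equal(out$t_last_f, 1)
})

test_that("a refractory channel is clamped at V_reset and discards input", {
  np <- neuron_params(tau_ref = 1)
  st <- neuron_state(V_f = 0.3, t_last_f = 0.5)
  out <- membrane_step(st, 10, 0, np, adapt_params(), t_now = 1) # diff 0.5 < tau_ref
  expect_equal(out$V_f, np$V_reset)
  expect_equal(out$S_f, 0)       # flag not re-raised while refractory
})

test_that("non-finite currents and states are rejected", {
  expect_error(membrane_step(neuron_state(), Inf, 0, neuron_params(),
                             adapt_params(), 1), "non-finite")
  expect_error(membrane_step(neuron_state(V_f = NaN), 0, 0, neuron_params(),
                             adapt_params(), 1), "non-finite")
})

test_that("long random simulations keep flags binary and respect tau_ref", {
  np <- neuron_params(tau_ref = 3)
  ap <- adapt_params()
  n <- 50; steps <- 1000
  set.seed(1)
  st <- rsnn:::.layer_state(1, n, np)
  Sf <- matrix(0, steps, n); Sr <- matrix(0, steps, n)
  for (t in seq_len(steps)) {
    st <- rsnn:::.layer_step(st, matrix(rnorm(n, 0.3, 0.5), 1),
                             matrix(rnorm(n, 0, 0.2), 1), np, ap,
                             np$gamma, t)
    expect_true(all(st$S_f %in% c(0, 1)) && all(st$S_r %in% c(0, 1)))
    Sf[t, ] <- st$S_f; Sr[t, ] <- st$S_r
  }
  expect_true(respects_refractory(Sf, np$tau_ref))
  expect_true(respects_refractory(Sr, np$tau_ref))
})

test_that("membrane stepping is bitwise deterministic", {
  st <- neuron_state(V_f = 0.2, V_r = 0.1, a = 0.05)
  a <- membrane_step(st, 0.4, 0.1, neuron_params(), adapt_params(), 3)
  b <- membrane_step(st, 0.4, 0.1, neuron_params(), adapt_params(), 3)
  expect_identical(a, b)
})

test_that("simulate_neuron returns a full trace with the expected columns", {
  tr <- simulate_neuron(rep(0.6, 20))
  expect_equal(names(tr), c("time_ms", "V_f", "V_r", "a", "S_f", "S_r"))
  expect_equal(nrow(tr), 20)
  expect_gt(sum(tr$S_f), 0)
  # adaptation variable stays non-negative and bounded by its 2-spike equilibrium
  expect_true(all(tr$a >= 0 & tr$a <= 2 + 1e-12))
})
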