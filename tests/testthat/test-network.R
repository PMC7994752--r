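test_that("sparse mask density behaves at the limits and in expectation", {
  expect_equal(make_sparse_mask(10, 1, seed = 1), matrix(1, 10, 10))
  expect_equal(make_sparse_mask(10, 0, seed = 1), matrix(0, 10, 10))
  expect_error(make_sparse_mask(10, 1.5), "density")
  m <- make_sparse_mask(1000, 0.5, seed = 3)
  se <- sqrt(0.5 * 0.5 / 1e6)
  expect_lt(abs(mean(m) - 0.5), 3 * se)
  expect_identical(m, make_sparse_mask(1000, 0.5, seed = 3))
})

test_that("initialisation is deterministic, masked and correctly scaled", {
  spec <- model_spec(n_input = 100, n_hidden = 150, n_classes = 4,
                     density = 0.3)
  m1 <- build_model(spec, seed = 9)
  m2 <- build_model(spec, seed = 9)
  expect_identical(m1, m2)
  # fan-in 100 -> weight sd about 0.1
  expect_equal(sd(m1$layers[[1]]$W_f), 0.1, tolerance = 0.1)
  expect_true(all(m1$layers[[1]]$W_r[m1$layers[[1]]$mask == 0] == 0))
  m0 <- build_model(model_spec(n_input = 100, n_hidden = 150, n_classes = 4,
                               density = 0), seed = 9)
  expect_true(all(m0$layers[[1]]$W_r == 0))
})

test_that("silence in gives silence out", {
  model <- tiny_model()
  fb <- forward_batch(model, matrix(0, 12, 15), record_raster = TRUE)
  expect_equal(fb$spike_count, 0)
  expect_equal(unname(fb$scores), matrix(0, 1, 3))
  expect_equal(nrow(fb$raster), 0)
})

test_that("refractoriness bounds the spike count of a driven neuron", {
  # one hidden neuron under constant suprathreshold drive: tau_ref = 1 ms at
  # dt = 1 ms allows at most one spike every second step
  spec <- model_spec(n_input = 1, n_hidden = 1, n_classes = 2, density = 0,
                     use_adaptive_threshold = FALSE,
                     neuron = neuron_params(tau_ref = 1))
  model <- build_model(spec, seed = 1)
  model$layers[[1]]$W_f <- matrix(5) # strong drive
  fb <- forward_batch(model, matrix(1, 1, 10))
  expect_lte(fb$spike_count, 5)
  expect_gt(fb$spike_count, 0)
})

test_that("adaptive thresholds never add spikes when inputs are matched", {
  # with recurrence the two runs would feed themselves different spike
  # trains, so the count comparison is made where inputs are identical:
  # a feedforward configuration driven by the same samples
  task <- easy_task()
  for (seed in 1:20) {
    on <- tiny_model(seed = seed, density = 0, use_adaptive_threshold = TRUE)
    off <- tiny_model(seed = seed, density = 0,
                      use_adaptive_threshold = FALSE)
    x <- task$train$samples[[seed %% 10 + 1]]
    expect_lte(forward_batch(on, x)$spike_count,
               forward_batch(off, x)$spike_count)
  }
})

test_that("scores equal a step-by-step readout recomputation on a toy model", {
  model <- tiny_model(n_input = 4, n_hidden = 3, n_classes = 2, seed = 2)
  x <- matrix(abs(rnorm(4 * 8, 0.5, 0.3)), 4, 8)
  fb <- forward_batch(model, x, record_trace = TRUE)
  np <- model$spec$neuron
  V <- matrix(0, 1, 2); acc <- matrix(0, 1, 2)
  for (t in 1:8) {
    s_t <- matrix(fb$trace_out_s[, , t], 1)
    V <- V + (np$dt / np$C) * (-np$g * (V - np$V_rest) + s_t %*% model$W_out)
    acc <- acc + V
  }
  expect_equal(unname(fb$scores), acc)
})

test_that("density 0 with recurrence on reproduces the pure feedforward net", {
  args <- list(n_input = 12, n_hidden = 20, n_classes = 3, density = 0)
  m_rec <- build_model(do.call(model_spec, c(args, use_recurrent = TRUE)),
                       seed = 4)
  m_ff <- build_model(do.call(model_spec, c(args, use_recurrent = FALSE)),
                      seed = 4)
  x <- easy_task()$train$samples[[3]]
  expect_identical(forward_batch(m_rec, x)$scores,
                   forward_batch(m_ff, x)$scores)
})

test_that("raster events match the recorded spike flags and refractory law", {
  task <- easy_task()
  model <- tiny_model(seed = 8, neuron = neuron_params(tau_ref = 2))
  out <- forward_sequence(model, task$train$samples[[1]], record_trace = TRUE)
  r <- out$raster
  expect_true(all(r$channel %in% c("ff", "rec")))
  s <- out$trace[[1]]$s # 1 x n x T total spikes per step
  for (i in seq_len(nrow(r))) {
    t_idx <- r$time_ms[i] / model$spec$neuron$dt
    expect_gte(s[1, r$neuron_id[i], t_idx], 1)
  }
  # per neuron+channel, spike separations respect tau_ref
  for (ch in c("ff", "rec")) {
    ev <- r[r$channel == ch, ]
    for (id in unique(ev$neuron_id)) {
      ts <- sort(ev$time_ms[ev$neuron_id == id])
      if (length(ts) > 1)
        expect_gte(min(diff(ts)), model$spec$neuron$tau_ref)
    }
  }
})

test_that("checkpoints round-trip losslessly", {
  model <- tiny_model(seed = 13)
  path <- tempfile(fileext = ".rds")
  save_model(model, path)
  expect_identical(load_model(path), model)
  unlink(path)
})

test_that("shape mismatches are reported", {
  model <- tiny_model()
  expect_error(forward_batch(model, matrix(0, 5, 15)), "bands")
})
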