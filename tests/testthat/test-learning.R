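test_that("boxcar surrogate gradient is 1 strictly inside the window", {
  expect_equal(surrogate_grad(0.5, 0.5, 0.5), 1)
  expect_equal(surrogate_grad(1.2, 0.5, 0.5), 0)
  expect_equal(surrogate_grad(1.0, 0.5, 0.5), 0) # boundary excluded
  expect_equal(surrogate_grad(c(0.3, 0.99, -0.1), 0.5, 0.5), c(1, 1, 0))
  expect_error(surrogate_grad(0, 0, 0))
})

test_that("reward signal is the label repeated one-hot at every step", {
  rp <- make_reward_signal(3, 10, 5)
  expect_equal(dim(rp), c(5, 10))
  expect_true(all(rowSums(rp) == 1))
  expect_true(all(rp[, 4] == 1))
  expect_error(make_reward_signal(10, 10, 5), "range")
  expect_equal(make_reward_signal(0, 1, 3), matrix(1, 3, 1))
})

test_that("reward gradient is the projected target minus the state", {
  B <- diag(2)
  expect_equal(reward_gradient(B, c(0, 1), c(0, 1)), c(0, 0))
  expect_equal(reward_gradient(B, c(0, 1), c(0, 0)), c(0, 1))
  B2 <- matrix(c(1, 0, 0, 2), 2, byrow = TRUE)
  expect_equal(reward_gradient(B2, c(0, 1), c(0.5, 0.5)), c(-0.5, 1.5))
  expect_error(reward_gradient(B2, c(0, 1, 0), c(0.5, 0.5)), "shape")
})

test_that("a closed surrogate window kills all hidden-weight updates", {
  task <- easy_task()
  model <- tiny_model()
  cfg <- learning_config(V_window = 1e-12)
  upd <- weight_update(model, task$train$samples[1:5],
                       task$train$labels[1:5], cfg)
  expect_equal(upd$layers[[1]]$dW_f, matrix(0, 12, 20))
  expect_equal(upd$layers[[1]]$dW_r, matrix(0, 20, 20))
})

test_that("a small reward-propagation step descends the target mismatch", {
  task <- easy_task()
  model <- tiny_model(seed = 3)
  cfg <- learning_config(eta_f = 1e-3, eta_r = 1e-3, V_window = 1,
                         rule = "reward_propagation")
  idx <- 1:10
  before <- weight_update(model, task$train$samples[idx],
                          task$train$labels[idx], cfg)
  model2 <- apply_update(model, before)
  after <- weight_update(model2, task$train$samples[idx],
                         task$train$labels[idx], cfg)
  expect_lt(after$target_mse, before$target_mse)
})

test_that("recurrent updates never escape the sparseness mask", {
  task <- easy_task()
  model <- tiny_model(density = 0.4, seed = 6)
  mask <- model$layers[[1]]$mask
  upd <- weight_update(model, task$train$samples[1:10],
                       task$train$labels[1:10],
                       learning_config(V_window = 1))
  expect_true(all(upd$layers[[1]]$dW_r[mask == 0] == 0))
  cfg <- learning_config(eta_f = 5e-3, eta_r = 5e-3, epochs = 5, seed = 2)
  fit <- train_network(model, task$train, cfg)
  expect_true(all(fit$model$layers[[1]]$W_r[mask == 0] == 0))
})

test_that("per-layer reward-propagation gradients are order-independent", {
  task <- easy_task()
  model <- build_model(model_spec(n_input = 12, n_hidden = c(15, 10),
                                  n_classes = 3), seed = 2)
  fb <- forward_batch(model, task$train$samples[1:6], record_trace = TRUE)
  Y <- rsnn:::.onehot(task$train$labels[1:6], 3)
  g_l <- function(l) {
    lay <- model$layers[[l]]
    rsnn:::.layer_rp_grad(fb$trace[[l]], lay$W_r, lay$mask, lay$B, Y, 0.5, 1)
  }
  order12 <- list(g_l(1), g_l(2))
  order21 <- rev(list(g_l(2), g_l(1)))
  expect_identical(order12, order21)
})

test_that("zero learning rates leave the weights bitwise unchanged", {
  task <- easy_task()
  model <- tiny_model(seed = 1)
  cfg <- learning_config(eta_f = 0, eta_r = 0, epochs = 2, seed = 9)
  fit <- train_network(model, task$train, cfg)
  expect_identical(fit$model$layers[[1]]$W_f, model$layers[[1]]$W_f)
  expect_identical(fit$model$layers[[1]]$W_r, model$layers[[1]]$W_r)
  expect_identical(fit$model$W_out, model$W_out)
})

test_that("training is deterministic given the config seed", {
  task <- easy_task()
  model <- tiny_model(seed = 1)
  cfg <- learning_config(epochs = 3, seed = 7)
  f1 <- train_network(model, task$train, cfg)
  f2 <- train_network(model, task$train, cfg)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$model, f2$model)
})

test_that("nonzero updates only arise from potentials inside the window", {
  # gating soundness: a column of dW_f is nonzero only if some step had that
  # neuron's potential within V_window of its effective threshold
  task <- easy_task()
  model <- tiny_model(seed = 12)
  cfg <- learning_config(V_window = 0.5)
  fb <- forward_batch(model, task$train$samples[1:8], record_trace = TRUE)
  upd <- weight_update(model, task$train$samples[1:8],
                       task$train$labels[1:8], cfg)
  sg_any <- apply(abs(fb$trace[[1]]$h - fb$trace[[1]]$th) < 0.5, 2, any)
  nonzero_cols <- apply(upd$layers[[1]]$dW_f != 0, 2, any)
  expect_true(all(!nonzero_cols | sg_any))
  nonzero_post <- apply(upd$layers[[1]]$dW_r != 0, 2, any)
  expect_true(all(!nonzero_post | sg_any))
})

test_that("both learning rules beat chance from the same initialisation", {
  task <- easy_task(n_classes = 3, samples_per_class = 15, seed = 21)
  model <- tiny_model(n_hidden = 60, seed = 4)
  for (rule in c("reward_propagation", "pseudo_bp")) {
    cfg <- learning_config(eta_f = 5e-3, eta_r = 5e-3, rule = rule,
                           epochs = 12, seed = 3, batch_size = 15)
    fit <- train_network(model, task$train, cfg)
    expect_gt(tail(fit$history$train_acc, 1), 1 / 3 + 0.15,
              label = sprintf("train accuracy under %s", rule))
  }
})
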