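#' Boxcar surrogate gradient of the spike function
#'
#' The spike nonlinearity is non-differentiable at threshold; its stand-in
#' derivative is a boxcar: 1 when the membrane potential lies strictly
#' within `V_window` of the effective threshold, 0 otherwise (equality maps
#' to 0). Vectorised.
#'
#' @param V Membrane potential(s) (mV).
#' @param V_th_eff Effective firing threshold(s) (mV).
#' @param V_window Half-width of the differentiable window (mV, positive).
#' @return 0/1 value(s).
#' @export
#' @examples
#' surrogate_grad(0.5, 0.5, 0.5) # 1: at threshold, inside the window
#' surrogate_grad(1.2, 0.5, 0.5) # 0: outside
surrogate_grad <- function(V, V_th_eff, V_window = 0.5) {
  stopifnot(V_window > 0)
  (abs(V - V_th_eff) < V_window) * 1
}

#' Repeated one-hot teaching signal
#'
#' The reward-propagation rule replaces backpropagated errors with the label
#' itself: the class's one-hot indicator repeated at every step of the
#' simulation window.
#'
#' @param label 0-based class index.
#' @param n_classes Number of classes.
#' @param T Number of time steps.
#' @return A `T x n_classes` binary matrix; column `label + 1` is all ones.
#' @export
make_reward_signal <- function(label, n_classes, T) {
  stopifnot(n_classes >= 1, T >= 1)
  if (length(label) != 1 || label < 0 || label >= n_classes)
    stop("label out of range [0, n_classes)")
  rp <- matrix(0, T, n_classes)
  rp[, label + 1] <- 1
  rp
}

#' Reward-propagation error of one layer state
#'
#' The projected-target-minus-state difference `B %*% rp - h`: the fixed
#' random feedback matrix `B` converts the class-space teaching signal into
#' the hidden layer's state space, and the layer's deviation from that
#' projection is the learning signal.
#'
#' @param B Feedback projection, `layer width x n_classes`.
#' @param rp One time-slice of the teaching signal (length `n_classes`).
#' @param h Layer state slice (length `layer width`).
#' @return Numeric vector of length `layer width`.
#' @export
reward_gradient <- function(B, rp, h) {
  if (!is.matrix(B) || ncol(B) != length(rp) || nrow(B) != length(h))
    stop("shape mismatch between B, rp and h")
  as.vector(B %*% rp) - h
}

#' Training configuration
#'
#' @param eta_f Feedforward (and readout) learning rate.
#' @param eta_r Recurrent learning rate.
#' @param V_window Surrogate-gradient half-width (mV).
#' @param rule `"reward_propagation"` (global label-driven rule) or
#'   `"pseudo_bp"` (layer-by-layer surrogate-gradient chain).
#' @param batch_size Mini-batch size.
#' @param epochs Number of epochs.
#' @param seed Seed controlling all training randomness (shuffling).
#' @param lr_step_every,lr_factor Stepwise learning-rate schedule: the rate
#'   is multiplied by `lr_factor` every `lr_step_every` epochs.
#' @param rec_depth Truncation depth of the backward credit flow through the
#'   recurrent weights (1 = credit from step `t + 1` only).
#' @return An object of class `learning_config`.
#' @export
learning_config <- function(eta_f = 1e-3, eta_r = 1e-3, V_window = 0.5,
                            rule = c("reward_propagation", "pseudo_bp"),
                            batch_size = 50, epochs = 100, seed = 1,
                            lr_step_every = 100, lr_factor = 0.5,
                            rec_depth = 1) {
  stopifnot(eta_f >= 0, eta_r >= 0, V_window > 0, batch_size >= 1,
            epochs >= 0, rec_depth >= 1)
  structure(list(eta_f = eta_f, eta_r = eta_r, V_window = V_window,
                 rule = match.arg(rule), batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 lr_step_every = as.integer(lr_step_every),
                 lr_factor = lr_factor, rec_depth = as.integer(rec_depth)),
            class = "learning_config")
}

# One-hot matrix from 0-based labels: nb x n_classes.
.onehot <- function(labels, n_classes) {
  Y <- matrix(0, length(labels), n_classes)
  Y[cbind(seq_along(labels), labels + 1)] <- 1
  Y
}

# Reward-propagation gradient of one hidden layer. Depends only on that
# layer's own trace, its feedback matrix B and the teaching signal, which is
# what makes the per-layer updates order-independent (parallelisable).
# Returns loss-gradient matrices (Adam minimises, so positive gradient of
# 0.5 * ||h - B rp||^2).
.layer_rp_grad <- function(tr, W_r, mask, B, Y, V_window, rec_depth) {
  dims <- dim(tr$h)
  nb <- dims[1]; n <- dims[2]; T <- dims[3]
  proj <- Y %*% t(B)                         # nb x n, constant over t
  sg <- (abs(tr$h - tr$th) < V_window) * 1   # nb x n x T
  gWf <- matrix(0, dim(tr$pre)[2], n)
  gWr <- matrix(0, n, n)
  e_gated <- array(0, dims)
  for (t in seq_len(T))
    e_gated[, , t] <- (matrix(tr$h[, , t], nb) - proj) *
      matrix(sg[, , t], nb)
  for (t in seq_len(T))
    gWf <- gWf + crossprod(matrix(tr$pre[, , t], nb),
                           matrix(e_gated[, , t], nb))
  # backward credit through W_r, truncated at rec_depth hops
  flow <- array(0, dims)
  prop <- e_gated
  for (j in seq_len(rec_depth)) {
    nxt <- array(0, dims)
    if (T > j) {
      for (t in seq_len(T - 1)) {
        f <- (matrix(prop[, , t + 1], nb) %*% t(W_r)) * matrix(sg[, , t], nb)
        nxt[, , t] <- f
      }
    }
    flow <- flow + nxt
    prop <- nxt
  }
  for (t in seq_len(T)) {
    s_prev <- if (t == 1) matrix(0, nb, n) else matrix(tr$s[, , t - 1], nb)
    gWr <- gWr + crossprod(s_prev,
                           matrix(e_gated[, , t] + flow[, , t], nb))
  }
  scale <- 1 / (nb * T)
  list(gWf = gWf * scale, gWr = (gWr * scale) * mask,
       target_mse = mean((tr$h - array(rep(proj, T), dims))^2))
}

# Pseudo-BP gradients: the output-layer MSE error is chained backwards
# layer-by-layer through the readout and feedforward weights, gated by the
# boxcar surrogate at every step.
.pseudo_bp_grads <- function(model, fb, e_out, V_window, rec_depth) {
  L <- length(model$layers)
  tr <- fb$trace
  nb <- nrow(e_out)
  grads <- vector("list", L)
  d_top <- e_out %*% t(model$W_out)   # nb x n_L, constant over t
  delta_next <- NULL
  for (l in rev(seq_len(L))) {
    tl <- tr[[l]]
    dims <- dim(tl$h)
    n <- dims[2]; T <- dims[3]
    sg <- (abs(tl$h - tl$th) < V_window) * 1
    e_gated <- array(0, dims)
    for (t in seq_len(T)) {
      d_t <- if (l == L) d_top
             else matrix(delta_next[, , t], nb) %*% t(model$layers[[l + 1]]$W_f)
      e_gated[, , t] <- d_t * matrix(sg[, , t], nb)
    }
    W_r <- model$layers[[l]]$W_r
    flow <- array(0, dims)
    prop <- e_gated
    for (j in seq_len(rec_depth)) {
      nxt <- array(0, dims)
      if (T > j) {
        for (t in seq_len(T - 1))
          nxt[, , t] <- (matrix(prop[, , t + 1], nb) %*% t(W_r)) *
            matrix(sg[, , t], nb)
      }
      flow <- flow + nxt
      prop <- nxt
    }
    gWf <- matrix(0, dim(tl$pre)[2], n)
    gWr <- matrix(0, n, n)
    for (t in seq_len(T)) {
      gWf <- gWf + crossprod(matrix(tl$pre[, , t], nb),
                             matrix(e_gated[, , t], nb))
      s_prev <- if (t == 1) matrix(0, nb, n) else matrix(tl$s[, , t - 1], nb)
      gWr <- gWr + crossprod(s_prev,
                             matrix(e_gated[, , t] + flow[, , t], nb))
    }
    scale <- 1 / (nb * T)
    grads[[l]] <- list(gWf = gWf * scale,
                       gWr = (gWr * scale) * model$layers[[l]]$mask)
    delta_next <- e_gated
  }
  grads
}

# Full gradient bundle for one mini-batch forward pass (with trace).
# labels are 0-based. Returns per-layer gWf/gWr, the readout gradient, the
# output MSE loss and the mean target MSE (reward-propagation rule only).
.compute_gradients <- function(model, fb, labels, config) {
  spec <- model$spec
  Y <- .onehot(labels, spec$n_classes)
  e_out <- fb$ybar - Y
  loss <- mean(e_out^2)
  nb <- nrow(Y)
  T <- fb$n_steps
  S_sum <- apply(fb$trace_out_s, c(1, 2), sum)
  gWout <- crossprod(S_sum, e_out) / (nb * T)
  target_mse <- NA_real_
  if (config$rule == "reward_propagation") {
    grads <- lapply(seq_along(model$layers), function(l) {
      lay <- model$layers[[l]]
      .layer_rp_grad(fb$trace[[l]], lay$W_r, lay$mask, lay$B, Y,
                     config$V_window, config$rec_depth)
    })
    target_mse <- mean(vapply(grads, `[[`, 0, "target_mse"))
    grads <- lapply(grads, function(g) g[c("gWf", "gWr")])
  } else {
    grads <- .pseudo_bp_grads(model, fb, e_out, config$V_window,
                              config$rec_depth)
  }
  if (!all(vapply(grads, function(g) all(is.finite(g$gWf)) &&
                    all(is.finite(g$gWr)), TRUE)) || !all(is.finite(gWout)))
    stop("non-finite gradients")
  list(layers = grads, gWout = gWout, loss = loss, target_mse = target_mse)
}

#' Plain-gradient weight increments for one mini-batch
#'
#' Computes the surrogate-gated weight increments of the configured learning
#' rule for a single batch and returns them as additive updates
#' `Delta W = -eta * grad` (no optimiser state). Useful for inspecting the
#' rule; the epoch loop ([train_epoch()]) applies the same gradients through
#' the adaptive-moment optimiser instead.
#'
#' @param model An `snn_model`.
#' @param samples List of sample matrices (one mini-batch).
#' @param labels Integer vector of 0-based class labels.
#' @param config A [learning_config()].
#' @return A list with per-layer `dW_f`/`dW_r`, `dW_out`, the batch `loss`
#'   (output MSE) and, under the reward-propagation rule, `target_mse` —
#'   the mean squared deviation of the hidden state from its projected
#'   target `B %*% rp`.
#' @export
weight_update <- function(model, samples, labels, config = learning_config()) {
  fb <- forward_batch(model, samples, record_trace = TRUE)
  g <- .compute_gradients(model, fb, labels, config)
  list(layers = lapply(g$layers, function(gl)
         list(dW_f = -config$eta_f * gl$gWf,
              dW_r = -config$eta_r * gl$gWr)),
       dW_out = -config$eta_f * g$gWout,
       loss = g$loss, target_mse = g$target_mse)
}

# Adaptive-moment (Adam) optimiser, one state slot per weight matrix.
.adam_init <- function() list(tt = list(), m = list(), v = list())

.adam_step <- function(opt, key, grad, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-8) {
  if (is.null(opt$m[[key]])) {
    opt$m[[key]] <- grad * 0
    opt$v[[key]] <- grad * 0
    opt$tt[[key]] <- 0
  }
  t <- opt$tt[[key]] + 1
  opt$tt[[key]] <- t
  opt$m[[key]] <- beta1 * opt$m[[key]] + (1 - beta1) * grad
  opt$v[[key]] <- beta2 * opt$v[[key]] + (1 - beta2) * grad^2
  mhat <- opt$m[[key]] / (1 - beta1^t)
  vhat <- opt$v[[key]] / (1 - beta2^t)
  list(opt = opt, delta = -lr * mhat / (sqrt(vhat) + eps))
}

#' Run one training epoch
#'
#' Shuffles the training set (using the current RNG stream), iterates
#' mini-batches, and for each batch runs the forward pass, computes the
#' gradients of the configured rule and applies an adaptive-moment step.
#' Recurrent updates are re-masked after every step so pruned connections
#' stay exactly zero.
#'
#' @param model An `snn_model`.
#' @param dataset A [spectro_dataset()].
#' @param config A [learning_config()].
#' @param opt Optimiser state from a previous call, or `NULL` to start.
#' @param lr_scale Multiplier applied to both learning rates (the stepwise
#'   schedule of [train_network()]).
#' @return A list with `model`, `opt`, and `metrics` (loss, train_acc,
#'   spike_rate for the epoch).
#' @export
train_epoch <- function(model, dataset, config, opt = NULL, lr_scale = 1) {
  stopifnot(inherits(dataset, "spectro_dataset"),
            inherits(config, "learning_config"))
  n <- length(dataset$samples)
  if (n == 0) stop("empty dataset")
  if (is.null(opt)) opt <- .adam_init()
  ord <- sample.int(n)
  losses <- c(); accs <- c(); rates <- c(); wts <- c()
  for (start in seq(1, n, by = config$batch_size)) {
    idx <- ord[start:min(start + config$batch_size - 1, n)]
    fb <- forward_batch(model, dataset$samples[idx], record_trace = TRUE)
    g <- .compute_gradients(model, fb, dataset$labels[idx], config)
    if (!is.finite(g$loss)) stop("divergent loss")
    preds <- max.col(fb$scores, ties.method = "first") - 1L
    losses <- c(losses, g$loss); wts <- c(wts, length(idx))
    accs <- c(accs, mean(preds == dataset$labels[idx]))
    rates <- c(rates, fb$spike_rate)
    for (l in seq_along(model$layers)) {
      sf <- .adam_step(opt, paste0("Wf", l), g$layers[[l]]$gWf,
                       config$eta_f * lr_scale)
      opt <- sf$opt
      model$layers[[l]]$W_f <- model$layers[[l]]$W_f + sf$delta
      sr <- .adam_step(opt, paste0("Wr", l), g$layers[[l]]$gWr,
                       config$eta_r * lr_scale)
      opt <- sr$opt
      model$layers[[l]]$W_r <- (model$layers[[l]]$W_r + sr$delta) *
        model$layers[[l]]$mask
    }
    so <- .adam_step(opt, "Wout", g$gWout, config$eta_f * lr_scale)
    opt <- so$opt
    model$W_out <- model$W_out + so$delta
  }
  list(model = model, opt = opt,
       metrics = list(loss = stats::weighted.mean(losses, wts),
                      train_acc = stats::weighted.mean(accs, wts),
                      spike_rate = stats::weighted.mean(rates, wts)))
}

#' Train a spiking network
#'
#' The full epoch loop: seeds the RNG from the config, applies the stepwise
#' learning-rate schedule, and logs one row per epoch. Fully deterministic
#' given the config seed and data.
#'
#' @param model An `snn_model` (freshly built or a checkpoint).
#' @param train_set A [spectro_dataset()].
#' @param config A [learning_config()].
#' @param test_set Optional held-out [spectro_dataset()] evaluated each
#'   epoch.
#' @param verbose Print one line per epoch.
#' @return A list of class `snn_fit`: `model` (trained), `history` (data
#'   frame with epoch, loss, train_acc, test_acc, lr, spike_rate), `config`.
#' @export
train_network <- function(model, train_set, config = learning_config(),
                          test_set = NULL, verbose = FALSE) {
  set.seed(config$seed)
  opt <- .adam_init()
  hist <- vector("list", config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr_scale <- config$lr_factor^((ep - 1) %/% config$lr_step_every)
    res <- train_epoch(model, train_set, config, opt, lr_scale)
    model <- res$model
    opt <- res$opt
    test_acc <- NA_real_
    if (!is.null(test_set))
      test_acc <- accuracy(predict(model, test_set), test_set$labels)
    hist[[ep]] <- data.frame(epoch = ep, loss = res$metrics$loss,
                             train_acc = res$metrics$train_acc,
                             test_acc = test_acc,
                             lr = config$eta_f * lr_scale,
                             spike_rate = res$metrics$spike_rate)
    if (verbose)
      message(sprintf("epoch %3d  loss %.5f  train_acc %.3f  test_acc %s",
                      ep, res$metrics$loss, res$metrics$train_acc,
                      ifelse(is.na(test_acc), "-", sprintf("%.3f", test_acc))))
  }
  structure(list(model = model, history = do.call(rbind, hist),
                 config = config),
            class = "snn_fit")
}

#' @export
print.snn_fit <- function(x, ...) {
  last <- x$history[nrow(x$history), ]
  cat(sprintf("Trained spiking network (%s, %d epochs): loss %.5f, train acc %.3f\n",
              x$config$rule, nrow(x$history), last$loss, last$train_acc))
  invisible(x)
}
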