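#' Random sparseness mask for recurrent connections
#'
#' Each entry of the returned `n x n` binary matrix is independently 1 with
#' probability `density` (uniform Bernoulli; self-connections are permitted).
#' The mask is fixed at model construction and enforced throughout training,
#' so a masked recurrent weight can never become nonzero.
#'
#' @param n Layer width.
#' @param density Fraction of permitted recurrent connections in `[0, 1]`.
#' @param seed Optional integer seed; if `NULL` the current RNG stream is
#'   used.
#' @return An `n x n` 0/1 matrix.
#' @export
#' @examples
#' make_sparse_mask(5, 1)   # fully connected
#' make_sparse_mask(5, 0)   # recurrence disabled
make_sparse_mask <- function(n, density, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.numeric(density) || density < 0 || density > 1)
    stop("density must lie in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  matrix((stats::runif(n * n) < density) * 1, n, n)
}

#' Specification of a recurrent spiking network
#'
#' Describes the architecture and dynamics of a layered spiking network:
#' an input layer fed with scaled spectrogram frames, one or more hidden
#' layers of two-channel adaptive-threshold LIF neurons with masked sparse
#' recurrent connections, and a non-spiking leaky-integrator readout with
#' one unit per class.
#'
#' @param n_input Input width (number of frequency bands).
#' @param n_hidden Integer vector of hidden-layer widths (default one layer
#'   of 500, the reference topology).
#' @param n_classes Number of classes (output width).
#' @param density Recurrent connection density in `[0, 1]` (0.5 reproduces
#'   the half-sparse reference configuration).
#' @param use_adaptive_threshold If `FALSE`, the adaptation coupling is
#'   ignored (`gamma` effectively 0) — the neuronal-plasticity ablation.
#' @param use_recurrent If `FALSE`, recurrent input is skipped entirely; with
#'   `density = 0` this is bitwise-identical to a pure feedforward network.
#' @param neuron A [neuron_params()].
#' @param adapt An [adapt_params()].
#' @param input_encoding `"analog"` feeds scaled spectrogram values straight
#'   into the first layer; `"binary"` thresholds them at `neuron$V_th` first
#'   (see [threshold_encode()]).
#' @return An object of class `model_spec`.
#' @seealso [build_model()]
#' @export
model_spec <- function(n_input, n_hidden = 500, n_classes,
                       density = 0.5,
                       use_adaptive_threshold = TRUE,
                       use_recurrent = TRUE,
                       neuron = neuron_params(),
                       adapt = adapt_params(),
                       input_encoding = c("analog", "binary")) {
  stopifnot(n_input >= 1, all(n_hidden >= 1), n_classes >= 2,
            inherits(neuron, "neuron_params"), inherits(adapt, "adapt_params"))
  if (density < 0 || density > 1) stop("density must lie in [0, 1]")
  structure(
    list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
         n_classes = as.integer(n_classes), density = density,
         use_adaptive_threshold = isTRUE(use_adaptive_threshold),
         use_recurrent = isTRUE(use_recurrent),
         neuron = neuron, adapt = adapt,
         input_encoding = match.arg(input_encoding)),
    class = "model_spec"
  )
}

#' Initialise a spiking network from its specification
#'
#' Draws all weights from zero-mean Gaussians scaled by `1/sqrt(fan-in)`,
#' applies the sparseness mask to the recurrent matrices, and draws the fixed
#' random feedback projection `B` of each hidden layer (entries uniform on
#' `[-1/sqrt(n_classes), 1/sqrt(n_classes)]`, never trained). Fully
#' deterministic given `seed`.
#'
#' @param spec A [model_spec()].
#' @param seed Integer seed for all initialisation randomness.
#' @return An object of class `snn_model`: the spec, a list of hidden layers
#'   (each with `W_f`, `W_r`, `mask`, `B`), the readout matrix `W_out`, and
#'   the construction seed.
#' @export
build_model <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  set.seed(seed)
  widths <- c(spec$n_input, spec$n_hidden)
  k <- spec$n_classes
  layers <- vector("list", length(spec$n_hidden))
  for (l in seq_along(spec$n_hidden)) {
    pre <- widths[l]
    n <- widths[l + 1]
    W_f <- matrix(stats::rnorm(pre * n, sd = 1 / sqrt(pre)), pre, n)
    mask <- make_sparse_mask(n, spec$density)
    W_r <- matrix(stats::rnorm(n * n, sd = 1 / sqrt(n)), n, n) * mask
    B <- matrix(stats::runif(n * k, -1 / sqrt(k), 1 / sqrt(k)), n, k)
    layers[[l]] <- list(W_f = W_f, W_r = W_r, mask = mask, B = B)
  }
  n_last <- spec$n_hidden[length(spec$n_hidden)]
  W_out <- matrix(stats::rnorm(n_last * k, sd = 1 / sqrt(n_last)), n_last, k)
  structure(list(spec = spec, layers = layers, W_out = W_out, seed = seed),
            class = "snn_model")
}

#' @export
print.snn_model <- function(x, ...) {
  cat(sprintf(
    "Recurrent spiking network: %d -> %s -> %d (density %.2f, %s, %s)\n",
    x$spec$n_input, paste(x$spec$n_hidden, collapse = " -> "),
    x$spec$n_classes, x$spec$density,
    if (x$spec$use_adaptive_threshold) "adaptive threshold" else "static threshold",
    if (x$spec$use_recurrent) "recurrent" else "feedforward-only"))
  invisible(x)
}

# Stack a list of band x frame matrices into an array (batch, bands, frames).
.stack_samples <- function(samples, n_input) {
  frames <- unique(vapply(samples, ncol, 1L))
  bands <- unique(vapply(samples, nrow, 1L))
  if (length(frames) != 1L || length(bands) != 1L)
    stop("all samples in a batch must share the same bands x frames shape")
  if (bands != n_input)
    stop(sprintf("sample has %d bands but the model input width is %d",
                 bands, n_input))
  arr <- array(0, c(length(samples), bands, frames))
  for (i in seq_along(samples)) arr[i, , ] <- samples[[i]]
  arr
}

#' Run the time-unrolled forward pass on a batch of samples
#'
#' Feeds each spectrogram frame-by-frame (one frame per integration step).
#' At step `t` the feedforward channel of layer 1 receives frame `t` through
#' `W_f`; deeper layers receive the previous layer's spikes; the recurrent
#' channel receives the same layer's spikes from step `t - 1` through the
#' masked `W_r`. The readout integrates the last hidden layer's spikes as a
#' non-spiking leaky membrane, and per-class scores are the readout
#' potential accumulated over the window.
#'
#' @param model An [build_model()] object.
#' @param samples A list of `bands x frames` matrices (a batch), or a single
#'   matrix.
#' @param record_trace If `TRUE`, retain per-step hidden potentials, spikes
#'   and presynaptic activity (needed for learning).
#' @param record_raster If `TRUE`, collect every hidden spike as an event
#'   row `(layer, neuron_id, time_ms, channel)`.
#' @return A list with `scores` (batch x classes accumulated potential),
#'   `ybar` (time-averaged readout), `spike_count`, `spike_rate` (mean spikes
#'   per neuron per step), `n_steps`, and optionally `trace` and `raster`.
#' @export
forward_batch <- function(model, samples, record_trace = FALSE,
                          record_raster = FALSE) {
  stopifnot(inherits(model, "snn_model"))
  if (is.matrix(samples)) samples <- list(samples)
  spec <- model$spec
  np <- spec$neuron
  ap <- spec$adapt
  gamma_eff <- if (spec$use_adaptive_threshold) np$gamma else 0
  X <- .stack_samples(samples, spec$n_input)
  nb <- dim(X)[1]
  n_steps <- dim(X)[3]
  if (spec$input_encoding == "binary") X <- (X > np$V_th) * 1

  L <- length(model$layers)
  states <- lapply(seq_len(L),
                   function(l) .layer_state(nb, spec$n_hidden[l], np))
  V_out <- matrix(np$V_rest, nb, spec$n_classes)
  ysum <- matrix(0, nb, spec$n_classes)
  spike_count <- 0
  dtC <- np$dt / np$C

  trace <- NULL
  if (record_trace) {
    trace <- lapply(seq_len(L), function(l) {
      n <- spec$n_hidden[l]
      pre <- c(spec$n_input, spec$n_hidden)[l]
      list(h = array(0, c(nb, n, n_steps)),
           th = array(0, c(nb, n, n_steps)),
           s = array(0, c(nb, n, n_steps)),
           pre = array(0, c(nb, pre, n_steps)))
    })
    trace_out_s <- array(0, c(nb, spec$n_hidden[L], n_steps))
  }
  raster <- if (record_raster) vector("list", n_steps) else NULL

  for (t in seq_len(n_steps)) {
    t_now <- t * np$dt
    drive <- matrix(X[, , t], nrow = nb)
    for (l in seq_len(L)) {
      lay <- model$layers[[l]]
      st <- states[[l]]
      I_ff <- drive %*% lay$W_f
      I_rec <- if (spec$use_recurrent) {
        (st$S_f + st$S_r) %*% lay$W_r
      } else {
        matrix(0, nb, ncol(lay$W_r))
      }
      new_st <- .layer_step(st, I_ff, I_rec, np, ap, gamma_eff, t_now)
      if (record_trace) {
        trace[[l]]$h[, , t] <- new_st$h_pre
        trace[[l]]$th[, , t] <- np$V_th + gamma_eff * st$a
        trace[[l]]$s[, , t] <- new_st$S_f + new_st$S_r
        trace[[l]]$pre[, , t] <- drive
      }
      if (record_raster) {
        ev_f <- which(new_st$S_f[1, ] == 1)
        ev_r <- which(new_st$S_r[1, ] == 1)
        if (length(ev_f) || length(ev_r)) {
          raster[[t]][[l]] <- data.frame(
            layer = l,
            neuron_id = c(ev_f, ev_r),
            time_ms = t_now,
            channel = rep(c("ff", "rec"), c(length(ev_f), length(ev_r))),
            stringsAsFactors = FALSE)
        }
      }
      spike_count <- spike_count + sum(new_st$S_f) + sum(new_st$S_r)
      states[[l]] <- new_st
      drive <- new_st$S_f + new_st$S_r
    }
    if (record_trace) trace_out_s[, , t] <- drive
    V_out <- V_out + dtC * (-np$g * (V_out - np$V_rest) + drive %*% model$W_out)
    ysum <- ysum + V_out
  }

  out <- list(scores = ysum, ybar = ysum / n_steps,
              spike_count = spike_count,
              spike_rate = spike_count / (nb * n_steps * sum(spec$n_hidden)),
              n_steps = n_steps)
  if (record_trace) {
    out$trace <- trace
    out$trace_out_s <- trace_out_s
  }
  if (record_raster) {
    rows <- unlist(raster, recursive = FALSE)
    rows <- rows[!vapply(rows, is.null, TRUE)]
    out$raster <- if (length(rows)) {
      df <- do.call(rbind, rows)
      df[order(df$time_ms, df$neuron_id), , drop = FALSE]
    } else {
      data.frame(layer = integer(), neuron_id = integer(),
                 time_ms = numeric(), channel = character(),
                 stringsAsFactors = FALSE)
    }
  }
  out
}

#' Forward pass of a single sample with spike raster
#'
#' Convenience wrapper around [forward_batch()] for one spectrogram: returns
#' the per-class score vector, the spike raster and (optionally) the full
#' hidden-state trace.
#'
#' @param model An `snn_model`.
#' @param sample A `bands x frames` matrix.
#' @param record_trace Retain hidden-state traces.
#' @return A list with `scores` (named numeric vector over classes 0-based),
#'   `prediction` (0-based class index), `raster`, `spike_rate`, and
#'   optionally `trace`.
#' @export
forward_sequence <- function(model, sample, record_trace = FALSE) {
  stopifnot(is.matrix(sample))
  fb <- forward_batch(model, list(sample), record_trace = record_trace,
                      record_raster = TRUE)
  scores <- drop(fb$scores)
  names(scores) <- as.character(seq_along(scores) - 1L)
  out <- list(scores = scores, prediction = which.max(scores) - 1L,
              raster = fb$raster, spike_rate = fb$spike_rate)
  if (record_trace) out$trace <- fb$trace
  out
}

#' Predict class labels for a dataset
#'
#' @param object An `snn_model`.
#' @param dataset A [spectro_dataset()] or a list of sample matrices.
#' @param batch_size Samples per forward batch.
#' @param ... Unused.
#' @return Integer vector of 0-based predicted class indices.
#' @export
predict.snn_model <- function(object, dataset, batch_size = 100, ...) {
  samples <- if (inherits(dataset, "spectro_dataset")) dataset$samples
             else dataset
  n <- length(samples)
  preds <- integer(n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    fb <- forward_batch(object, samples[idx])
    preds[idx] <- max.col(fb$scores, ties.method = "first") - 1L
  }
  preds
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the full model (weights, masks, feedback
#' projections, parameters and construction seed); the round trip is
#' loss-free.
#'
#' @param model An `snn_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   restored `snn_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "snn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "snn_model"))
  model
}
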