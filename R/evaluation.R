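#' Classification accuracy
#'
#' The number of correctly identified samples divided by the number of all
#' samples.
#'
#' @param predictions Integer vector of predicted class indices.
#' @param labels Integer vector of true class indices (same length).
#' @return Fraction correct in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0 || length(predictions) != length(labels))
    stop("predictions and labels must be non-empty and of equal length")
  mean(predictions == labels)
}

#' Noise-robustness ratio
#'
#' `RobustRatio = Acc_noiseless,noise / Acc_noise,noise`: the accuracy of a
#' model trained on clean data and tested on corrupted data, relative to a
#' model trained *and* tested on corrupted data. Values near 1 mean noise
#' generalisation costs nothing; the ratio is undefined when the denominator
#' is zero.
#'
#' @param acc_noiseless_noise Accuracy under the noiseless-noise regime.
#' @param acc_noise_noise Accuracy under the noise-noise regime (must be
#'   positive).
#' @return The quotient.
#' @export
robust_ratio <- function(acc_noiseless_noise, acc_noise_noise) {
  stopifnot(acc_noiseless_noise >= 0, acc_noiseless_noise <= 1,
            acc_noise_noise >= 0, acc_noise_noise <= 1)
  if (acc_noise_noise == 0)
    stop("robust ratio undefined: zero noise-noise accuracy")
  acc_noiseless_noise / acc_noise_noise
}

#' Evaluate a model on a dataset
#'
#' @param model An `snn_model` or `dense_model`.
#' @param dataset A [spectro_dataset()].
#' @return A list of class `run_metrics`: `accuracy`, `loss` (output MSE,
#'   spiking models only), `confusion` (true x predicted counts), and
#'   `spike_rate` (mean spikes per neuron per step; `NA` for the dense
#'   baseline).
#' @export
evaluate_model <- function(model, dataset) {
  stopifnot(inherits(dataset, "spectro_dataset"))
  n_classes <- if (inherits(model, "snn_model")) model$spec$n_classes
               else model$n_classes
  loss <- NA_real_
  spike_rate <- NA_real_
  if (inherits(model, "snn_model")) {
    fb <- forward_batch(model, dataset$samples)
    preds <- max.col(fb$scores, ties.method = "first") - 1L
    loss <- mean((fb$ybar - .onehot(dataset$labels, n_classes))^2)
    spike_rate <- fb$spike_rate
  } else {
    preds <- predict(model, dataset)
  }
  confusion <- table(factor(dataset$labels, levels = 0:(n_classes - 1)),
                     factor(preds, levels = 0:(n_classes - 1)))
  structure(list(accuracy = accuracy(preds, dataset$labels), loss = loss,
                 confusion = confusion, spike_rate = spike_rate),
            class = "run_metrics")
}

#' @export
print.run_metrics <- function(x, ...) {
  cat(sprintf("accuracy %.3f, loss %s, spike rate %s\n", x$accuracy,
              ifelse(is.na(x$loss), "-", sprintf("%.5f", x$loss)),
              ifelse(is.na(x$spike_rate), "-",
                     sprintf("%.4f", x$spike_rate))))
  invisible(x)
}

#' Write / read a spike raster as a plain-text event list
#'
#' One row per spike event, columns `layer,neuron_id,time_ms,channel`
#' (channel `ff` or `rec`), sorted by time then neuron id. The round trip
#' reproduces the raster exactly.
#'
#' @param raster Raster data frame (from [forward_sequence()]).
#' @param path Output file path.
#' @return `export_raster` returns `path` invisibly; `read_raster` returns
#'   the raster data frame.
#' @export
export_raster <- function(raster, path) {
  need <- c("layer", "neuron_id", "time_ms", "channel")
  stopifnot(is.data.frame(raster), all(need %in% names(raster)))
  raster <- raster[order(raster$time_ms, raster$neuron_id), need,
                   drop = FALSE]
  utils::write.csv(raster, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname export_raster
#' @export
read_raster <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(layer = "integer",
                                       neuron_id = "integer",
                                       time_ms = "numeric",
                                       channel = "character"))
  df
}

#' Noise-robustness experiment: spiking network vs dense baseline
#'
#' For every corruption proportion in `grid` and every seed, trains each
#' model under the two regimes — noise-noise (train and test both
#' corrupted) and noiseless-noise (test only) — evaluates on the corrupted
#' test set, and computes the robustness ratio. Corruption replaces entries
#' with uniform draws over the training data's value range.
#'
#' @param synth A [synth_spec()] describing the task (its seed is offset by
#'   each experiment seed so replicates see independent datasets).
#' @param grid Numeric vector of corruption proportions in `[0, 1]`.
#' @param seeds Integer vector of experiment seeds (replicates).
#' @param n_hidden Hidden width used for both models.
#' @param epochs Training epochs for both models.
#' @param config Optional [learning_config()] template for the spiking
#'   model (epochs and seed are overridden per run).
#' @param density Recurrent density of the spiking model.
#' @param verbose Print one line per run.
#' @return A list of class `robustness_report`: `results` (one row per
#'   model x proportion x seed with both accuracies and the ratio, `NA`
#'   where undefined) and `summary` (median ratio per model x proportion).
#' @export
run_robustness_experiment <- function(synth, grid = c(0, 0.1, 0.25, 0.5),
                                      seeds = 1:5, n_hidden = 100,
                                      epochs = 15, config = NULL,
                                      density = 0.5, verbose = FALSE) {
  stopifnot(inherits(synth, "synth_spec"), all(grid >= 0), all(grid <= 1))
  if (is.null(config)) config <- learning_config()
  rows <- list()
  for (seed in seeds) {
    task <- synth
    task$seed <- synth$seed + 1000L * as.integer(seed)
    data <- generate_dataset(task)
    scl <- fit_input_scale(data$train)
    train_clean <- scale_spectrogram(data$train, scl)
    test_clean <- scale_spectrogram(data$test, scl)
    vr <- range(unlist(train_clean$samples))
    for (prop in grid) {
      train_noisy <- add_uniform_noise(train_clean, noise_spec(prop, seed),
                                      vr)
      test_noisy <- add_uniform_noise(test_clean, noise_spec(prop, seed + 1),
                                     vr)
      accs <- list()
      for (regime in c("noise_noise", "noiseless_noise")) {
        tr <- if (regime == "noise_noise") train_noisy else train_clean
        # spiking model
        spec <- model_spec(n_input = task$n_bands, n_hidden = n_hidden,
                           n_classes = task$n_classes, density = density)
        cfg <- config
        cfg$epochs <- as.integer(epochs)
        cfg$seed <- as.integer(seed)
        fit <- train_network(build_model(spec, seed = seed), tr, cfg)
        accs[[paste0("snn_", regime)]] <-
          accuracy(predict(fit$model, test_noisy), test_noisy$labels)
        # dense baseline
        dn <- train_dense_baseline(tr, task$n_classes, n_hidden = n_hidden,
                                   epochs = epochs, seed = seed)
        accs[[paste0("dense_", regime)]] <-
          accuracy(predict(dn, test_noisy), test_noisy$labels)
      }
      for (m in c("snn", "dense")) {
        ann <- accs[[paste0(m, "_noise_noise")]]
        aln <- accs[[paste0(m, "_noiseless_noise")]]
        rows[[length(rows) + 1]] <- data.frame(
          model = m, proportion = prop, seed = seed,
          acc_noise_noise = ann, acc_noiseless_noise = aln,
          robust_ratio = if (ann > 0) aln / ann else NA_real_)
        if (verbose)
          message(sprintf("seed %d prop %.2f %s: nn %.3f ln %.3f",
                          seed, prop, m, ann, aln))
      }
    }
  }
  results <- do.call(rbind, rows)
  summary <- stats::aggregate(robust_ratio ~ model + proportion, results,
                              stats::median, na.action = stats::na.omit)
  structure(list(results = results, summary = summary),
            class = "robustness_report")
}

#' @export
print.robustness_report <- function(x, ...) {
  cat("Median robustness ratio by model and corruption proportion:\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
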