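# Shared fixtures: everything is generated in code at test time.

# Small easy synthetic task (high template contrast, low noise), scaled onto
# the membrane-potential range.
easy_task <- function(n_classes = 3, samples_per_class = 10, n_bands = 12,
                      n_frames = 15, noise_sd = 0.05, seed = 11) {
  spec <- synth_spec(n_classes = n_classes,
                     samples_per_class = samples_per_class,
                     n_bands = n_bands, n_frames = n_frames,
                     noise_sd = noise_sd, seed = seed)
  data <- generate_dataset(spec)
  scl <- fit_input_scale(data$train)
  list(spec = spec,
       train = scale_spectrogram(data$train, scl),
       test = scale_spectrogram(data$test, scl),
       templates = data$templates, scale = scl)
}

tiny_model <- function(n_input = 12, n_hidden = 20, n_classes = 3,
                       density = 0.5, seed = 5, ...) {
  build_model(model_spec(n_input = n_input, n_hidden = n_hidden,
                         n_classes = n_classes, density = density, ...),
              seed = seed)
}

# Apply plain-gradient increments from weight_update() to a model.
apply_update <- function(model, upd) {
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W_f <- model$layers[[l]]$W_f + upd$layers[[l]]$dW_f
    model$layers[[l]]$W_r <- (model$layers[[l]]$W_r + upd$layers[[l]]$dW_r) *
      model$layers[[l]]$mask
  }
  model$W_out <- model$W_out + upd$dW_out
  model
}

# Spike-time refractory check: TRUE when no two spikes of any neuron on the
# given channel matrix (steps x neurons, 0/1) are separated by < tau_ref.
respects_refractory <- function(spikes, tau_ref, dt = 1) {
  all(apply(spikes, 2, function(s) {
    ts <- which(s == 1) * dt
    length(ts) < 2 || min(diff(ts)) >= tau_ref
  }))
}
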