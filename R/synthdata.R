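#' Specification of a synthetic spectrogram classification task
#'
#' The generator emulates the statistical structure of filterbank speech
#' features: each class has one fixed smooth band-by-frame energy template
#' (a band-limited random field, so class evidence is spread over frames),
#' and every sample is its class template plus independent additive noise,
#' clipped at zero. Defaults mirror the 39-band x 39-frame layout of
#' FFT-processed spoken-digit spectrograms.
#'
#' @param n_classes Number of classes (>= 2).
#' @param samples_per_class Samples generated per class, in each of the
#'   train and test splits.
#' @param n_bands,n_frames Matrix dimensions.
#' @param template_sparsity Fraction of active (positive) cells per class
#'   template.
#' @param noise_sd Standard deviation of the additive Gaussian perturbation
#'   (templates have unit peak energy, so 0.1 is an easy regime and 1.0 a
#'   hard one).
#' @param seed Integer seed; generation is fully deterministic.
#' @return An object of class `synth_spec`.
#' @export
synth_spec <- function(n_classes = 4, samples_per_class = 25, n_bands = 39,
                       n_frames = 39, template_sparsity = 0.25,
                       noise_sd = 0.1, seed = 1) {
  stopifnot(n_classes >= 2, samples_per_class >= 1, n_bands >= 1,
            n_frames >= 1, template_sparsity > 0, template_sparsity <= 1,
            noise_sd >= 0)
  structure(list(n_classes = as.integer(n_classes),
                 samples_per_class = as.integer(samples_per_class),
                 n_bands = as.integer(n_bands),
                 n_frames = as.integer(n_frames),
                 template_sparsity = template_sparsity,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synth_spec")
}

# Smooth positive random field: white noise on a coarse grid, bilinearly
# interpolated up, thresholded at the (1 - sparsity) quantile and rescaled
# to unit peak. Low-frequency structure spreads class evidence over frames.
.smooth_template <- function(n_bands, n_frames, sparsity, coarse = 6) {
  C <- matrix(stats::rnorm(coarse * coarse), coarse, coarse)
  u <- seq(1, coarse, length.out = n_bands)
  v <- seq(1, coarse, length.out = n_frames)
  i0 <- pmin(floor(u), coarse - 1); fu <- u - i0
  j0 <- pmin(floor(v), coarse - 1); fv <- v - j0
  A <- C[i0, j0] * outer(1 - fu, 1 - fv) + C[i0 + 1, j0] * outer(fu, 1 - fv) +
    C[i0, j0 + 1] * outer(1 - fu, fv) + C[i0 + 1, j0 + 1] * outer(fu, fv)
  cut <- stats::quantile(A, 1 - sparsity, names = FALSE)
  A <- pmax(A - cut, 0)
  if (max(A) > 0) A <- A / max(A)
  A
}

#' Generate a labelled synthetic spectrogram dataset
#'
#' Draws one fixed template per class, then builds disjoint train and test
#' splits of `samples_per_class` noisy realisations per class each.
#' Bitwise-reproducible for a given spec.
#'
#' @param spec A [synth_spec()].
#' @return A list with `train` and `test` ([spectro_dataset()]s) and
#'   `templates` (list of class template matrices).
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  set.seed(spec$seed)
  templates <- lapply(seq_len(spec$n_classes), function(k)
    .smooth_template(spec$n_bands, spec$n_frames, spec$template_sparsity))
  draw_split <- function(tag) {
    samples <- vector("list", spec$n_classes * spec$samples_per_class)
    labels <- integer(length(samples))
    ids <- character(length(samples))
    i <- 0
    for (k in seq_len(spec$n_classes)) {
      for (s in seq_len(spec$samples_per_class)) {
        i <- i + 1
        noise <- matrix(stats::rnorm(spec$n_bands * spec$n_frames,
                                     sd = spec$noise_sd),
                        spec$n_bands, spec$n_frames)
        samples[[i]] <- pmax(templates[[k]] + noise, 0)
        labels[i] <- k - 1L
        ids[i] <- sprintf("%s_c%d_s%03d", tag, k - 1L, s)
      }
    }
    spectro_dataset(samples, labels, ids)
  }
  list(train = draw_split("train"), test = draw_split("test"),
       templates = templates)
}

#' Uniform-noise corruption specification
#'
#' @param proportion Fraction of matrix entries to corrupt, in `[0, 1]`.
#' @param seed Optional integer seed (`NULL`: current RNG stream).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(proportion, seed = NULL) {
  if (!is.numeric(proportion) || proportion < 0 || proportion > 1)
    stop("proportion must lie in [0, 1]")
  structure(list(proportion = proportion, seed = seed), class = "noise_spec")
}

#' Corrupt a sample with uniformly-distributed random noise
#'
#' Replaces a fixed fraction of entries — `round(proportion * n_entries)`
#' positions chosen uniformly at random without replacement — by independent
#' draws from `Uniform(lo, hi)`. Remaining entries and the label are
#' untouched. This is the corruption operator behind the noise-robustness
#' protocols.
#'
#' @param x A matrix, `spectrogram_sample`, or [spectro_dataset()].
#' @param noise A [noise_spec()] (or a bare proportion).
#' @param value_range Length-2 vector `(lo, hi)`, `lo < hi`.
#' @return Corrupted object of the same type.
#' @export
add_uniform_noise <- function(x, noise, value_range = c(0, 1)) {
  if (is.numeric(noise)) noise <- noise_spec(noise)
  stopifnot(inherits(noise, "noise_spec"), length(value_range) == 2)
  lo <- value_range[1]; hi <- value_range[2]
  if (!(lo < hi)) stop("value_range must satisfy lo < hi")
  if (!is.null(noise$seed)) set.seed(noise$seed)
  corrupt <- function(m) {
    k <- round(noise$proportion * length(m))
    if (k > 0) {
      idx <- sample.int(length(m), k)
      m[idx] <- stats::runif(k, lo, hi)
    }
    m
  }
  if (inherits(x, "spectro_dataset")) {
    x$samples <- lapply(x$samples, corrupt)
    return(x)
  }
  if (inherits(x, "spectrogram_sample")) {
    x$values <- corrupt(x$values)
    return(x)
  }
  corrupt(x)
}

#' Nearest-template classifier
#'
#' Assigns each sample to the class whose template is closest in Euclidean
#' distance. This is the analytic reference classifier defining the "easy"
#' regime of the synthetic task: when additive noise is small relative to
#' template contrast it is exact, and its accuracy decays as noise grows.
#'
#' @param dataset A [spectro_dataset()].
#' @param templates List of class template matrices (class k at index
#'   `k + 1`).
#' @return Integer vector of 0-based predicted labels.
#' @export
nearest_template <- function(dataset, templates) {
  stopifnot(inherits(dataset, "spectro_dataset"))
  vapply(dataset$samples, function(s) {
    d <- vapply(templates, function(tm) sum((s - tm)^2), 0)
    which.min(d) - 1L
  }, 0L)
}
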