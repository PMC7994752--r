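#' Labelled spectrogram sample and dataset containers
#'
#' A sample is a real-valued `bands x frames` matrix with a 0-based integer
#' class label; a dataset is a list of such samples with parallel label and
#' id vectors. All values must be finite.
#'
#' @param values `bands x frames` numeric matrix.
#' @param label 0-based class index.
#' @param sample_id Optional identifier string.
#' @return `spectrogram_sample`: an object with `values`, `label`,
#'   `sample_id`.
#' @export
spectrogram_sample <- function(values, label, sample_id = NULL) {
  stopifnot(is.matrix(values), ncol(values) >= 1)
  if (!all(is.finite(values))) stop("non-finite spectrogram values")
  stopifnot(length(label) == 1, label >= 0, label == floor(label))
  structure(list(values = values, label = as.integer(label),
                 sample_id = sample_id),
            class = "spectrogram_sample")
}

#' @param samples List of `bands x frames` matrices.
#' @param labels Integer vector of 0-based class labels, one per sample.
#' @param sample_ids Optional character vector of identifiers.
#' @rdname spectrogram_sample
#' @export
spectro_dataset <- function(samples, labels, sample_ids = NULL) {
  stopifnot(is.list(samples), length(samples) == length(labels),
            all(labels >= 0))
  if (is.null(sample_ids))
    sample_ids <- sprintf("s%04d", seq_along(samples))
  bands <- unique(vapply(samples, nrow, 1L))
  if (length(bands) != 1)
    stop("all samples must have the same number of bands")
  structure(list(samples = samples, labels = as.integer(labels),
                 sample_ids = sample_ids, n_bands = bands),
            class = "spectro_dataset")
}

#' @export
print.spectro_dataset <- function(x, ...) {
  cat(sprintf("Spectrogram dataset: %d samples, %d bands, %d classes\n",
              length(x$samples), x$n_bands, length(unique(x$labels))))
  invisible(x)
}

#' Rescale spectrogram input by a scalar
#'
#' The network-input half of the two-part coding: raw spectrogram energies
#' are brought onto the membrane-potential scale by a single multiplicative
#' constant, preserving all relative structure. Labels are untouched.
#'
#' @param x A `spectrogram_sample`, a [spectro_dataset()], or a bare matrix.
#' @param scalar Finite multiplier.
#' @return Object of the same type with every value multiplied by `scalar`.
#' @export
scale_spectrogram <- function(x, scalar) {
  stopifnot(is.numeric(scalar), length(scalar) == 1, is.finite(scalar))
  if (inherits(x, "spectro_dataset")) {
    x$samples <- lapply(x$samples, `*`, scalar)
    return(x)
  }
  if (inherits(x, "spectrogram_sample")) {
    x$values <- x$values * scalar
    return(x)
  }
  x * scalar
}

#' Scalar that normalises a dataset onto the membrane scale
#'
#' Returns the multiplier mapping the dataset's `q`-quantile energy to 1,
#' the default input-resize constant (q = 0.99 so rare extreme bins do not
#' dominate the scale).
#'
#' @param dataset A [spectro_dataset()].
#' @param q Quantile normalised to 1.
#' @return A positive scalar.
#' @export
fit_input_scale <- function(dataset, q = 0.99) {
  stopifnot(inherits(dataset, "spectro_dataset"))
  ref <- stats::quantile(unlist(dataset$samples), q, names = FALSE)
  if (ref <= 0) return(1)
  1 / ref
}

#' Binary spike encoding by threshold comparison
#'
#' The inner-network half of the coding: a signal strictly above the
#' threshold becomes a spike (1), anything at or below it stays silent (0).
#'
#' @param values Numeric matrix (or vector) of finite values.
#' @param threshold Comparison threshold (mV-equivalent).
#' @return Binary matrix/vector of the same shape.
#' @export
#' @examples
#' threshold_encode(c(0.4, 0.6), 0.5) # 0 1
threshold_encode <- function(values, threshold) {
  if (!all(is.finite(values))) stop("non-finite values")
  (values > threshold) * 1
}

#' Read / write a spectrogram dataset as delimited text
#'
#' The on-disk format is one CSV matrix file per sample (rows = bands,
#' columns = frames, no header) plus a manifest CSV with columns
#' `sample_id,path,label`; paths are relative to the manifest.
#'
#' @param manifest_path Path to the manifest CSV.
#' @return `read_spectro_dataset` returns a [spectro_dataset()].
#' @export
read_spectro_dataset <- function(manifest_path) {
  man <- utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  need <- c("sample_id", "path", "label")
  if (!all(need %in% names(man)))
    stop("manifest must have columns sample_id, path, label")
  base <- dirname(manifest_path)
  samples <- lapply(man$path, function(p) {
    m <- as.matrix(utils::read.csv(file.path(base, p), header = FALSE))
    dimnames(m) <- NULL
    if (!all(is.finite(m))) stop(sprintf("non-finite values in %s", p))
    m
  })
  spectro_dataset(samples, man$label, man$sample_id)
}

#' @param dataset A [spectro_dataset()].
#' @param dir Output directory (created if missing).
#' @rdname read_spectro_dataset
#' @return `write_spectro_dataset` returns the manifest path invisibly.
#' @export
write_spectro_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "spectro_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- sprintf("%s.csv", dataset$sample_ids)
  for (i in seq_along(dataset$samples))
    utils::write.table(dataset$samples[[i]], file.path(dir, paths[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  man <- data.frame(sample_id = dataset$sample_ids, path = paths,
                    label = dataset$labels)
  manifest <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manifest, row.names = FALSE)
  invisible(manifest)
}
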