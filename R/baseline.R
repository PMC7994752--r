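# Dense non-spiking comparator: a single-hidden-layer tanh network on the
# flattened scaled spectrogram, trained with Adam on the same MSE-vs-one-hot
# loss as the spiking models. Deliberately minimal — it exists to contrast
# noise robustness, not to be a tuned classifier.

#' Train the dense non-spiking baseline
#'
#' @param train_set A [spectro_dataset()].
#' @param n_classes Number of classes.
#' @param n_hidden Hidden width (match the spiking model's for a fair
#'   comparison).
#' @param epochs,batch_size,lr Training loop parameters (Adam, MSE loss).
#' @param seed Seed for initialisation and shuffling.
#' @return An object of class `dense_model`.
#' @export
train_dense_baseline <- function(train_set, n_classes, n_hidden = 100,
                                 epochs = 30, batch_size = 50, lr = 1e-3,
                                 seed = 1) {
  stopifnot(inherits(train_set, "spectro_dataset"))
  set.seed(seed)
  X <- t(vapply(train_set$samples, as.vector,
                numeric(length(train_set$samples[[1]]))))
  Y <- .onehot(train_set$labels, n_classes)
  d <- ncol(X)
  W1 <- matrix(stats::rnorm(d * n_hidden, sd = 1 / sqrt(d)), d, n_hidden)
  b1 <- numeric(n_hidden)
  W2 <- matrix(stats::rnorm(n_hidden * n_classes, sd = 1 / sqrt(n_hidden)),
               n_hidden, n_classes)
  b2 <- numeric(n_classes)
  opt <- .adam_init()
  n <- nrow(X)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    for (start in seq(1, n, by = batch_size)) {
      idx <- ord[start:min(start + batch_size - 1, n)]
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      H <- tanh(sweep(Xb %*% W1, 2, b1, `+`))
      O <- sweep(H %*% W2, 2, b2, `+`)
      E <- (O - Yb) / nrow(Xb)
      gW2 <- crossprod(H, E); gb2 <- colSums(E)
      dH <- (E %*% t(W2)) * (1 - H^2)
      gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
      for (nm in c("W1", "b1", "W2", "b2")) {
        st <- .adam_step(opt, nm, get(paste0("g", nm)), lr)
        opt <- st$opt
        assign(nm, get(nm) + st$delta)
      }
    }
  }
  structure(list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
                 n_classes = n_classes), class = "dense_model")
}

#' @param object A `dense_model`.
#' @param dataset A [spectro_dataset()].
#' @param ... Unused.
#' @rdname train_dense_baseline
#' @return `predict.dense_model` returns 0-based predicted labels.
#' @export
predict.dense_model <- function(object, dataset, ...) {
  X <- t(vapply(dataset$samples, as.vector,
                numeric(length(dataset$samples[[1]]))))
  H <- tanh(sweep(X %*% object$W1, 2, object$b1, `+`))
  O <- sweep(H %*% object$W2, 2, object$b2, `+`)
  max.col(O, ties.method = "first") - 1L
}
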