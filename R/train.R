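#' Spike-count histograms ("frames") from flatten events
#'
#' For each sample window, counts the spikes each flatten neuron emitted and
#' normalizes the counts by the window's maximum, giving an analog vector in
#' `[0, 1]` (a "frame") that captures the spiking dynamics immediately
#' before the classifier. A window with no spikes yields the zero vector.
#'
#' @param flatten_events tibble with columns `t` and `idx` (0-based flatten
#'   indices), as produced by [run_convnet()].
#' @param h flatten size (histogram length).
#' @param windows `NULL` to use the whole record as one sample, or a tibble
#'   with `t_start`, `t_end` (half-open windows; the final window is closed
#'   at the top so end-of-stream spikes are kept).
#' @return a numeric matrix, one row per window, `h` columns.
#' @export
build_histograms <- function(flatten_events, h, windows = NULL) {
  if (any(flatten_events$idx >= h | flatten_events$idx < 0)) {
    abort("flatten index out of range", class = "spikehist_validation_error")
  }
  if (is.null(windows)) {
    windows <- tibble(t_start = -Inf, t_end = Inf)
  }
  nw <- nrow(windows)
  out <- matrix(0, nw, h)
  # assign each event to the last window starting at or before it, then
  # keep those inside their window (final window closed at the top)
  wi <- findInterval(flatten_events$t, windows$t_start)
  top <- ifelse(seq_len(nw) == nw |
                  c(windows$t_start[-1L], Inf) > windows$t_end,
                windows$t_end + 1e-9, windows$t_end)
  ok <- wi >= 1L & flatten_events$t < top[pmax(wi, 1L)]
  wi <- wi[ok]
  idx <- flatten_events$idx[ok]
  counts <- matrix(tabulate((wi - 1L) * h + idx + 1L, nbins = nw * h),
                   nrow = h)
  mx <- apply(counts, 2L, max)
  nz <- mx > 0
  out[nz, ] <- t(counts[, nz, drop = FALSE]) / mx[nz]
  out
}

#' Bias-free softmax classifier trained by mini-batch SGD
#'
#' `softmax_forward()` computes the class probabilities
#' \deqn{Y_k(x, W) = \frac{e^{W_k x}}{\sum_j e^{W_j x}}}
#' (no bias term; numerically stabilized by max-subtraction), `nll_loss()`
#' the negative log-likelihood cost
#' \deqn{C = -\frac{1}{|D|} \sum_{i \in D} \log Y_{L_i}(x_i, W),}
#' and `train_msgd()` minimizes `C` by mini-batch stochastic gradient
#' descent with the analytic gradient
#' \eqn{\nabla_W C = \frac{1}{|D|}\sum_i (Y(x_i) - \mathrm{onehot}(L_i))\,x_i^T}
#' and a fixed learning rate: `W <- W - eta * grad`. Weights start at zero
#' (the problem is convex) and mini-batches are drawn from a fresh seeded
#' shuffle each epoch.
#'
#' @param W weight matrix, `classes x h`.
#' @param x a frame (length-`h` vector) or a matrix of frames (rows).
#' @return `softmax_forward()`: matrix of class probabilities (one row per
#'   frame); rows sum to 1.
#' @export
softmax_forward <- function(W, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  z <- x %*% t(W)
  z <- z - apply(z, 1L, max)
  ez <- exp(z)
  ez / rowSums(ez)
}

#' @rdname softmax_forward
#' @param labels integer labels in `[0, classes)`, one per frame row.
#' @return `nll_loss()`: the scalar cost over the batch.
#' @export
nll_loss <- function(W, x, labels) {
  if (is.vector(x)) x <- matrix(x, nrow = 1L)
  Y <- softmax_forward(W, x)
  p <- Y[cbind(seq_len(nrow(x)), as.integer(labels) + 1L)]
  -mean(log(p))
}

softmax_grad <- function(W, x, labels) {
  Y <- softmax_forward(W, x)
  T_ <- matrix(0, nrow(x), nrow(W))
  T_[cbind(seq_len(nrow(x)), as.integer(labels) + 1L)] <- 1
  t(Y - T_) %*% x / nrow(x)
}

#' @rdname softmax_forward
#' @param frames matrix of training frames (samples x h), e.g. from
#'   [build_histograms()].
#' @param eta learning rate (default 0.1).
#' @param epochs number of passes over the training set (default 1500).
#' @param batch_size mini-batch size (default 50, capped at the sample
#'   count).
#' @param seed integer seed for the per-epoch shuffles.
#' @param n_classes number of classes; by default `max(labels) + 1`, in
#'   which case every class must have at least one sample. Passing it
#'   explicitly (e.g. in cross-validation folds) permits empty classes.
#' @return `train_msgd()`: a `softmax_fit` with elements `W` (classes x h),
#'   `classes`, `final_loss`, and the training configuration.
#' @export
train_msgd <- function(frames, labels, eta = 0.1, epochs = 1500,
                       batch_size = 50, seed = 1, n_classes = NULL) {
  stopifnot(eta >= 0, epochs >= 1)
  frames <- as.matrix(frames)
  labels <- as.integer(labels)
  n <- nrow(frames)
  stopifnot(length(labels) == n, n >= 1)
  if (is.null(n_classes)) {
    k <- max(labels) + 1L
    if (length(unique(labels)) < k) {
      abort("every class in [0, max(label)] needs at least one sample",
            class = "spikehist_validation_error")
    }
  } else {
    k <- as.integer(n_classes)
    stopifnot(all(labels < k))
  }
  batch_size <- min(batch_size, n)
  W <- matrix(0, k, ncol(frames))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n_batch <- ceiling(n / batch_size)
  for (ep in seq_len(epochs)) {
    perm <- sample.int(n)
    for (b in seq_len(n_batch)) {
      rows <- perm[((b - 1L) * batch_size + 1L):min(b * batch_size, n)]
      W <- W - eta * softmax_grad(W, frames[rows, , drop = FALSE],
                                  labels[rows])
    }
  }
  structure(list(W = W, classes = k, eta = eta, epochs = epochs,
                 batch_size = batch_size, seed = seed,
                 n_train = n,
                 final_loss = nll_loss(W, frames, labels)),
            class = "softmax_fit")
}

#' @export
print.softmax_fit <- function(x, ...) {
  cat(sprintf("<softmax_fit> %d classes x %d inputs; %d epochs, eta %g, final NLL %.4f\n",
              x$classes, ncol(x$W), x$epochs, x$eta, x$final_loss))
  if (!is.null(x$W_int)) {
    cat(sprintf("  integer-scaled: K = %s = TH_FC, max rounding error %.3g\n",
                format(x$k_scale, scientific = FALSE), x$max_round_error))
  }
  invisible(x)
}

#' Predict classes from frames
#'
#' The predicted class is the unit with maximum activation,
#' `argmax_k W_k . x` (the softmax is monotone, so logits suffice). Ties go
#' to the lowest class index.
#'
#' @param object a `softmax_fit`.
#' @param frames frame matrix (or single vector).
#' @param type `"class"` (0-based indices) or `"prob"` (probability matrix).
#' @param ... unused.
#' @export
predict.softmax_fit <- function(object, frames, type = c("class", "prob"),
                                ...) {
  type <- match.arg(type)
  if (is.vector(frames)) frames <- matrix(frames, nrow = 1L)
  if (type == "prob") return(softmax_forward(object$W, frames))
  z <- frames %*% t(object$W)
  max.col(z, ties.method = "first") - 1L
}

#' Scale learned weights onto the spiking classifier
#'
#' Maps the real-valued softmax weights to the integer weights of the
#' spiking fully-connected layer: `W_int = round(K * W)`, with the
#' classifier threshold set equal to the scale, `TH_FC = K` (default
#' 10,000,000). The argmax is invariant to the positive scale, so the
#' spiking layer implements the same decision rule up to rounding (at most
#' `0.5/K` per weight) and threshold discretization.
#'
#' @param fit a `softmax_fit`.
#' @param k_scale positive integer scale `K` (default 1e7).
#' @return the fit, extended with `W_int`, `k_scale`, `th_fc` and
#'   `max_round_error` (the largest `|W - W_int/K|`).
#' @export
scale_weights <- function(fit, k_scale = 1e7) {
  stopifnot(inherits(fit, "softmax_fit"), k_scale > 0)
  W_int <- round(fit$W * k_scale)
  if (any(abs(W_int) >= 2^53)) {
    abort("scaled weights exceed exact integer range",
          class = "spikehist_validation_error")
  }
  fit$W_int <- W_int
  fit$k_scale <- k_scale
  fit$th_fc <- k_scale
  fit$max_round_error <- max(abs(fit$W - W_int / k_scale))
  fit
}

#' @export
tidy.softmax_fit <- function(x, ...) {
  W <- x$W
  tibble(class = rep(seq_len(nrow(W)) - 1L, ncol(W)),
         index = rep(seq_len(ncol(W)) - 1L, each = nrow(W)),
         weight = as.vector(W),
         weight_int = if (is.null(x$W_int)) NA_real_ else as.vector(x$W_int))
}

#' @export
glance.softmax_fit <- function(x, ...) {
  tibble(classes = x$classes, inputs = ncol(x$W), epochs = x$epochs,
         eta = x$eta, batch_size = x$batch_size, n_train = x$n_train,
         final_loss = x$final_loss,
         k_scale = x$k_scale %||% NA_real_,
         max_round_error = x$max_round_error %||% NA_real_)
}
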