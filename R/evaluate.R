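#' Classifier loss
#'
#' The difference in recognition performance between the frame-based (ANN)
#' classifier and its spiking (SNN) version, in percentage points:
#' `snn_acc - ann_acc`. Negative values mean the conversion to spikes
#' degraded accuracy; positive values mean it improved.
#'
#' @param ann_acc,snn_acc accuracies in percent, in `[0, 100]`.
#' @return percentage points (scalar).
#' @examples
#' classifier_loss(98.45, 98.42)  # -0.03
#' @export
classifier_loss <- function(ann_acc, snn_acc) {
  stopifnot(all(ann_acc >= 0 & ann_acc <= 100),
            all(snn_acc >= 0 & snn_acc <= 100))
  snn_acc - ann_acc
}

#' Network latency
#'
#' Time lapsed from the first input spike to the first classifier output
#' spike, in microseconds. Samples that never produce an output spike have
#' undefined latency: `NA` is returned and such samples are excluded from
#' summary means.
#'
#' @param input_stream an [event_stream()] (or tibble with `t`) holding the
#'   input events of one sample; must be non-empty.
#' @param output_events tibble with `t` (classifier output spikes).
#' @return latency in microseconds, or `NA` if there was no output spike.
#' @export
latency_metric <- function(input_stream, output_events) {
  if (!nrow(input_stream)) {
    abort("latency is undefined for an empty input stream",
          class = "spikehist_validation_error")
  }
  if (!nrow(output_events)) return(NA_real_)
  min(output_events$t) - min(input_stream$t)
}

#' Wilson score confidence interval for an accuracy
#'
#' Interval for a binomial success probability, assuming independent test
#' samples. The Wilson score interval is used (well-behaved near 0 and 1 and
#' for the small test sets of DVS data).
#'
#' @param successes number of correct classifications.
#' @param n number of test samples (> 0).
#' @param level confidence level (default 0.99).
#' @return named vector `c(lo, hi)` on the probability scale.
#' @export
confidence_interval <- function(successes, n, level = 0.99) {
  stopifnot(n > 0, successes >= 0, successes <= n)
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  c(lo = max(0, center - half), hi = min(1, center + half))
}

#' Spiking readout of the classifier output
#'
#' The predicted class of a sample window is the output neuron that spiked
#' the most within it; ties are broken by the earliest first spike. A window
#' with no output spikes yields no decision (`NA`), which is scored as
#' incorrect and tallied separately.
#'
#' @param fc_events tibble with `t`, `class` (0-based) classifier spikes.
#' @param n_classes number of classes.
#' @param window optional `c(t_start, t_end)`; default: all events.
#' @return 0-based predicted class, or `NA` for no decision.
#' @export
readout_class <- function(fc_events, n_classes, window = NULL) {
  ev <- fc_events
  if (!is.null(window)) {
    ev <- ev[ev$t >= window[1L] & ev$t < window[2L], , drop = FALSE]
  }
  if (!nrow(ev)) return(NA_integer_)
  counts <- tabulate(ev$class + 1L, nbins = n_classes)
  best <- which(counts == max(counts))
  if (length(best) > 1L) {
    first_spike <- vapply(best, function(c) min(ev$t[ev$class == c - 1L]),
                          numeric(1))
    best <- best[which.min(first_spike)]
  }
  best[1L] - 1L
}

#' Accuracy as a function of the input-event fraction
#'
#' In an event-driven system the output evolves event by event, so accuracy
#' can be measured part-way through each symbol: for each fraction `f`,
#' every test sample's input stream is truncated to its first `f`% of
#' events (by event count), the network plus spiking classifier is re-run,
#' and the spiking readout accuracy is recorded.
#'
#' @param samples a [sample_set()] of test samples.
#' @param config a [convnet_config()].
#' @param fit a [scale_weights()]-scaled `softmax_fit`.
#' @param fractions percentages in `(0, 100]`.
#' @param leak engage leakage (matches the training condition).
#' @return tibble `fraction`, `accuracy` (percent), `no_decision` (count).
#' @export
accuracy_vs_fraction <- function(samples, config, fit,
                                 fractions = seq(10, 100, by = 10),
                                 leak = FALSE) {
  stopifnot(all(fractions > 0 & fractions <= 100), !is.null(fit$W_int))
  g <- ev_geometry(samples$stream[[1L]])
  purrr::map_dfr(fractions, function(f) {
    correct <- 0L; nodec <- 0L
    for (i in seq_len(nrow(samples))) {
      s <- samples$stream[[i]]
      n_keep <- floor(nrow(s) * f / 100)
      ev <- unclass_stream(s)[seq_len(n_keep), , drop = FALSE]
      trunc <- event_stream(ev, g[["width"]], g[["height"]],
                            duration_us = ev_duration(s))
      res <- run_convnet(trunc, config, leak = leak, weights = fit$W_int)
      pred <- readout_class(res$fc, fit$classes)
      if (is.na(pred)) nodec <- nodec + 1L
      else if (pred == samples$label[i]) correct <- correct + 1L
    }
    tibble(fraction = f, accuracy = 100 * correct / nrow(samples),
           no_decision = nodec)
  })
}

#' Leave-one-out cross-validation over a sample set
#'
#' For each held-out sample the classifier is trained on the *slices* of
#' every other sample (each sample's flatten record is cut into
#' `slice_len_us` windows and each window becomes one training frame) and
#' tested on the whole held-out sample. Simulation happens once per sample;
#' folds reuse the recorded flatten events.
#'
#' @param samples a [sample_set()].
#' @param config a [convnet_config()].
#' @param slice_len_us training-slice length in microseconds.
#' @param leak engage leakage.
#' @param eta,epochs,batch_size,seed passed to [train_msgd()].
#' @param k_scale weight scale for the spiking classifier.
#' @return list with `accuracy` (SNN, percent over all folds),
#'   `ann_accuracy` (frame-domain predictions on the held-out frames), and
#'   `folds` (tibble `fold`, `label`, `pred_snn`, `pred_ann`).
#' @export
loocv <- function(samples, config, slice_len_us, leak = FALSE, eta = 0.1,
                  epochs = 200, batch_size = 50, seed = 1, k_scale = 1e7) {
  n <- nrow(samples)
  stopifnot(n >= 2)
  cls <- class_count(samples)
  tab <- table(samples$label)
  if (any(tab < 2L)) {
    warn("classes with a single sample cannot be trained in their own fold")
  }
  h <- config$geometry$flatten_size
  sims <- purrr::map(samples$stream, run_convnet, config = config,
                     leak = leak)
  # per-sample training slices: frames over consecutive windows
  slice_frames <- purrr::map2(sims, samples$stream, function(sim, s) {
    dur <- ev_duration(s)
    n_sl <- max(1L, ceiling(dur / slice_len_us))
    if (dur > 0 && dur %% slice_len_us == 0) n_sl <- dur %/% slice_len_us
    win <- tibble(t_start = (seq_len(n_sl) - 1) * slice_len_us,
                  t_end = pmin(seq_len(n_sl) * slice_len_us, dur))
    build_histograms(sim$flatten, h, win)
  })
  whole_frames <- t(vapply(sims, function(sim)
    build_histograms(sim$flatten, h)[1L, ], numeric(h)))
  folds <- purrr::map_dfr(seq_len(n), function(i) {
    X <- do.call(rbind, slice_frames[-i])
    yl <- rep(samples$label[-i],
              vapply(slice_frames[-i], nrow, integer(1)))
    fit <- train_msgd(X, yl, eta = eta, epochs = epochs,
                      batch_size = batch_size, seed = seed, n_classes = cls)
    fit <- scale_weights(fit, k_scale)
    fcv <- run_fc_layer(sims[[i]]$flatten, fit$W_int, fit$th_fc,
                        leak_slope = if (leak) fit$th_fc / config$fc_tl_us else 0)
    tibble(fold = i, label = samples$label[i],
           pred_snn = readout_class(fcv, cls),
           pred_ann = predict(fit, whole_frames[i, ]))
  })
  list(accuracy = 100 * mean(!is.na(folds$pred_snn) &
                               folds$pred_snn == folds$label),
       ann_accuracy = 100 * mean(folds$pred_ann == folds$label),
       folds = folds)
}
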