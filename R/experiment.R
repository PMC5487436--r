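#' Run the full train-and-convert experiment
#'
#' The complete methodology on a labeled train/test split of event streams:
#'
#' 1. simulate every training sample through the spiking front end and
#'    build one normalized spike-count histogram ("frame") per sample at
#'    the flatten output;
#' 2. train the bias-free softmax classifier on the frames by mini-batch
#'    SGD;
#' 3. scale the learned weights by `K = TH_FC` onto the spiking classifier;
#' 4. run the test streams through the full spiking network (front end plus
#'    classifier) and score the spiking readout against the frame-domain
#'    classifier on the same test frames.
#'
#' Presentation modes: `"sbs"` (sample by sample) simulates each sample in
#' a fresh network with zero leakage; `"op"` (one pass) concatenates all
#' samples into a single stream separated by `gap_us` of silence and relies
#' on the linear leakage (time constants from `config`) to fade activity
#' between samples. With `leak = FALSE` and `reset_at_boundaries = TRUE`,
#' OP is equivalent to SBS sample for sample.
#'
#' @param train_set,test_set [sample_set()]s sharing geometry and classes.
#' @param config a [convnet_config()].
#' @param mode `"sbs"` or `"op"`.
#' @param gap_us OP inter-sample gap (default 1e7, i.e. 10 s). One-pass
#'   operation relies on there being enough inter-sample time for neuron
#'   states to fade to rest; at the default classifier leak slope
#'   (`TH_FC / fc_tl_us` ~ 833 units/us) this gap absorbs accumulated
#'   membrane charge of up to ~8e9 units, so samples do not interact.
#' @param leak engage leakage; defaults to `TRUE` in OP mode, `FALSE` in
#'   SBS.
#' @param reset_at_boundaries reset all membranes at every OP sample start
#'   (used to emulate SBS within a single pass).
#' @param eta,epochs,batch_size,seed training hyper-parameters (see
#'   [train_msgd()]).
#' @param k_scale weight scale `K` (and classifier threshold `TH_FC`).
#' @return an `snn_experiment`: list with `metrics` (one-row tibble:
#'   `ann_accuracy`, `snn_accuracy`, `classifier_loss`, `mean_latency_us`,
#'   `sd_latency_us`, `mean_input_events`, `mean_total_events`,
#'   `n_no_decision`), `per_sample` (label, predictions, latency per test
#'   sample), `fit` (the scaled classifier), plus the run configuration.
#'   `glance()` returns the metrics row; `tidy()` the per-sample table.
#' @export
run_experiment <- function(train_set, test_set, config,
                           mode = c("sbs", "op"), gap_us = 1e7,
                           leak = NULL, reset_at_boundaries = FALSE,
                           eta = 0.1, epochs = 1500, batch_size = 50,
                           seed = 1, k_scale = 1e7) {
  mode <- match.arg(mode)
  if (is.null(leak)) leak <- mode == "op"
  h <- config$geometry$flatten_size
  cls <- class_count(train_set)

  sim_set <- function(samples) {
    if (mode == "sbs") {
      sims <- purrr::map(samples$stream, run_convnet, config = config,
                         leak = leak)
      frames <- t(vapply(sims, function(s)
        build_histograms(s$flatten, h)[1L, ], numeric(h)))
      list(sims = sims, frames = frames, labels = samples$label,
           windows = NULL, op = NULL)
    } else {
      op <- concat_streams(samples, gap_us)
      ann <- ev_samples(op)
      resets <- if (reset_at_boundaries) ann$t_start else numeric()
      sim <- run_convnet(op, config, leak = leak, reset_times = resets)
      # windows run to the next sample start so spikes delayed into the
      # gap still count toward their sample
      win <- tibble(t_start = ann$t_start,
                    t_end = c(ann$t_start[-1L], Inf))
      frames <- build_histograms(sim$flatten, h, win)
      list(sims = list(sim), frames = frames, labels = ann$label,
           windows = win, op = op)
    }
  }

  tr <- sim_set(train_set)
  fit <- train_msgd(tr$frames, tr$labels, eta = eta, epochs = epochs,
                    batch_size = batch_size, seed = seed, n_classes = cls)
  fit <- scale_weights(fit, k_scale)

  te <- sim_set(test_set)
  pred_ann <- predict(fit, te$frames)

  n_test <- length(te$labels)
  pred_snn <- integer(n_test); latency <- numeric(n_test)
  n_input <- numeric(n_test); n_total <- numeric(n_test)
  if (mode == "sbs") {
    for (i in seq_len(n_test)) {
      res <- run_convnet(test_set$stream[[i]], config, leak = leak,
                         weights = fit$W_int)
      pred_snn[i] <- readout_class(res$fc, cls)
      latency[i] <- latency_metric(test_set$stream[[i]], res$fc)
      n_input[i] <- res$n_input
      # every emitted spike traverses the C1, S1 and flatten links
      n_total[i] <- res$n_input + 3 * res$n_c1 + res$n_fc
    }
  } else {
    ann <- ev_samples(te$op)
    resets <- if (reset_at_boundaries) ann$t_start else numeric()
    res <- run_convnet(te$op, config, leak = leak, weights = fit$W_int,
                       reset_times = resets)
    starts <- te$windows$t_start
    wi_in <- findInterval(te$op$t, starts)
    wi_fc <- findInterval(res$fc$t, starts)
    wi_fl <- findInterval(res$flatten$t, starts)
    n_input <- tabulate(wi_in, nbins = n_test)
    n_fc_w <- tabulate(wi_fc, nbins = n_test)
    n_total <- n_input + 3 * tabulate(wi_fl, nbins = n_test) + n_fc_w
    # events are time-sorted, so the first event per window is its earliest
    first_in_t <- te$op$t[match(seq_len(n_test), wi_in)]
    first_fc_t <- res$fc$t[match(seq_len(n_test), wi_fc)]
    latency <- first_fc_t - first_in_t   # NA where either side is absent
    key_fc <- (wi_fc - 1L) * cls + res$fc$class  # 0-based within window
    counts_fc <- matrix(tabulate(key_fc + 1L, nbins = n_test * cls),
                        nrow = cls)
    first_t_key <- rep(Inf, n_test * cls)
    fst <- !duplicated(key_fc)
    first_t_key[key_fc[fst] + 1L] <- res$fc$t[fst]
    for (i in seq_len(n_test)) {
      if (n_fc_w[i] == 0L) { pred_snn[i] <- NA_integer_; next }
      ci <- counts_fc[, i]
      best <- which(ci == max(ci))
      if (length(best) > 1L) {
        ft <- first_t_key[(i - 1L) * cls + best]
        best <- best[which.min(ft)]
      }
      pred_snn[i] <- best[1L] - 1L
    }
  }

  ann_acc <- 100 * mean(pred_ann == te$labels)
  snn_acc <- 100 * mean(!is.na(pred_snn) & pred_snn == te$labels)
  metrics <- tibble(
    mode = mode, leak = leak,
    ann_accuracy = ann_acc, snn_accuracy = snn_acc,
    classifier_loss = classifier_loss(ann_acc, snn_acc),
    mean_latency_us = mean(latency, na.rm = TRUE),
    sd_latency_us = stats::sd(latency, na.rm = TRUE),
    mean_input_events = mean(n_input),
    mean_total_events = mean(n_total),
    n_no_decision = sum(is.na(pred_snn)))
  structure(list(metrics = metrics,
                 per_sample = tibble(label = te$labels, pred_ann = pred_ann,
                                     pred_snn = pred_snn,
                                     latency_us = latency,
                                     input_events = n_input),
                 fit = fit, config = config, mode = mode, leak = leak,
                 gap_us = gap_us, seed = seed),
            class = "snn_experiment")
}

#' @export
print.snn_experiment <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<snn_experiment> %s%s: ANN %.2f%%, SNN %.2f%%, classifier loss %+.2f\n",
              toupper(x$mode), if (x$leak) " (leak)" else "",
              m$ann_accuracy, m$snn_accuracy, m$classifier_loss))
  cat(sprintf("  latency %.2f +/- %.2f us; %.1f input / %.1f total events per sample; %d no-decision\n",
              m$mean_latency_us, m$sd_latency_us, m$mean_input_events,
              m$mean_total_events, m$n_no_decision))
  invisible(x)
}

#' @export
glance.snn_experiment <- function(x, ...) x$metrics

#' @export
tidy.snn_experiment <- function(x, ...) x$per_sample
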