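#' Spiking ConvNet configuration and geometry
#'
#' The network topology is fixed: an `n x n` input feeding one convolution
#' layer of `length(bank)` feature maps (valid convolution, no padding, so
#' each map is `(n - k + 1)^2`), a subsampling pooling layer (factor
#' `pool`), a flatten module that relabels `(fm, x, y)` addresses into a
#' single linear index, and optionally a fully-connected spiking classifier.
#'
#' Convolution layer neurons share one kernel per feature map and use
#' symmetric thresholds with negative output spikes *disabled*: reaching
#' `c1_th_minus` resets the membrane silently. Classifier neurons are the
#' degenerate positive-only variant with threshold `fc_th`. The resting
#' level is 0 throughout. Leakage time constants are only engaged in
#' one-pass (OP) presentation; sample-by-sample (SBS) runs are leak-free.
#'
#' @param input_size input side `n` (square input).
#' @param kernel_size kernel side `k`.
#' @param bank a [quantize_kernels()] integer kernel bank (defaults to the
#'   18-kernel Gabor bank at `kernel_scale`).
#' @param kernel_scale integer scale applied to the unit-amplitude Gabor
#'   taps (default 1e7).
#' @param c1_th_plus,c1_th_minus convolution-layer thresholds (symmetric by
#'   default). The default 6e7 means a neuron fires after integrating ~6
#'   kernel-units of aligned evidence (the positive taps along one stripe of
#'   the default Gabor sum to ~5.8).
#' @param c1_tl_us,fc_tl_us leakage time constants, microseconds (OP mode).
#' @param c1_emit_negative emit `-1` spikes from the convolution layer
#'   (default `FALSE`, the configuration that keeps the model identical to
#'   its hardware implementations).
#' @param fc_th classifier threshold `TH_FC`; equal to the weight scale `K`
#'   (1e7) so that a learned weight of 1.0 fires in one spike.
#' @param pool pooling factor; `(n - k + 1)` must be divisible by it.
#' @return a `convnet_config` list with a `geometry` element
#'   (`c1_side`, `pooled_side`, `n_fm`, `flatten_size`).
#' @examples
#' cfg <- convnet_config(28)
#' cfg$geometry$flatten_size  # 2178
#' @export
convnet_config <- function(input_size, kernel_size = 7, bank = NULL,
                           kernel_scale = 1e7,
                           c1_th_plus = 6e7, c1_th_minus = -c1_th_plus,
                           c1_tl_us = 1.2e4, c1_emit_negative = FALSE,
                           fc_th = 1e7, fc_tl_us = 1.2e4, pool = 2) {
  if (is.null(bank)) {
    bank <- quantize_kernels(gabor_bank(size = kernel_size), kernel_scale)
  }
  kernel_size <- nrow(bank[[1L]])
  geom <- convnet_geometry(input_size, kernel_size, length(bank), pool)
  structure(list(input_size = as.integer(input_size),
                 kernel_size = as.integer(kernel_size),
                 bank = bank, kernel_scale = kernel_scale,
                 c1_th_plus = c1_th_plus, c1_th_minus = c1_th_minus,
                 c1_tl_us = c1_tl_us,
                 c1_emit_negative = isTRUE(c1_emit_negative),
                 fc_th = fc_th, fc_tl_us = fc_tl_us,
                 pool = as.integer(pool), geometry = geom),
            class = "convnet_config")
}

#' @rdname convnet_config
#' @param n_fm number of feature maps.
#' @export
convnet_geometry <- function(input_size, kernel_size, n_fm = 18L, pool = 2L) {
  c1_side <- input_size - kernel_size + 1L
  if (c1_side < 1L) {
    abort("kernel larger than input", class = "spikehist_config_error")
  }
  if (c1_side %% pool != 0L) {
    abort(sprintf(
      "feature-map side %d (= %d - %d + 1) is not divisible by the pooling factor %d",
      c1_side, input_size, kernel_size, pool), class = "spikehist_config_error")
  }
  pooled <- c1_side %/% pool
  list(c1_side = as.integer(c1_side), pooled_side = as.integer(pooled),
       n_fm = as.integer(n_fm),
       flatten_size = as.integer(n_fm * pooled * pooled))
}

# (k*k) x n_fm tap matrix, row-major within a kernel: row dy*k + dx + 1
# holds the tap at offset (dx, dy) = (x_in - x_out_topleft, y_in - y_out_topleft)
kernel_tap_matrix <- function(bank) {
  vapply(bank, function(m) as.vector(t(m)), numeric(length(bank[[1L]])))
}

#' Run the event-driven ConvNet over a stream
#'
#' Feeds every input event through the convolution layer (each event updates
#' the `k^2` neurons per feature map whose receptive field covers it),
#' pools emitted spikes by address remap (`(x, y) -> (x %/% pool, y %/%
#' pool)`), relabels them to flatten indices, and, when `weights` are given,
#' drives the fully-connected spiking classifier. Processing is event-driven
#' and depth-first; with the zero module delays used here this is exactly
#' the global earliest-first dispatch of [run_netlist()].
#'
#' @param stream an [event_stream()] matching `config$input_size`.
#' @param config a [convnet_config()].
#' @param leak apply the linear leakage (`TRUE` in OP mode, `FALSE` in SBS).
#' @param weights optional integer classifier weight matrix
#'   (`classes x flatten_size`), e.g. from [scale_weights()].
#' @param reset_times times (microseconds) at which all membranes are reset
#'   to rest (used for boundary resets in concatenated streams).
#' @param record_c1_vm also return the final per-feature-map membrane maps.
#' @return a list with `flatten` (tibble `t, idx, sign`; `idx` 0-based),
#'   `fc` (tibble `t, class`; 0-based class indices), event counts
#'   `n_input`, `n_c1`, `n_fc`, and optionally `c1_vm` (list of matrices).
#' @export
run_convnet <- function(stream, config, leak = FALSE, weights = NULL,
                        reset_times = numeric(), record_c1_vm = FALSE) {
  g <- ev_geometry(stream)
  if (g[["width"]] != config$input_size || g[["height"]] != config$input_size) {
    abort("stream geometry does not match the configured input size",
          class = "spikehist_config_error")
  }
  slope <- function(th, tl) if (leak) abs(th) / tl else 0
  res <- cpp_run_snn(stream$t, as.integer(stream$x), as.integer(stream$y),
                     stream$sign, config$input_size, config$input_size,
                     config$kernel_size, kernel_tap_matrix(config$bank),
                     config$c1_th_plus, config$c1_th_minus,
                     config$c1_emit_negative,
                     slope(config$c1_th_plus, config$c1_tl_us),
                     slope(config$c1_th_minus, config$c1_tl_us),
                     config$pool, weights, config$fc_th,
                     slope(config$fc_th, config$fc_tl_us),
                     slope(config$fc_th, config$fc_tl_us),
                     as.double(sort(reset_times)), TRUE, record_c1_vm)
  out <- list(flatten = tibble(t = res$flatten_t, idx = res$flatten_idx,
                               sign = res$flatten_sign),
              fc = tibble(t = res$fc_t, class = res$fc_class),
              n_input = res$n_input, n_c1 = res$n_c1, n_fc = res$n_fc)
  if (record_c1_vm) out$c1_vm <- res$c1_vm
  out
}

#' Run the spiking fully-connected classifier over recorded flatten events
#'
#' Drives one degenerate positive-only LIF neuron per class: a flatten event
#' with index `j` and sign `s` delivers `s * W[c, j + 1]` to every class
#' neuron `c`; a neuron reaching `th_fc` emits a class spike and resets.
#' Used when the front end has already been simulated and its flatten
#' record kept.
#'
#' @param events tibble with `t`, `idx` (0-based flatten index), `sign`.
#' @param weights integer weight matrix, `classes x h`.
#' @param th_fc classifier threshold `TH_FC`.
#' @param leak_slope leak rate in membrane units per microsecond (0 = no
#'   leak; the OP value is `th_fc / fc_tl_us`).
#' @param reset_times boundary reset instants (microseconds).
#' @return tibble of classifier output spikes: `t`, `class` (0-based).
#' @export
run_fc_layer <- function(events, weights, th_fc = 1e7, leak_slope = 0,
                         reset_times = numeric()) {
  res <- cpp_run_fc(events$t, as.integer(events$idx), events$sign,
                    weights, th_fc, leak_slope, leak_slope,
                    as.double(sort(reset_times)))
  tibble(t = res$fc_t, class = res$fc_class)
}

#' Event-driven subsampling (pooling)
#'
#' Two pooling semantics over event addresses. `remap` (the default used in
#' the network) forwards every event at the decimated address
#' `(x %/% factor, y %/% factor)` - a pure relabeling that conserves event
#' counts. `accumulate` keeps one signed counter per pooled address and
#' emits a single event (carrying the counter's sign) each time `m` net
#' input events have arrived there.
#'
#' @param events tibble with columns `t`, `x`, `y`, `sign` (optional `fm`).
#' @param factor pooling factor (default 2).
#' @param mode `"remap"` or `"accumulate"`.
#' @param m accumulate threshold (events per output), default 4.
#' @return tibble of pooled events in the same column layout.
#' @export
subsample_events <- function(events, factor = 2L,
                             mode = c("remap", "accumulate"), m = 4L) {
  mode <- match.arg(mode)
  events <- as_tibble(events)
  if (mode == "remap") {
    events$x <- events$x %/% factor
    events$y <- events$y %/% factor
    return(events)
  }
  stopifnot(m >= 1)
  fm <- if ("fm" %in% names(events)) events$fm else rep(0, nrow(events))
  key <- paste(fm, events$x %/% factor, events$y %/% factor)
  counter <- new.env(parent = emptyenv())
  keep <- logical(nrow(events))
  outsign <- numeric(nrow(events))
  for (i in seq_len(nrow(events))) {
    cur <- get0(key[i], envir = counter, ifnotfound = 0)
    cur <- cur + events$sign[i]
    if (cur >= m) {
      keep[i] <- TRUE; outsign[i] <- 1; cur <- cur - m
    } else if (cur <= -m) {
      keep[i] <- TRUE; outsign[i] <- -1; cur <- cur + m
    }
    assign(key[i], cur, envir = counter)
  }
  out <- events[keep, , drop = FALSE]
  out$x <- out$x %/% factor
  out$y <- out$y %/% factor
  out$sign <- outsign[keep]
  out
}

#' Flatten addressing
#'
#' Bijective relabeling between `(fm, x, y)` addresses on the pooled grid
#' and linear indices `fm * side^2 + y * side + x` (feature-map-major,
#' row-major; everything 0-based).
#'
#' @param fm,x,y 0-based feature-map and pooled-grid coordinates.
#' @param side pooled grid side.
#' @return `flatten_index()`: 0-based linear indices;
#'   `flatten_address()`: tibble `fm, x, y`.
#' @export
flatten_index <- function(fm, x, y, side) {
  stopifnot(all(x >= 0 & x < side), all(y >= 0 & y < side))
  fm * side^2 + y * side + x
}

#' @rdname flatten_index
#' @param idx 0-based linear flatten indices.
#' @export
flatten_address <- function(idx, side) {
  tibble(fm = idx %/% side^2,
         x = (idx %% side^2) %% side,
         y = (idx %% side^2) %/% side)
}
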