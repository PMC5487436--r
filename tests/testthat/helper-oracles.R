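# Independent oracles used across the suite. These deliberately avoid the
# package's event-driven code paths: the clock oracle integrates the
# membrane equation with 1-us Euler steps, and the convolution oracle is a
# direct dense evaluation.

# Clock-driven LIF reference: steps time at 1 us, applies the linear leak
# each step (clamped at rest), delivers inputs at their timestamps, checks
# thresholds like the model under test. Returns membrane and emitted spike
# at each event time.
clock_lif <- function(train, params, dt = 1) {
  vm <- params$memb_reset
  t_end <- if (nrow(train)) max(train$t) else 0
  slope_p <- params$slope_plus * dt
  slope_m <- params$slope_minus * dt
  out_vm <- numeric(nrow(train))
  out_spike <- numeric(nrow(train))
  ei <- 1L
  refrac_end <- -Inf
  t <- 0
  while (t <= t_end) {
    while (ei <= nrow(train) && train$t[ei] == t) {
      if (t >= refrac_end) {
        vm <- vm + train$sign[ei] * train$weight[ei]
        if (vm >= params$th_plus) {
          out_spike[ei] <- 1
          vm <- params$memb_reset
          refrac_end <- t + params$refractory_us
        } else if (vm <= params$th_minus) {
          if (params$emit_negative) out_spike[ei] <- -1
          vm <- params$memb_reset
          refrac_end <- t + params$refractory_us
        }
      }
      out_vm[ei] <- vm
      ei <- ei + 1L
    }
    # one Euler step of the leak
    if (vm > params$memb_reset) {
      vm <- max(params$memb_reset, vm - slope_p)
    } else if (vm < params$memb_reset) {
      vm <- min(params$memb_reset, vm + slope_m)
    }
    t <- t + dt
  }
  tibble::tibble(t = train$t, vm = out_vm, spike = out_spike)
}

# random single-neuron event train at integer microsecond times
random_train <- function(n_events, t_max, w_max, p_neg = 0.3) {
  t <- sort(sample.int(t_max, n_events, replace = TRUE)) - 1L
  tibble::tibble(t = t,
                 weight = runif(n_events, 0.05 * w_max, w_max),
                 sign = sample(c(1, -1), n_events, replace = TRUE,
                               prob = c(1 - p_neg, p_neg)))
}

# dense valid cross-correlation of a (signed) event-count image with a
# kernel, evaluated pointwise: out[yo, xo] = sum_k img[yo+dy, xo+dx] * K[dy, dx]
dense_xcorr <- function(img, K) {
  k <- nrow(K)
  side_y <- nrow(img) - k + 1L
  side_x <- ncol(img) - k + 1L
  out <- matrix(0, side_y, side_x)
  for (yo in seq_len(side_y)) {
    for (xo in seq_len(side_x)) {
      acc <- 0
      for (dy in seq_len(k)) {
        for (dx in seq_len(k)) {
          acc <- acc + img[yo + dy - 1L, xo + dx - 1L] * K[dy, dx]
        }
      }
      out[yo, xo] <- acc
    }
  }
  out
}

# signed event-count image from an event table (0-based coords)
event_count_image <- function(events, width, height) {
  img <- matrix(0, height, width)
  for (i in seq_len(nrow(events))) {
    img[events$y[i] + 1L, events$x[i] + 1L] <-
      img[events$y[i] + 1L, events$x[i] + 1L] + events$sign[i]
  }
  img
}

# random input event stream on a small geometry
random_stream <- function(n_events, n, t_max = 1000, signed = TRUE) {
  ev <- tibble::tibble(
    t = sort(sample.int(t_max, n_events, replace = TRUE)) - 1L,
    x = sample.int(n, n_events, replace = TRUE) - 1L,
    y = sample.int(n, n_events, replace = TRUE) - 1L,
    sign = if (signed) sample(c(1, -1), n_events, replace = TRUE)
           else rep(1, n_events))
  event_stream(ev, n, n, t_max)
}

# tiny labeled bar sample sets for end-to-end tests
tiny_bar_sets <- function(per_class = 12, seed = 5, encode = latency_encode) {
  imgs <- gen_bar_images(per_class = per_class, seed = seed)
  enc <- function(rows) sample_set(lapply(rows$image, encode), rows$label)
  list(train = enc(imgs[imgs$split == "train", ]),
       test = enc(imgs[imgs$split == "test", ]))
}
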