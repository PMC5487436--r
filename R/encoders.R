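#' Convert a grayscale image to a Poisson spike train
#'
#' Each pixel fires at a rate proportional to its intensity, rates are
#' capped so that no pixel expects more than `max_spikes_per_pixel` spikes,
#' and the *total* number of spikes of the input population is fixed at
#' `total_spikes` for the stimulus duration: the budget is allocated by one
#' multinomial draw over the normalized capped rates and timestamps are
#' drawn uniformly in `[0, duration_us)`. Defaults follow the standard
#' synthetic encoding: 255 us stimulus, at most 15 expected spikes per
#' pixel, 1,000 spikes in total.
#'
#' The capped expected rates solve a small water-filling problem: expected
#' counts are `min(c * I_j, max_spikes_per_pixel)` with `c` chosen so they
#' sum to `total_spikes`. The full budget is always drawn; on an image with
#' fewer than `total_spikes / max_spikes_per_pixel` nonzero pixels the cap
#' saturates and the rates flatten toward uniform over the active pixels.
#'
#' @param image numeric matrix, intensities in `[0, 255]` (row = y, column
#'   = x, origin top-left).
#' @param duration_us stimulus duration (default 255).
#' @param total_spikes total event budget (default 1000).
#' @param max_spikes_per_pixel cap on the per-pixel expectation (default 15).
#' @param seed optional integer; if supplied the encoder is reproducible.
#' @return an [event_stream()] with exactly `total_spikes` events, all
#'   `sign = +1`.
#' @export
poisson_encode <- function(image, duration_us = 255, total_spikes = 1000,
                           max_spikes_per_pixel = 15, seed = NULL) {
  stopifnot(is.matrix(image), duration_us > 0, total_spikes >= 0)
  if (any(image < 0 | image > 255)) {
    abort("image intensities must lie in [0, 255]",
          class = "spikehist_validation_error")
  }
  h <- nrow(image); w <- ncol(image)
  if (total_spikes == 0) return(event_stream(NULL, w, h, duration_us))
  I <- as.vector(image)  # column-major: index = y + h*(x-1) in 1-based terms
  if (all(I == 0)) {
    abort("all-zero image has no rate mass to allocate",
          class = "spikehist_validation_error")
  }
  expected <- waterfill_cap(I, total_spikes, max_spikes_per_pixel)
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  counts <- as.vector(rmultinom(1L, total_spikes, expected / sum(expected)))
  idx <- rep.int(seq_along(counts), counts)
  ys <- (idx - 1L) %% h          # 0-based row
  xs <- (idx - 1L) %/% h         # 0-based column
  t <- floor(runif(length(idx), 0, duration_us))
  event_stream(tibble(t = t, x = xs, y = ys, sign = 1),
               w, h, duration_us)
}

# expected counts min(c*I, cap) with sum(expected) = total: f(c) is
# continuous, piecewise-linear and increasing, so solve by bisection. If the
# cap binds on every nonzero pixel the rate shape saturates at uniform.
waterfill_cap <- function(I, total, cap) {
  pos <- I > 0
  e <- numeric(length(I))
  if (cap * sum(pos) <= total) {
    e[pos] <- cap
    return(e)
  }
  Ip <- I[pos]
  f <- function(c) sum(pmin(c * Ip, cap))
  c_hi <- cap / min(Ip)               # f(c_hi) = cap * npos > total
  c_root <- stats::uniroot(function(c) f(c) - total, c(0, c_hi),
                           tol = 1e-12)$root
  e[pos] <- pmin(c_root * Ip, cap)
  e
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
restore_rng_state <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Convert a grayscale image to an intensity-to-latency spike train
#'
#' One spike per nonzero pixel, with a delay decreasing linearly in
#' intensity: `t = round((1 - I/255) * duration_us)`. Maximum intensity
#' spikes at `t = 0`; zero-intensity pixels stay silent (the limiting delay
#' at the far end of the window is never emitted, which matches the low
#' per-sample input activity this encoding is chosen for). Deterministic.
#'
#' @inheritParams poisson_encode
#' @return an [event_stream()] with one `+1` event per nonzero pixel.
#' @export
latency_encode <- function(image, duration_us = 255) {
  stopifnot(is.matrix(image), duration_us > 0)
  if (any(image < 0 | image > 255)) {
    abort("image intensities must lie in [0, 255]",
          class = "spikehist_validation_error")
  }
  h <- nrow(image); w <- ncol(image)
  idx <- which(image > 0)
  if (!length(idx)) return(event_stream(NULL, w, h, duration_us))
  ys <- (idx - 1L) %% h
  xs <- (idx - 1L) %/% h
  t <- round((1 - image[idx] / 255) * duration_us)
  event_stream(tibble(t = t, x = xs, y = ys, sign = 1),
               w, h, duration_us)
}
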