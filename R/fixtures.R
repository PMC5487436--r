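#' Synthetic oriented-bar image set
#'
#' Generates labeled grayscale images of anti-aliased oriented bars, one
#' class per orientation, with small positional/angular jitter and additive
#' sensor-like noise (Gaussian, clipped at a black level so the background
#' stays mostly silent under latency encoding, as in digit images). Class
#' angles should match the Gabor bank orientations so that each class has a
#' dominant-responding feature map.
#'
#' @param angles class orientations in degrees (one class per angle). A bar
#'   at angle `theta` runs along the stripe direction of the Gabor kernel
#'   with the same `theta`.
#' @param n image side (default 28).
#' @param per_class samples per class (default 125).
#' @param bar_width,bar_len bar geometry in pixels.
#' @param noise_sd additive Gaussian noise, gray levels (default 10).
#' @param black_level intensities below this are clamped to 0 (default 10).
#' @param jitter_px,jitter_deg positional / angular jitter half-ranges.
#' @param train_frac fraction of each class recorded as the training split.
#' @param seed integer seed; same seed, same images, byte for byte.
#' @return tibble with `label` (0-based), `angle`, `split`
#'   (`"train"`/`"test"`), and `image` (list of `n x n` matrices in
#'   `[0, 255]`).
#' @export
gen_bar_images <- function(angles = c(0, 40, 80, 120), n = 28,
                           per_class = 125, bar_width = 3, bar_len = 18,
                           noise_sd = 10, black_level = 10, jitter_px = 2,
                           jitter_deg = 4, train_frac = 0.8, seed = 1) {
  stopifnot(!anyDuplicated(angles), per_class >= 1)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  n_train <- round(per_class * train_frac)
  rows <- purrr::map_dfr(seq_along(angles), function(ci) {
    purrr::map_dfr(seq_len(per_class), function(si) {
      ang <- angles[ci] + runif(1, -jitter_deg, jitter_deg)
      cx <- (n - 1) / 2 + runif(1, -jitter_px, jitter_px)
      cy <- (n - 1) / 2 + runif(1, -jitter_px, jitter_px)
      len <- bar_len * runif(1, 0.85, 1.15)
      img <- render_bar(n, cx, cy, ang, bar_width, len)
      img <- img + matrix(rnorm(n * n, 0, noise_sd), n, n)
      img[img < black_level] <- 0
      img[img > 255] <- 255
      tibble(label = ci - 1L, angle = angles[ci],
             split = if (si <= n_train) "train" else "test",
             image = list(round(img)))
    })
  })
  rows
}

# anti-aliased bar: intensity falls off linearly over one pixel at the
# edges; bar direction is the Gabor stripe direction (-sin, cos) for the
# same theta, x = column (right), y = row (down), 0-based centers
render_bar <- function(n, cx, cy, angle_deg, width, len) {
  th <- angle_deg * pi / 180
  ux <- -sin(th); uy <- cos(th)      # along the bar
  wx <- cos(th); wy <- sin(th)       # across the bar
  xs <- matrix(0:(n - 1), n, n, byrow = TRUE)
  ys <- matrix(0:(n - 1), n, n)
  dx <- xs - cx; dy <- ys - cy
  d_perp <- abs(dx * wx + dy * wy)
  d_long <- abs(dx * ux + dy * uy)
  soft <- function(d, half) pmin(1, pmax(0, half + 0.5 - d))
  255 * soft(d_perp, width / 2) * soft(d_long, len / 2)
}

#' Synthetic DVS-like event stream of a moving oriented bar
#'
#' Emulates an event camera watching an oriented bar sweep across the field
#' of view: the bar moves along its normal at constant speed (bouncing at
#' the borders), and each pixel integrates the local intensity change into
#' an accumulator that emits one event per `contrast` gray levels of change
#' - ON (`sign = +1`) for brightening, OFF (`sign = -1`) for darkening -
#' with a uniform timestamp jitter within the integration step. Uniform
#' background noise events are added at `noise_rate_hz` over the whole
#' array with random polarity.
#'
#' Event count scales with the swept path length (so with speed at fixed
#' duration), and a symmetric bar on a uniform background yields balanced
#' ON/OFF counts.
#'
#' @param angle bar orientation in degrees.
#' @param n field side in pixels.
#' @param duration_us recording length (default 20000, i.e. 20 ms).
#' @param speed_px_s sweep speed in pixels per second (default 600).
#' @param bar_width,bar_len bar geometry.
#' @param contrast gray levels of accumulated change per event (default 40).
#' @param dt_us integration step of the emulation (default 500).
#' @param noise_rate_hz background noise events per second (default 1000).
#' @param seed optional integer seed.
#' @return an [event_stream()].
#' @export
gen_dvs_stream <- function(angle, n = 28, duration_us = 20000,
                           speed_px_s = 600, bar_width = 3, bar_len = 18,
                           contrast = 40, dt_us = 500, noise_rate_hz = 1000,
                           seed = NULL) {
  if (!is.null(seed)) {
    old <- get_rng_state(); on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  th <- angle * pi / 180
  wx <- cos(th); wy <- sin(th)       # motion along the bar normal
  c0 <- (n - 1) / 2
  travel <- n / 2 - 4                # bounce amplitude, pixels
  phase <- runif(1, 0, 4 * travel)
  pos_at <- function(t_us) {
    # triangle wave in [-travel, travel] along the normal
    s <- speed_px_s * t_us / 1e6 + phase
    per <- 4 * travel
    ph <- s %% per
    if (ph < travel) ph
    else if (ph < 3 * travel) 2 * travel - ph
    else ph - 4 * travel
  }
  steps <- seq(0, duration_us, by = dt_us)
  accum <- matrix(0, n, n)
  prev <- NULL
  et <- list(); ex <- list(); ey <- list(); es <- list()
  for (i in seq_along(steps)) {
    off <- pos_at(steps[i])
    frame <- render_bar(n, c0 + off * wx, c0 + off * wy, angle,
                        bar_width, bar_len)
    if (!is.null(prev)) {
      accum <- accum + (frame - prev)
      n_ev <- floor(abs(accum) / contrast)
      fire <- which(n_ev > 0)
      if (length(fire)) {
        cnt <- n_ev[fire]
        sgn <- sign(accum[fire])
        accum[fire] <- accum[fire] - cnt * sgn * contrast
        reps <- rep.int(fire, cnt)
        et[[i]] <- floor(steps[i - 1L] + runif(length(reps), 0, dt_us))
        ex[[i]] <- (reps - 1L) %/% n   # column-major index -> x
        ey[[i]] <- (reps - 1L) %% n
        es[[i]] <- rep.int(sgn, cnt)
      }
    }
    prev <- frame
  }
  n_noise <- rpois(1L, noise_rate_hz * duration_us / 1e6)
  ev <- tibble(
    t = c(unlist(et), floor(runif(n_noise, 0, duration_us))),
    x = c(unlist(ex), floor(runif(n_noise, 0, n))),
    y = c(unlist(ey), floor(runif(n_noise, 0, n))),
    sign = c(unlist(es), sample(c(-1, 1), n_noise, replace = TRUE)))
  event_stream(ev, n, n, duration_us)
}

#' @rdname gen_dvs_stream
#' @param angles class orientations (one class per angle).
#' @param per_class samples per class.
#' @param ... passed to `gen_dvs_stream()`.
#' @return `gen_dvs_samples()`: a [sample_set()] of labeled recordings
#'   (speed and phase vary per sample through the seeded RNG).
#' @export
gen_dvs_samples <- function(angles = c(0, 40, 80, 120), per_class = 125,
                            seed = 1, ...) {
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  streams <- list(); labels <- integer()
  for (ci in seq_along(angles)) {
    for (si in seq_len(per_class)) {
      streams[[length(streams) + 1L]] <-
        gen_dvs_stream(angles[ci] + runif(1, -4, 4), ...)
      labels <- c(labels, ci - 1L)
    }
  }
  sample_set(streams, labels, class_count = length(angles))
}
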