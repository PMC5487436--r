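#' Gabor convolution kernels
#'
#' Generates the oriented Gabor kernels used to program the feature-map
#' layer. For integer pixel offsets `(x, y)` centered on 0,
#'
#' \deqn{g(x, y) = \exp\!\left(-\frac{x'^2 + \gamma^2 y'^2}{2\sigma^2}\right)
#'   \cos\!\left(\frac{2\pi x'}{\lambda} + \psi\right)}
#'
#' with \eqn{x' = x\cos\theta + y\sin\theta},
#' \eqn{y' = -x\sin\theta + y\cos\theta}. \eqn{\lambda} is the wavelength of
#' the sinusoidal factor, \eqn{\theta} the orientation of the normal to the
#' stripes (degrees), \eqn{\psi} the phase offset (radians), \eqn{\sigma}
#' the Gaussian width and \eqn{\gamma} the spatial aspect ratio. With
#' \eqn{\psi = 0} the kernel is even (`g(x,y) == g(-x,-y)`) and its center
#' value is exactly 1.
#'
#' The default bank uses 9 orientations (0 to 160 degrees in steps of 20)
#' times 2 phases (0 and 1.7), i.e. 18 kernels, with \eqn{\sigma = 4},
#' \eqn{\lambda = 8}, \eqn{\gamma = 0.5} on a 7x7 grid.
#'
#' @param theta orientation in degrees.
#' @param sigma Gaussian width (> 0).
#' @param lambda sinusoid wavelength (> 0).
#' @param psi phase offset in radians.
#' @param gamma spatial aspect ratio.
#' @param size kernel side `k`; taps are evaluated at integer offsets
#'   `-(k-1)/2 .. (k-1)/2` for odd `k` (row = y offset, column = x offset).
#' @return `gabor_kernel()`: a `size x size` numeric matrix.
#' @export
gabor_kernel <- function(theta, sigma = 4, lambda = 8, psi = 0,
                         gamma = 0.5, size = 7) {
  stopifnot(sigma > 0, lambda > 0, size >= 1)
  half <- (size - 1) / 2
  off <- seq_len(size) - 1 - floor(half)
  th <- theta * pi / 180
  xm <- matrix(off, size, size, byrow = TRUE)   # column -> x offset
  ym <- matrix(off, size, size)                 # row    -> y offset
  xp <- xm * cos(th) + ym * sin(th)
  yp <- -xm * sin(th) + ym * cos(th)
  exp(-(xp^2 + gamma^2 * yp^2) / (2 * sigma^2)) *
    cos(2 * pi * xp / lambda + psi)
}

#' @rdname gabor_kernel
#' @param theta_list,psi_list orientation (degrees) and phase (radians)
#'   lists; one kernel per combination, theta-major (all phases of the first
#'   orientation, then the next orientation, ...).
#' @return `gabor_bank()`: a `kernel_bank` - a list of matrices with a
#'   parameter table attribute (`bank_params()`).
#' @export
gabor_bank <- function(theta_list = seq(0, 160, by = 20),
                       psi_list = c(0, 1.7),
                       sigma = 4, lambda = 8, gamma = 0.5, size = 7) {
  stopifnot(length(theta_list) >= 1, length(psi_list) >= 1)
  grid <- expand.grid(psi = psi_list, theta = theta_list)[, 2:1]
  kernels <- purrr::map2(grid$theta, grid$psi,
                         ~gabor_kernel(.x, sigma, lambda, .y, gamma, size))
  structure(kernels, class = "kernel_bank",
            params = tibble(fm = seq_along(kernels) - 1L,
                            theta = grid$theta, psi = grid$psi,
                            sigma = sigma, lambda = lambda, gamma = gamma,
                            size = as.integer(size)))
}

#' @rdname gabor_kernel
#' @param bank a `kernel_bank`.
#' @export
bank_params <- function(bank) attr(bank, "params")

#' @export
print.kernel_bank <- function(x, ...) {
  p <- bank_params(x)
  cat(sprintf("<kernel_bank> %d kernels, %dx%d\n", length(x),
              p$size[1L], p$size[1L]))
  print(p, ...)
  invisible(x)
}

#' Quantize a kernel bank to integer taps
#'
#' Membrane arithmetic is integer, so real-valued kernels are scaled and
#' rounded before being loaded into the spiking convolution layer:
#' `round(tap * scale)`. The maximum per-tap quantization error after
#' de-scaling is `0.5 / scale`.
#'
#' @param bank a `kernel_bank` (or plain list of matrices).
#' @param scale positive scale constant; the default 1e7 puts a unit tap at
#'   the order of the classifier threshold.
#' @return a `kernel_bank` of integer-valued matrices with attributes
#'   `scale` and `max_quant_error` (largest `|tap - round(tap*scale)/scale|`).
#' @export
quantize_kernels <- function(bank, scale = 1e7) {
  stopifnot(scale > 0)
  q <- lapply(bank, function(k) round(k * scale))
  err <- max(purrr::map2_dbl(bank, q, ~max(abs(.x - .y / scale))), 0)
  structure(q, class = "kernel_bank", params = attr(bank, "params"),
            scale = scale, max_quant_error = err)
}
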