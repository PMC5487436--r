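#' Plot methods
#'
#' `autoplot.event_stream()` draws the classic AER raster: one point per
#' event at (time, linear pixel address), colored by polarity.
#' `autoplot.kernel_bank()` tiles the kernels as heat maps, one facet per
#' feature map. `autoplot.snn_experiment()` shows ANN vs SNN accuracy with
#' Wilson confidence intervals.
#'
#' @param object the object to plot.
#' @param level confidence level for accuracy intervals.
#' @param ... unused.
#' @return a ggplot.
#' @name spikehist-plots
NULL

#' @rdname spikehist-plots
#' @export
autoplot.event_stream <- function(object, ...) {
  g <- ev_geometry(object)
  df <- tibble(t = object$t,
               address = object$y * g[["width"]] + object$x,
               polarity = factor(ifelse(object$sign > 0, "ON", "OFF"),
                                 levels = c("ON", "OFF")))
  ggplot2::ggplot(df, ggplot2::aes(.data$t, .data$address,
                                   colour = .data$polarity)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.6) +
    ggplot2::labs(x = "time (us)", y = "pixel address") +
    ggplot2::theme_minimal()
}

#' @rdname spikehist-plots
#' @export
autoplot.kernel_bank <- function(object, ...) {
  p <- bank_params(object)
  df <- purrr::map_dfr(seq_along(object), function(i) {
    m <- object[[i]]
    k <- nrow(m)
    tibble(fm = sprintf("fm %02d: theta=%g psi=%g", i - 1L,
                        p$theta[i], p$psi[i]),
           x = rep(seq_len(k), each = k), y = rep(seq_len(k), k),
           tap = as.vector(m))
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$tap)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~fm) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @rdname spikehist-plots
#' @export
autoplot.snn_experiment <- function(object, level = 0.99, ...) {
  m <- object$metrics
  n <- nrow(object$per_sample)
  rows <- purrr::map_dfr(
    list(c("ANN (frames)", m$ann_accuracy), c("SNN", m$snn_accuracy)),
    function(r) {
      acc <- as.numeric(r[2L])
      ci <- confidence_interval(round(acc / 100 * n), n, level)
      tibble(classifier = r[1L], accuracy = acc,
             lo = 100 * ci[["lo"]], hi = 100 * ci[["hi"]])
    })
  ggplot2::ggplot(rows, ggplot2::aes(.data$classifier, .data$accuracy)) +
    ggplot2::geom_col(width = 0.6, fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                           width = 0.15) +
    ggplot2::labs(y = sprintf("accuracy %% (%.0f%% CI)", 100 * level),
                  x = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname spikehist-plots
#' @param curve a tibble from [accuracy_vs_fraction()].
#' @export
plot_accuracy_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(.data$fraction, .data$accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "% of input events per symbol", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
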