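# ggplot2 displays for the main result types.

#' Plot a current trace
#'
#' @param object An `sc_trace`.
#' @param max_points Traces longer than this are thinned for display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sc_trace <- function(object, max_points = 2e4, ...) {
  tt <- trace_time(object)
  y <- object$current
  if (length(y) > max_points) {
    keep <- unique(round(seq(1, length(y), length.out = max_points)))
    tt <- tt[keep]
    y <- y[keep]
  }
  ggplot2::ggplot(tibble::tibble(time = tt, current = y),
                  ggplot2::aes(x = .data$time, y = .data$current)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "current (pA)",
                  title = paste0(trace_voltage(object), " mV, ",
                                 trace_fs(object) / 1000, " kHz")) +
    ggplot2::theme_minimal()
}

#' Plot an amplitude histogram
#'
#' @param object An `amp_hist`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.amp_hist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = object$bin_hi[1] - object$bin_lo[1],
                      fill = "grey60") +
    ggplot2::labs(x = "amplitude (fraction of full open)", y = "density") +
    ggplot2::theme_minimal()
}

#' Plot a log-binned dwell-time histogram with an optional mixture fit
#'
#' Log-time abscissa, square-root-count ordinate; the fitted per-component
#' and total densities are overlaid when a fit is supplied.
#'
#' @param object A `dwell_hist`.
#' @param fit Optional `dwell_mixture_fit` for the same durations.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dwell_hist <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$mid, y = .data$sqrt_count)) +
    ggplot2::geom_col(fill = "grey70", width = object$bin_hi - object$bin_lo) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "dwell time (ms)", y = expression(sqrt(count))) +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    n <- attr(object, "n")
    tt <- exp(seq(log(min(object$bin_lo)), log(max(object$bin_hi)),
                  length.out = 200))
    bw <- log(10) / attr(object, "bins_per_decade")
    total <- rowSums(vapply(seq_len(fit$k), function(i)
      fit$areas[i] / fit$taus[i] * exp(-(tt - fit$t_dead) / fit$taus[i]),
      numeric(length(tt))))
    # expected sqrt-count density on the log axis
    dens <- sqrt(n * total * tt * bw)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(mid = tt, sqrt_count = dens),
      colour = "black")
  }
  p
}

#' Plot an MDS embedding of model-to-data distances
#'
#' @param object An `mds_embedding`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mds_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dim1, y = .data$dim2,
                                       label = .data$label)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "dimension 1", y = "dimension 2") +
    ggplot2::theme_minimal()
}

#' Po-voltage plot with an optional Boltzmann fit curve
#'
#' @param po_table Data frame with `voltage` (mV) and `po` (optionally a
#'   `class` column for colouring).
#' @param fit Optional `boltzmann_fit`.
#' @return A ggplot.
#' @export
plot_po_voltage <- function(po_table, fit = NULL) {
  po_table <- tibble::as_tibble(po_table)
  aes <- if ("class" %in% names(po_table))
    ggplot2::aes(x = .data$voltage, y = .data$po, colour = .data$class)
  else ggplot2::aes(x = .data$voltage, y = .data$po)
  p <- ggplot2::ggplot(po_table, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "voltage (mV)", y = "Po") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    vv <- seq(min(po_table$voltage), max(po_table$voltage), length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(voltage = vv, po = predict(fit, vv)),
      ggplot2::aes(x = .data$voltage, y = .data$po), inherit.aes = FALSE)
  }
  p
}
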