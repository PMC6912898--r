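#' Manhattan-style plot of a window statistic
#'
#' Windows are laid out in scaffold order along the x axis; an optional
#' horizontal line marks a threshold (e.g. the 99th-percentile outlier
#' threshold).
#'
#' @param stats window table from [compute_window_stats()].
#' @param stat column to plot (default `"fst"`).
#' @param threshold optional horizontal threshold line.
#' @return A ggplot object.
#' @export
plot_window_stat <- function(stats, stat = "fst", threshold = NULL) {
  dat <- stats |>
    dplyr::arrange(.data$scaffold, .data$window_index) |>
    dplyr::mutate(idx = dplyr::row_number(),
                  scaffold = factor(.data$scaffold,
                                    levels = unique(.data$scaffold)))
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$idx,
                                         y = .data[[stat]],
                                         colour = .data$scaffold)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::labs(x = "window (genome order)", y = stat) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @export
autoplot.elevated_windows <- function(object, stat = "fst", ...) {
  thr <- object$thresholds[[if (stat == "df") "df" else "fst"]]
  p <- plot_window_stat(object$retained, stat, threshold = thr)
  if (nrow(object$intersection) > 0) {
    dat <- object$retained |>
      dplyr::arrange(.data$scaffold, .data$window_index) |>
      dplyr::mutate(idx = dplyr::row_number())
    hit <- dat[paste(dat$scaffold, dat$window_index) %in%
                 paste(object$intersection$scaffold,
                       object$intersection$window_index), ]
    p <- p + ggplot2::geom_point(data = hit, colour = "orange", size = 1.6,
                                 shape = 8)
  }
  p
}

#' @export
autoplot.abc_choice <- function(object, ...) {
  ggplot2::ggplot(object$posterior,
                  ggplot2::aes(x = .data$scenario, y = .data$posterior)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "posterior probability") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.abc_posterior <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$parameter, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lower,
                                          ymax = .data$upper)) +
    ggplot2::scale_y_log10() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior median (95% interval)") +
    ggplot2::theme_minimal()
}
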