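#' Plot a separability result against its shuffle null
#'
#' Histogram of the label-shuffle null accuracies with the observed accuracy
#' marked, the standard display for a permutation-tested statistic.
#'
#' @param object An `ecog_separability` with a computed null.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecog_separability
#' @export
autoplot.ecog_separability <- function(object, ...) {
  if (is.null(object$null_accuracies)) {
    abort("result carries no null distribution to plot")
  }
  df <- tibble(null = 100 * object$null_accuracies)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = 100 * object$accuracy,
                        linewidth = 1) +
    ggplot2::labs(
      x = "kNN accuracy (%)", y = "shuffles",
      title = sprintf(
        "observed %.1f%% vs shuffle null %.1f%% (p = %.3g)",
        100 * object$accuracy, 100 * object$null_mean, object$empirical_p
      )
    ) +
    ggplot2::theme_minimal()
}

#' Plot a component sensitivity analysis
#'
#' Knockout mode: accuracy after removing each component, with the full-space
#' accuracy as a reference line. Incremental mode: accuracy as a function of
#' the number of leading components included. Variance explained is overlaid
#' when available.
#'
#' @param object An `ecog_sensitivity` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ecog_sensitivity
#' @export
autoplot.ecog_sensitivity <- function(object, ...) {
  df <- tidy(object)
  xvar <- if (object$mode == "knockout") "component" else "n_components"
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]],
                                        y = 100 * .data$accuracy)) +
    ggplot2::geom_point(colour = "firebrick", size = 2) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_hline(yintercept = 100 * object$full_acc,
                        linetype = "dashed") +
    ggplot2::labs(
      x = if (object$mode == "knockout") "removed component"
          else "components included",
      y = "kNN accuracy (%)"
    ) +
    ggplot2::theme_minimal()
  vcol <- intersect(c("var_explained", "cum_var_explained"), names(df))
  if (length(vcol) && !all(is.na(df[[vcol]]))) {
    p <- p + ggplot2::geom_point(
      ggplot2::aes(y = 100 * .data[[vcol]]), colour = "black", shape = 1
    )
  }
  p
}

#' Plot a component-space trajectory around stimulus pulses
#'
#' Shows the "wander" of the cross-channel activity distribution in the
#' plane of two components: spontaneous samples before the pulse in black,
#' post-stimulus samples coloured by latency, illustrating the excursion and
#' the return toward the spontaneous distribution after roughly 200 ms.
#'
#' @param scores An `ecog_scores` series.
#' @param events Stimulus event tibble; the first event inside the series is
#'   used unless `event_time_s` is given.
#' @param event_time_s Optional explicit pulse time (s).
#' @param components Length-2 integer, which components to plot (default 1:2).
#' @param pre_ms,post_ms Time before/after the pulse to display (ms).
#' @return A ggplot object.
#' @export
plot_pc_trajectory <- function(scores, events, event_time_s = NULL,
                               components = c(1L, 2L),
                               pre_ms = 200, post_ms = 300) {
  stopifnot(inherits(scores, "ecog_scores"), length(components) == 2L)
  t0 <- event_time_s %||% events$time_s[1L]
  fs <- scores$fs_hz
  s0 <- time_to_sample(t0, fs, scores$t0_s)
  idx <- seq.int(
    max(1L, s0 - round(pre_ms * fs / 1000)),
    min(ncol(scores$scores), s0 + round(post_ms * fs / 1000))
  )
  df <- tibble(
    latency_ms = (idx - s0) * 1000 / fs,
    x = scores$scores[components[1L], idx],
    y = scores$scores[components[2L], idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(
      data = df[df$latency_ms < 0, ], colour = "black", alpha = 0.6
    ) +
    ggplot2::geom_path(
      data = df[df$latency_ms >= 0, ],
      ggplot2::aes(colour = .data$latency_ms)
    ) +
    ggplot2::geom_point(data = df[df$latency_ms == 0, ],
                        colour = "blue", size = 2) +
    ggplot2::scale_colour_viridis_c(name = "latency (ms)") +
    ggplot2::labs(
      x = sprintf("PC%d score", components[1L]),
      y = sprintf("PC%d score", components[2L])
    ) +
    ggplot2::theme_minimal()
}
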