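#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clock model
#'
#' @param x A `clock_model`.
#' @param ... Unused.
#' @return One-row tibble with `shift`, `drift`, `quality`, `n_windows`.
#' @method tidy clock_model
#' @export
tidy.clock_model <- function(x, ...) {
  tibble::tibble(shift = x$shift, drift = x$drift, quality = x$quality,
                 n_windows = nrow(x$windows))
}

#' Glance at an arousal model
#'
#' @param x An `arousal_model`.
#' @param ... Unused.
#' @return One-row tibble with parameter count, receptive field and trained
#'   phases.
#' @method glance arousal_model
#' @export
glance.arousal_model <- function(x, ...) {
  tibble::tibble(
    n_parameters = sum(unlist(tree_map(length, x$params))),
    receptive_field_s = receptive_field_seconds(x$cfg),
    wiring = x$cfg$wiring,
    trained = paste(x$trained, collapse = "+"))
}

#' Tidy an annotation set into its event table
#'
#' @param x An `annotation_set`.
#' @param ... Unused.
#' @return The event tibble with an added `end` column.
#' @method tidy annotation_set
#' @export
tidy.annotation_set <- function(x, ...) {
  dplyr::mutate(x$events, end = .data$onset + .data$duration)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a probability series with optional detected events
#'
#' @param object A `probability_series`.
#' @param threshold Optional threshold; when given, detected events are
#'   shaded.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probability_series
#' @export
autoplot.probability_series <- function(object, threshold = NULL, ...) {
  df <- tibble::tibble(
    time = object$start + (seq_along(object$values) - 1) / object$rate,
    p = object$values)
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$p)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "Time (s)", y = "Arousal probability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    ev <- probability_to_events(object, threshold)
    if (nrow(ev)) {
      gg <- gg + ggplot2::geom_rect(
        data = ev, inherit.aes = FALSE,
        ggplot2::aes(xmin = .data$onset, xmax = .data$onset + .data$duration,
                     ymin = 0, ymax = 1),
        fill = "tomato", alpha = 0.2)
    }
    gg <- gg + ggplot2::geom_hline(yintercept = threshold,
                                   linetype = "dashed")
  }
  gg
}

#' Plot a waveform segment
#'
#' @param object A `waveform`.
#' @param from,to Optional time range in seconds.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot waveform
#' @export
autoplot.waveform <- function(object, from = NULL, to = NULL, ...) {
  t <- wf_times(object)
  keep <- rep(TRUE, length(t))
  if (!is.null(from)) keep <- keep & t >= from
  if (!is.null(to)) keep <- keep & t <= to
  df <- tibble::tibble(time = t[keep], value = object$samples[keep])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "Time (s)", y = object$label) +
    ggplot2::theme_minimal()
}
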