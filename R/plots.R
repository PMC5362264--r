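# ggplot2 visualisations for the main result types.

#' Plot a linescan trace
#'
#' Single traces are drawn as a line; averaged traces additionally show a
#' +/- SD ribbon, with the membrane peak and the cytosol quantification
#' window marked.
#'
#' @param object a `linescan` (from [extract_linescan()],
#'   [normalize_trace()] or [align_and_average()])
#' @param ... unused
#' @return a ggplot object
#' @method autoplot linescan
#' @export
autoplot.linescan <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$index, y = .data$value))
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd),
      fill = "grey80")
  }
  p <- p + ggplot2::geom_line(colour = "darkgreen")
  peak <- attr(object, "peak_index")
  if (!is.null(peak)) {
    p <- p +
      ggplot2::geom_vline(xintercept = peak, linetype = "dashed") +
      ggplot2::annotate("rect", xmin = peak + 10, xmax = peak + 14,
                        ymin = -Inf, ymax = Inf, alpha = 0.15,
                        fill = "steelblue")
  }
  p + ggplot2::labs(
    x = "position along scan (px, outside → inside)",
    y = if (isTRUE(attr(object, "normalized")))
      "normalized intensity" else "intensity",
    title = "Linescan across the plasma membrane")
}

#' Plot a FRAP recovery trace
#'
#' @param object a [recovery_trace()]
#' @param ... unused
#' @return a ggplot object
#' @method autoplot recovery_trace
#' @export
autoplot.recovery_trace <- function(object, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$value))
  if ("sd" %in% names(object)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$sd,
                   ymax = .data$value + .data$sd), fill = "grey80")
  }
  p + ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time after bleach (s)",
                  y = "normalized intensity",
                  title = "FRAP recovery")
}

#' Plot a hyperbolic FRAP fit over its trace
#'
#' @param object a [fit_hyperbola()] result
#' @param ... unused
#' @return a ggplot object
#' @method autoplot frap_fit
#' @export
autoplot.frap_fit <- function(object, ...) {
  tr <- object$trace
  grid <- tibble(time = seq(min(tr$time), max(tr$time), length.out = 200))
  grid$value <- predict(object, grid)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point(size = 0.8, colour = "grey40") +
    ggplot2::geom_line(data = grid, colour = "red") +
    ggplot2::geom_vline(xintercept = object$t_half, linetype = "dashed") +
    ggplot2::labs(
      x = "time after bleach (s)", y = "normalized intensity",
      title = sprintf("Hyperbolic recovery fit: t½ = %.1f s",
                      object$t_half))
}

#' Bar plot of condition summaries
#'
#' Means +/- SEM per condition with significance stars against the
#' reference, the standard presentation for periphery/cytosol ratios and
#' binding quantifications.
#'
#' @param summary output of [summarize_conditions()]
#' @return a ggplot object
#' @export
plot_condition_summary <- function(summary) {
  check_that(is.data.frame(summary) &&
               all(c("condition", "mean", "sem") %in% names(summary)),
             "`summary` must come from summarize_conditions()")
  p <- ggplot2::ggplot(
    summary,
    ggplot2::aes(x = .data$condition, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem), width = 0.2) +
    ggplot2::labs(x = NULL, y = "mean ± SEM")
  if ("stars" %in% names(summary)) {
    lab <- summary[!is.na(summary$stars), ]
    p <- p + ggplot2::geom_text(
      data = lab,
      ggplot2::aes(label = .data$stars,
                   y = .data$mean + 2 * dplyr::coalesce(.data$sem, 0)),
      vjust = 0)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
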