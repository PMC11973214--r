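#' Scatter plot of a regional score against age with the fitted line
#'
#' One panel per region: score versus chronological age, the least-squares
#' line and its 95\% confidence band, annotated with the fit R-squared.
#'
#' @param scores Data.frame with \code{age}, \code{region} and the score
#'   column (e.g. the \code{scores.csv} output of \code{\link{runPipeline}}).
#' @param score Score column to plot.
#' @return A ggplot object.
#' @export
plotScoreVsAge <- function(scores, score = c("AS", "ADS")) {
  score <- if (length(score) > 1L) match.arg(score) else score
  r2 <- vapply(split(scores, scores$region), function(s)
    fitScoreVsAge(s, score)$r2, numeric(1))
  lab <- data.frame(region = names(r2),
                    label = sprintf("R² = %.2f", r2))
  ggplot2::ggplot(scores,
                  ggplot2::aes(x = .data[["age"]], y = .data[[score]])) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, level = 0.95,
                         color = "red", linewidth = 0.6) +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data[["label"]]),
                       x = -Inf, y = Inf, hjust = -0.1, vjust = 1.5,
                       inherit.aes = FALSE, size = 3) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = "chronological age (years)", y = score) +
    ggplot2::theme_bw()
}

#' Boxplots of age-adjusted scores by clinical group
#'
#' @param scores Data.frame with \code{group}, \code{region} and the
#'   (typically age-adjusted) score column.
#' @param score Score column to plot.
#' @return A ggplot object.
#' @export
plotGroupScores <- function(scores, score) {
  stopifnot(score %in% names(scores))
  scores$group <- factor(as.character(scores$group),
                         levels = intersect(.GROUP_LEVELS,
                                            unique(scores$group)))
  ggplot2::ggplot(scores, ggplot2::aes(x = .data[["group"]],
                                       y = .data[[score]])) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::facet_wrap(~region, scales = "free_y") +
    ggplot2::labs(x = NULL, y = score) +
    ggplot2::theme_bw()
}

#' @importFrom ggplot2 .data
NULL
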