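#' Plot parameter estimates with standard-error bars
#'
#' Bar chart of the five model parameters per condition, with one standard
#' error above and below each estimate — the conventional display for the
#' cooperation parameter and the three punishment parameters plus bias.
#'
#' @param object A `cp_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cp_fit
#' @export
autoplot.cp_fit <- function(object, ...) {
  est <- tidy(object)
  est$parameter <- factor(est$parameter, levels = cp_param_names())
  ggplot2::ggplot(est, ggplot2::aes(x = .data$parameter,
                                    y = .data$estimate,
                                    fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$estimate - .data$std.error),
                   ymax = pmin(1, .data$estimate + .data$std.error)),
      position = ggplot2::position_dodge(width = 0.8), width = 0.25
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "Estimate (probability)",
                  fill = "Condition") +
    ggplot2::theme_minimal()
}

#' Plot a test battery's effect sizes
#'
#' @param object A `cp_report`.
#' @param ... Unused.
#' @return A ggplot object: Cohen's w per restriction test, annotated with
#'   significance at the 0.05 level.
#' @method autoplot cp_report
#' @export
autoplot.cp_report <- function(object, ...) {
  tests <- tidy(object)
  tests$significant <- tests$p.value < 0.05
  ggplot2::ggplot(tests, ggplot2::aes(x = stats::reorder(.data$parameter,
                                                         .data$w),
                                      y = .data$w,
                                      fill = .data$significant)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Cohen's w", fill = "p < 0.05") +
    ggplot2::theme_minimal()
}
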