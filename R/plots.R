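# ggplot2 autoplot methods for the fitted objects

#' @export
autoplot.hurst_fit <- function(object, ...) {
  df <- tidy.hurst_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$window_size), log(.data$mean_rs))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log window size", y = "log mean R/S",
                  title = sprintf("R/S scaling, H = %.3f", object$exponent)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.higuchi_fit <- function(object, ...) {
  df <- tidy.higuchi_fit(object)
  ggplot2::ggplot(df, ggplot2::aes(log(.data$k), log(.data$mean_length))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "grey40") +
    ggplot2::labs(x = "log k", y = "log mean curve length",
                  title = sprintf("Higuchi scaling, D = %.3f", object$dimension)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.threshold_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(.data$threshold, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "proportional threshold (%)", y = object$measure,
                  title = sprintf("%s curve, integral = %.2f",
                                  object$measure, object$integral)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.overall_pca <- function(object, ...) {
  df <- object$scores
  if ("condition" %in% names(df) && !all(is.na(df$condition))) {
    ggplot2::ggplot(df, ggplot2::aes(.data$condition, .data$pc1)) +
      ggplot2::geom_boxplot(outlier.shape = NA) +
      ggplot2::geom_jitter(width = 0.1, alpha = 0.6) +
      ggplot2::labs(y = "overall complexity (PC1 score)",
                    title = sprintf("PC1 explains %.1f%% of metric variance",
                                    100 * object$variance_explained)) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(tibble::tibble(component = seq_along(object$explained_curve),
                                   cumulative = object$explained_curve),
                    ggplot2::aes(.data$component, .data$cumulative)) +
      ggplot2::geom_col() +
      ggplot2::labs(y = "cumulative variance explained") +
      ggplot2::theme_minimal()
  }
}
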