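#' Plot methods
#'
#' `autoplot()` methods for the main result types: Kaplan-Meier curves
#' ([kaplan_meier()]), time-dependent ROC curves ([time_dependent_auc()])
#' and degree distributions with their log-log power-law fit
#' ([degree_distribution_fit()]).
#'
#' @param object a result object.
#' @param ... ignored.
#' @return A ggplot object.
#' @name cerna-plots
NULL

#' @rdname cerna-plots
#' @method autoplot cerna_km
#' @export
autoplot.cerna_km <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(group = unique(object$group), time = 0, estimate = 1),
    tibble::as_tibble(object)[, c("group", "time", "estimate")]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$estimate,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Time (days)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @rdname cerna-plots
#' @method autoplot cerna_auc
#' @export
autoplot.cerna_auc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("Time-dependent ROC (t = %.3g), AUC = %.3f",
                      object$horizon, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname cerna-plots
#' @method autoplot cerna_degree_dist
#' @export
autoplot.cerna_degree_dist <- function(object, ...) {
  h <- object$histogram[object$histogram$degree > 0, , drop = FALSE]
  p <- ggplot2::ggplot(h, ggplot2::aes(x = .data$degree, y = .data$n)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Degree", y = "Frequency") +
    ggplot2::theme_minimal()
  if (isTRUE(object$fit_available)) {
    p <- p + ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                                  linewidth = 0.5, colour = "firebrick") +
      ggplot2::labs(subtitle = sprintf("slope = %.2f, R^2 = %.3f",
                                       object$exponent, object$r_squared))
  }
  p
}
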