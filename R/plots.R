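# ggplot2 visualisations for result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Plot per-repeat AUCs of a repeated-subsampling evaluation
#'
#' @param object A `ps_eval` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ps_eval <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc)) +
    ggplot2::geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = object$mean_auc, linetype = 2) +
    ggplot2::labs(
      x = "AUC per repeat", y = "repeats",
      title = sprintf("Repeated negative subsampling: mean AUC %.3f over %d repeats",
                      object$mean_auc, object$repeats)) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation AUCs
#'
#' @param object A `truncps_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.truncps_cv <- function(object, ...) {
  ggplot2::ggplot(object$per_fold,
                  ggplot2::aes(x = factor(.data$fold), y = .data$auc)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = 2) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "fold", y = "held-out AUC",
                  title = sprintf("%d-fold CV, mean AUC %.3f",
                                  object$k, object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Standardized coefficients of a DosPS model
#'
#' @param object A `dosps_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.dosps_model <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "(Intercept)", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0) +
    ggplot2::labs(x = NULL, y = "standardized weight",
                  title = "DosPS logistic-regression coefficients") +
    ggplot2::theme_minimal()
}

#' Score vs covariate with the rolling-median trend
#'
#' Visualises the distance-to-median normalization: raw scores against the
#' confounding covariate with the rolling median overlaid.
#'
#' @param data Output of [dm_normalize()].
#' @param score,covariate Column names used in the normalization.
#' @return A ggplot.
#' @export
plot_dm_series <- function(data, score, covariate) {
  ggplot2::ggplot(data, ggplot2::aes(x = .data[[covariate]])) +
    ggplot2::geom_point(ggplot2::aes(y = .data[[score]]),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rps), colour = "firebrick") +
    ggplot2::labs(y = score,
                  title = "Rolling-median trend removed by DM normalization") +
    ggplot2::theme_minimal()
}
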