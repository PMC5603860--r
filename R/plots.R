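# ggplot2 views of the main result types.

#' Williams plot (standardized residual vs leverage)
#'
#' Training compounds are drawn with the h* vertical guide and the
#' +/- 2.5 standardized-residual horizontal guides delimiting the
#' applicability domain; an optional second table (e.g. screening
#' candidates) is overlaid at residual 0.
#'
#' @param model A `qsar_mlr` model.
#' @param newdata Optional descriptor table of external compounds to
#'   overlay (their residuals are unknown and drawn at 0).
#' @return A ggplot object.
#' @export
plot_williams <- function(model, newdata = NULL) {
  ad <- applicability_domain(model)
  df <- dplyr::mutate(ad$records, set = "training")
  if (!is.null(newdata)) {
    ext <- applicability_domain(model, newdata)$records
    ext <- dplyr::mutate(ext, std_residual = 0, set = "external")
    df <- dplyr::bind_rows(df, ext)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$leverage,
                                   y = .data$std_residual,
                                   colour = .data$set)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = ad$h_star, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-2.5, 2.5), linetype = "dotted") +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = sprintf("Williams plot (h* = %.3f)", ad$h_star)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_mlr <- function(object, ...) {
  df <- augment(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$observed, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "observed pIC50", y = "fitted pIC50",
                  title = sprintf("MLR fit (R2 = %.3f, Q2 = %.3f)",
                                  object$stats$r2, object$stats$q2_loo)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_ga <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"generation",
                            names_to = "series", values_to = "rmscv")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$generation, y = .data$rmscv,
                                   colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "LOO RMScv", title = "GA fitness history") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_yrand <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(x = .data$r2)) +
    ggplot2::geom_histogram(bins = 20, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$original_r2,
                        colour = "red", linetype = "dashed") +
    ggplot2::labs(x = expression(shuffled ~ R^2),
                  title = "Y-randomization: shuffled vs original R2") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.qsar_ad <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$leverage, y = .data$std_residual)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$inside)) +
    ggplot2::geom_vline(xintercept = object$h_star, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = c(-2.5, 2.5), linetype = "dotted") +
    ggplot2::labs(x = "leverage h", y = "standardized residual") +
    ggplot2::theme_minimal()
}
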