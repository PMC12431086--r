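#' Plot methods
#'
#' ggplot2 `autoplot()` methods for the main result types: predicted-versus-
#' measured regression, per-category bias, and precision-recall curves.
#'
#' @param object a fitted result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name autoplot-methods
NULL

#' @rdname autoplot-methods
#' @export
autoplot.area_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$measured, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "#2166ac") +
    ggplot2::labs(
      x = "measured floral area (cm²)",
      y = "predicted floral area (cm²)",
      title = sprintf("R² = %.3f, RMSE = %.2f cm² (n = %d)",
                      object$r2, object$rmse, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.category_evaluation <- function(object, ...) {
  ggplot2::ggplot(object$residuals,
                  ggplot2::aes(x = .data$group, y = .data$residual)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_boxplot(outlier.alpha = 0.5, fill = "#d1e5f0") +
    ggplot2::labs(
      x = paste(object$factor, "category"),
      y = "predicted − measured (cm²)",
      title = sprintf("bias by %s: F(%d, %d) = %.2f, p = %.3f",
                      object$factor, object$anova$df_between,
                      object$anova$df_within, object$anova$f_stat,
                      object$anova$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-methods
#' @export
autoplot.ap_result <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$recall)) +
    ggplot2::geom_step(ggplot2::aes(y = .data$precision), colour = "grey50") +
    ggplot2::geom_step(ggplot2::aes(y = .data$precision_envelope),
                       colour = "#b2182b") +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "recall", y = "precision",
      title = sprintf("AP@%.2f = %.4f", object$iou_threshold, object$ap)
    ) +
    ggplot2::theme_minimal()
}
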