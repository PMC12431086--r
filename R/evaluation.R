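#' Mean bias of predicted versus measured areas
#'
#' Bias is the mean of the per-image differences `predicted - measured`
#' (cm^2); positive bias means over-estimation. Zero for identical vectors,
#' and translation-equivariant: shifting every prediction by `c` shifts the
#' bias by `c`.
#'
#' @param predicted,measured numeric vectors of equal length (n >= 1).
#' @param group optional category label carried into the result.
#' @return A one-row tibble: `group` (if given), `bias`, `n`.
#' @examples
#' area_bias(c(3, 5), c(1, 2))   # 2.5
#' @export
area_bias <- function(predicted, measured, group = NULL) {
  if (length(predicted) != length(measured)) {
    pp_abort("predicted and measured must have equal length", "parameter")
  }
  if (length(predicted) == 0L) pp_abort("bias needs at least one pair", "parameter")
  out <- tibble(bias = mean(predicted - measured), n = length(predicted))
  if (!is.null(group)) out <- bind_cols(tibble(group = group), out)
  out
}

#' Regression accuracy of predicted versus measured areas
#'
#' Fits ordinary least squares of `predicted` on `measured` and reports the
#' fit's coefficient of determination (R^2), slope and intercept, together
#' with the root mean squared error of the raw pairs,
#' `RMSE = sqrt(mean((predicted - measured)^2))`. RMSE is deliberately
#' computed on identity residuals, not regression residuals: it measures the
#' estimator's disagreement with ground truth, while R^2 describes the
#' strength of the linear relationship.
#'
#' @param predicted,measured numeric vectors (n >= 2); `measured` must not be
#'   constant.
#' @return An object of class `area_regression`: `r2`, `rmse`, `slope`,
#'   `intercept`, `n`, and the underlying `lm` fit.
#' @export
regression_metrics <- function(predicted, measured) {
  if (length(predicted) != length(measured)) {
    pp_abort("predicted and measured must have equal length", "parameter")
  }
  n <- length(predicted)
  if (n < 2L) pp_abort("regression needs at least two pairs", "parameter")
  if (sd(measured) == 0) {
    pp_abort("measured values are constant; regression is degenerate",
             "degenerate_regression")
  }
  fit <- lm(predicted ~ measured)
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- sum((predicted - mean(predicted))^2)
  structure(
    list(
      r2 = 1 - ss_res / ss_tot,
      rmse = sqrt(mean((predicted - measured)^2)),
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      n = n,
      fit = fit,
      data = tibble(predicted = predicted, measured = measured)
    ),
    class = "area_regression"
  )
}

#' @export
print.area_regression <- function(x, ...) {
  cat(sprintf("R^2 = %.4f, RMSE = %.3f cm^2 (slope %.3f, intercept %.3f, n = %d)\n",
              x$r2, x$rmse, x$slope, x$intercept, x$n))
  invisible(x)
}

#' @export
glance.area_regression <- function(x, ...) {
  tibble(r2 = x$r2, rmse = x$rmse, slope = x$slope,
         intercept = x$intercept, n = x$n)
}

#' @export
tidy.area_regression <- function(x, ...) {
  tibble(term = c("intercept", "slope"), estimate = c(x$intercept, x$slope))
}

#' One-way analysis of variance
#'
#' Classic fixed-effects one-way ANOVA: the total sum of squares about the
#' grand mean is decomposed into between-group and within-group parts,
#' `F = MS_between / MS_within` with `df = (k - 1, n - k)`, and the p-value is
#' the upper tail of the F distribution (the regularized incomplete beta
#' form, as computed by [stats::pf()]).
#'
#' Degenerate inputs follow explicit conventions rather than returning NaN:
#' when every value is identical (both mean squares zero) F is 0 with flag
#' `"all_identical"` and p = 1; when groups are internally constant but their
#' means differ (MS_within = 0, MS_between > 0) F is `Inf` with flag
#' `"infinite_f"` and p = 0.
#'
#' @param groups named list of numeric vectors (k >= 2 non-empty groups,
#'   n - k >= 1), or a data frame with columns `value` and `group`.
#' @return An object of class `anova_result`: `f_stat`, `df_between`,
#'   `df_within`, `p_value`, `group_means`, `ss_between`, `ss_within`,
#'   `ss_total`, `n`, `flag`.
#' @examples
#' one_way_anova(list(a = c(1, 2), b = c(3, 4)))  # F = 8 on (1, 2) df
#' @export
one_way_anova <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("value", "group") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (length(groups) < 2L) pp_abort("ANOVA needs at least two groups", "parameter")
  sizes <- lengths(groups)
  if (any(sizes == 0L)) pp_abort("every group must be non-empty", "parameter")
  values <- unlist(groups, use.names = FALSE)
  if (anyNA(values)) pp_abort("groups must not contain NA", "parameter")
  n <- length(values)
  k <- length(groups)
  if (n - k < 1L) pp_abort("ANOVA needs n - k >= 1 residual df", "parameter")

  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(sizes * (means - grand)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((groups[[i]] - means[i])^2)
  }, numeric(1)))
  df_b <- k - 1L
  df_w <- n - k
  ms_b <- ss_between / df_b
  ms_w <- ss_within / df_w

  flag <- NA_character_
  if (ms_w == 0 && ms_b == 0) {
    f <- 0; p <- 1; flag <- "all_identical"
  } else if (ms_w == 0) {
    f <- Inf; p <- 0; flag <- "infinite_f"
  } else {
    f <- ms_b / ms_w
    p <- pf(f, df_b, df_w, lower.tail = FALSE)
  }
  structure(
    list(f_stat = f, df_between = df_b, df_within = df_w, p_value = p,
         group_means = means, ss_between = ss_between, ss_within = ss_within,
         ss_total = ss_between + ss_within, n = n, flag = flag),
    class = "anova_result"
  )
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f_stat, x$p_value))
  if (!is.na(x$flag)) cat("flag:", x$flag, "\n")
  invisible(x)
}

#' @export
glance.anova_result <- function(x, ...) {
  tibble(f_stat = x$f_stat, df_between = x$df_between, df_within = x$df_within,
         p_value = x$p_value, n = x$n, flag = x$flag)
}

#' @export
tidy.anova_result <- function(x, ...) {
  tibble(
    term = c("between", "within"),
    df = c(x$df_between, x$df_within),
    sumsq = c(x$ss_between, x$ss_within),
    meansq = c(x$ss_between / x$df_between, x$ss_within / x$df_within),
    statistic = c(x$f_stat, NA_real_),
    p_value = c(x$p_value, NA_real_)
  )
}

factor_column <- function(factor) {
  switch(factor,
    color = "color_category",
    petal = "petal_category",
    distance = "distance_cm",
    pp_abort(paste0("unknown factor: ", factor), "parameter")
  )
}

#' Evaluate estimation bias across a category factor
#'
#' Groups the per-image residuals `predicted_cm2 - measured_cm2` by one
#' category factor (flower colour T1-T5, petal display C1-C3, or capture
#' distance 60/80/100 cm), reports each group's bias and sample size, and
#' runs a one-way ANOVA on the residuals across groups to test whether the
#' estimator's bias depends on the factor. The ANOVA works on per-image
#' residuals (not per-group bias values), so its degrees of freedom are
#' `(k - 1, n - k)` for n images and k groups.
#'
#' @param table an evaluation table (see [read_eval_table()]): columns
#'   `image_id`, `predicted_cm2`, `measured_cm2`, `color_category`,
#'   `petal_category`, `distance_cm`.
#' @param factor one of `"color"`, `"petal"`, `"distance"`.
#' @param alpha significance level reported alongside, default 0.05.
#' @return An object of class `category_evaluation`: `factor`,
#'   `bias_by_group` (tibble `group`, `bias`, `n`), `anova`
#'   (an `anova_result`), `alpha`, `residuals` (tibble).
#' @export
evaluate_by_category <- function(table, factor = c("color", "petal", "distance"),
                                 alpha = 0.05) {
  factor <- match.arg(factor)
  col <- factor_column(factor)
  validate_eval_table(table)
  labels <- table[[col]]
  if (anyNA(labels) | any(labels == "")) {
    bad <- table$image_id[is.na(labels) | labels == ""]
    pp_abort(paste0("rows missing ", col, " labels: ", paste(bad, collapse = ", ")),
             "schema")
  }
  resid <- table$predicted_cm2 - table$measured_cm2
  grp <- as.character(labels)
  bias_by_group <- tibble(group = grp, residual = resid) |>
    group_by(.data$group) |>
    summarise(bias = mean(.data$residual), n = dplyr::n(), .groups = "drop") |>
    arrange(.data$group)
  anova <- one_way_anova(split(resid, grp))
  structure(
    list(factor = factor, bias_by_group = bias_by_group, anova = anova,
         alpha = alpha,
         residuals = tibble(image_id = table$image_id, group = grp,
                            residual = resid)),
    class = "category_evaluation"
  )
}

#' @export
print.category_evaluation <- function(x, ...) {
  cat(sprintf("bias by %s category:\n", x$factor))
  print(x$bias_by_group)
  print(x$anova)
  cat(sprintf("reject equal bias at alpha = %g: %s\n", x$alpha,
              ifelse(x$anova$p_value < x$alpha, "yes", "no")))
  invisible(x)
}

#' @export
tidy.category_evaluation <- function(x, ...) x$bias_by_group

#' @export
glance.category_evaluation <- function(x, ...) {
  bind_cols(tibble(factor = x$factor), glance(x$anova), tibble(alpha = x$alpha))
}
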