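test_that("bias is the mean difference, sign-preserving and translation-equivariant", {
  expect_equal(area_bias(c(1, 2, 3), c(1, 2, 3))$bias, 0)
  expect_equal(area_bias(c(1, 2, 3) + 1.5, c(1, 2, 3))$bias, 1.5)
  expect_equal(area_bias(c(3, 5), c(1, 2))$bias, 2.5)
  expect_error(area_bias(1:3, 1:2), class = "petalpix_error_parameter")
  expect_error(area_bias(numeric(), numeric()), class = "petalpix_error_parameter")

  set.seed(2)
  p <- rnorm(10); m <- rnorm(10); c <- rnorm(1)
  expect_equal(area_bias(p + c, m)$bias, area_bias(p, m)$bias + c)
})

test_that("regression metrics match closed-form OLS and identity-residual RMSE", {
  r <- regression_metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(c(r$r2, r$rmse, r$slope, r$intercept), c(1, 0, 1, 0))

  r <- regression_metrics(c(2, 4, 6), c(1, 2, 3))
  expect_equal(r$slope, 2)
  expect_equal(r$intercept, 0)
  expect_equal(r$r2, 1)
  expect_equal(r$rmse, sqrt(14 / 3))

  expect_error(regression_metrics(1, 1), class = "petalpix_error_parameter")
  expect_error(regression_metrics(c(1, 2), c(3, 3)),
               class = "petalpix_error_degenerate_regression")
})

test_that("R^2 equals the squared correlation for simple OLS", {
  set.seed(8)
  for (i in 1:10) {
    m <- rnorm(20, 100, 30)
    p <- 1.1 * m + rnorm(20, 0, 10)
    r <- regression_metrics(p, m)
    expect_equal(r$r2, cor(p, m)^2, tolerance = 1e-12)
    expect_lte(r$r2, 1)
    expect_gte(r$rmse, 0)
  }
})

test_that("one-way ANOVA reproduces hand-computed F and the t^2 relation", {
  a <- one_way_anova(list(g1 = c(1, 2), g2 = c(3, 4)))
  expect_equal(a$f_stat, 8)
  expect_equal(c(a$df_between, a$df_within), c(1, 2))
  # with k = 2 the F test is the squared two-sample t test
  tt <- t.test(c(1, 2), c(3, 4), var.equal = TRUE)
  expect_equal(a$f_stat, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(a$p_value, tt$p.value, tolerance = 1e-12)
  expect_equal(a$p_value, 0.1055728, tolerance = 1e-6)

  expect_equal(one_way_anova(list(a = c(1, 2, 3), b = c(1, 2, 3)))$f_stat, 0)
  expect_error(one_way_anova(list(a = 1:3)), class = "petalpix_error_parameter")
  expect_error(one_way_anova(list(a = 1:3, b = numeric())),
               class = "petalpix_error_parameter")
})

test_that("ANOVA degenerate conventions: all-identical and zero within-variance", {
  all_same <- one_way_anova(list(a = c(2, 2), b = c(2, 2)))
  expect_equal(all_same$f_stat, 0)
  expect_equal(all_same$p_value, 1)
  expect_equal(all_same$flag, "all_identical")

  no_within <- one_way_anova(list(a = c(1, 1), b = c(2, 2)))
  expect_equal(no_within$f_stat, Inf)
  expect_equal(no_within$p_value, 0)
  expect_equal(no_within$flag, "infinite_f")
})

test_that("ANOVA agrees with brute force and stats::aov on random groups", {
  set.seed(17)
  for (i in 1:25) {
    k <- sample(2:5, 1)
    groups <- lapply(seq_len(k), function(j) rnorm(sample(2:8, 1), mean = rnorm(1)))
    names(groups) <- paste0("g", seq_len(k))
    a <- one_way_anova(groups)
    expect_equal(a$f_stat, f_bruteforce(groups), tolerance = 1e-10)
    expect_equal(a$ss_total, a$ss_between + a$ss_within, tolerance = 1e-9)

    df <- data.frame(value = unlist(groups),
                     group = rep(names(groups), lengths(groups)))
    fit <- summary(stats::aov(value ~ group, data = df))[[1]]
    expect_equal(a$f_stat, fit[["F value"]][1], tolerance = 1e-8)
    expect_equal(a$p_value, fit[["Pr(>F)"]][1], tolerance = 1e-8)
  }
})

make_eval_table <- function(n_per = 10, offset = c(A = 0, B = 0, C = 0), sd = 1,
                            seed = 99) {
  set.seed(seed)
  groups <- names(offset)
  tibble::tibble(
    image_id = sprintf("img%03d", seq_len(n_per * length(groups))),
    measured_cm2 = stats::runif(n_per * length(groups), 50, 150),
    color_category = rep(groups, each = n_per),
    petal_category = rep("C1", n_per * length(groups)),
    distance_cm = rep(60, n_per * length(groups))
  ) |>
    dplyr::mutate(predicted_cm2 = measured_cm2 +
                    rep(offset, each = n_per) + stats::rnorm(n_per * length(groups), 0, sd))
}

test_that("per-category evaluation recovers group bias and detects injected offsets", {
  # all residuals zero
  tbl <- make_eval_table(sd = 0)
  tbl$predicted_cm2 <- tbl$measured_cm2
  ev <- evaluate_by_category(tbl, "color")
  expect_true(all(ev$bias_by_group$bias == 0))
  expect_equal(ev$anova$f_stat, 0)

  # an injected offset in one category is found at alpha = 0.05
  tbl <- make_eval_table(offset = c(A = 0, B = 0, C = 3), sd = 1, n_per = 15)
  ev <- evaluate_by_category(tbl, "color")
  expect_lt(ev$anova$p_value, 0.05)
  expect_equal(ev$bias_by_group$bias[ev$bias_by_group$group == "C"], 3,
               tolerance = 1)
  expect_equal(ev$anova$df_between, 2)
  expect_equal(ev$anova$df_within, nrow(tbl) - 3)

  # missing labels error and name the offending images
  tbl$color_category[2] <- NA
  expect_error(evaluate_by_category(tbl, "color"), regexp = "img002",
               class = "petalpix_error_schema")
})

test_that("null ANOVA rejects at close to the nominal rate", {
  set.seed(424)
  rejections <- vapply(seq_len(400), function(i) {
    groups <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8))
    one_way_anova(groups)$p_value < 0.05
  }, logical(1))
  expect_gt(mean(rejections), 0.02)
  expect_lt(mean(rejections), 0.09)
})
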