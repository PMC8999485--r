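test_that("design building keeps complete recurrent-pain cases only", {
  sim <- simulate_cohort(seed = 9)
  # knock out month-6 disability for 5 of the 22 recurrent-pain participants
  rnp_ids <- sim$cohort$participant_id[sim$cohort$group == "rnp"]
  lg <- sim$longitudinal
  lg$ndi[lg$participant_id %in% rnp_ids[1:5] & lg$month == 6] <- NA
  des <- build_design(sim$cohort, lg, "ndi6")
  with_m6 <- sum(!is.na(lg$ndi[lg$month == 6]))
  expect_equal(length(des$y), with_m6)
  expect_equal(ncol(des$x), 15)
  expect_identical(colnames(des$x), table_predictors)
  expect_false(anyNA(des$x))

  # a month with pain intensity below 20/100 contributes zero qualifying days
  lg2 <- data.frame(participant_id = rep("P016", 2), month = 1:2,
                    ndi = c(5, 5), days_with_pain = c(10, 6),
                    mean_vas = c(15, 40))
  one <- sim$cohort[sim$cohort$participant_id == "P016", ]
  des2 <- suppressWarnings(build_design(one, lg2, "days"))
  expect_equal(des2$y, mean(c(0, 6)))

  # constant day counts: the mean-days outcome is that constant
  lg3 <- data.frame(participant_id = "P016", month = 1:12, ndi = 5,
                    days_with_pain = 5, mean_vas = 50)
  expect_equal(suppressWarnings(build_design(one, lg3, "days"))$y, 5)

  expect_warning(build_design(one, lg3, "days", min_n = 10), "unstable")
})

test_that("LASSO selection shrinks to the intercept under a dominating penalty", {
  sim <- simulate_cohort(0, 60, 0, seed = 17)
  des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
  sel <- lasso_select(des$x, des$y, lambda = 1e6)
  expect_length(sel$selected, 0)
  expect_true(all(sel$coefficients[-1] == 0))

  # reproducible under the fold seed
  s1 <- lasso_select(des$x, des$y, seed = 5)
  s2 <- lasso_select(des$x, des$y, seed = 5)
  expect_identical(s1$lambda, s2$lambda)
  expect_identical(s1$coefficients, s2$coefficients)

  # constant columns are dropped with a warning, not an error
  x2 <- des$x
  x2$constant <- 1
  expect_warning(lasso_select(x2, des$y, seed = 1), "constant")
})

test_that("duplicated signal carriers are never selected with opposite signs", {
  for (s in 1:10) {
    sim <- simulate_cohort(0, 100, 0, seed = 300 + s)
    des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
    x <- des$x
    x$episodes_copy <- x$episodes
    sel <- lasso_select(x, des$y, seed = s)
    expect_true(any(c("episodes", "episodes_copy") %in% sel$selected))
    co <- sel$coefficients[c("episodes", "episodes_copy")]
    expect_false(all(co != 0) && prod(sign(co)) < 0)
  }
})

test_that("OLS reporting matches closed-form solutions and printed-precision anchors", {
  # exact linear relationship: perfect fit
  x <- data.frame(p = 1:10)
  y <- 3 + 2 * x$p
  fit <- suppressWarnings(fit_ols(x, y))
  expect_equal(fit$r2, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)

  # three points, normal equations by hand: slope 1.5, intercept -1/6
  fit3 <- fit_ols(data.frame(p = c(0, 1, 2)), c(0, 1, 3))
  expect_equal(fit3$terms$beta, c(-1 / 6, 1.5), tolerance = 1e-10)

  # t-quantile interval reconstruction at 14 residual df
  tq <- qt(0.975, 14)
  expect_equal(round(0.54 + tq * 0.21, 2), 0.99)
  expect_equal(round(0.54 - tq * 0.21, 2), 0.09)

  # rank deficiency is an error naming the collinear column
  xd <- data.frame(a = 1:8, b = (1:8) * 2)
  expect_error(fit_ols(xd, rnorm(8)), "collinear.*b")

  expect_error(fit_ols(data.frame(a = 1:3, b = 4:6, c = 7:9), 1:3), "more observations")
})

test_that("adjusted R-squared and F follow their defining identities", {
  expect_equal(adjusted_r2(0.50, 17, 2), 1 - 0.5 * 16 / 14)
  expect_equal(round(adjusted_r2(0.50, 17, 2), 2), 0.43)
  expect_equal(round(adjusted_r2(0.29, 19, 1), 2), 0.25)
  expect_equal(adjusted_r2(1, 20, 3), 1)
  expect_error(adjusted_r2(0.5, 4, 3), "n > k")
  # adjusted never exceeds unadjusted; F strictly increasing in R2
  for (r2 in seq(0, 0.95, by = 0.19)) {
    expect_lte(adjusted_r2(r2, 20, 4), r2 + 1e-12)
  }
  fs <- vapply(seq(0.1, 0.9, by = 0.2), f_from_r2, numeric(1), k = 2, df2 = 14)
  expect_true(all(diff(fs) > 0))
  expect_equal(f_from_r2(0, 2, 14), 0)
  expect_equal(f_from_r2(1, 2, 14), Inf)
})

test_that("RMSE is the root mean squared residual on the outcome scale", {
  expect_equal(compute_rmse(1:5, 1:5), 0)
  expect_equal(compute_rmse(c(3, -4), c(0, 0)), sqrt(12.5))
  expect_error(compute_rmse(1:3, 1:4), "equal length")

  # at the reference noise level the in-sample RMSE sits near the generating SD
  sim <- simulate_cohort(0, 200, 0, seed = 77)
  des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
  fit <- fit_ols(des$x[, c("episodes", "mvc_flexion")], des$y)
  expect_equal(fit$rmse, 3.5, tolerance = 0.15 * 3.5)
})

test_that("the scatter report annotates RMSE and flags intercept-only models", {
  sim <- simulate_cohort(0, 30, 0, seed = 21)
  des <- build_design(sim$cohort, sim$longitudinal, "ndi6")
  fit <- fit_ols(des$x[, "episodes", drop = FALSE], des$y)
  p <- scatter_fit_report(fit)
  expect_s3_class(p, "ggplot")
  expect_match(p$labels$subtitle, sprintf("RMSE = %.2f", fit$rmse), fixed = TRUE)

  fit0 <- fit_ols(des$x[, 0, drop = FALSE], des$y)
  p0 <- scatter_fit_report(fit0)
  expect_match(p0$labels$subtitle, "intercept-only")
})
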