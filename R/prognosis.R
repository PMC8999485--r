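#' Build the predictor matrix and outcome vector for a prognostic model
#'
#' Restricts the cohort to the recurrent-neck-pain group, assembles the 15
#' candidate predictors (disability, kinesiophobia, quality of life, pain
#' history, kinematic, proprioceptive and neuromuscular features), computes
#' the chosen outcome from the longitudinal table, and keeps complete cases
#' only — no imputation is performed, so the number of observations differs
#' between outcomes.
#'
#' Outcomes: `"ndi6"` is the disability score recorded at month 6 (0-50).
#' `"days"` is the mean over the participant's observed months of the monthly
#' day counts that satisfy the painful-day definition (pain lasting at least
#' 24 h with monthly average intensity of at least 20/100); a month whose
#' average intensity is below 20 contributes zero qualifying days.
#'
#' @param cohort Cohort data frame (as from [simulate_cohort()]).
#' @param longitudinal Monthly outcome table with `participant_id`, `month`,
#'   `ndi`, `days_with_pain`, `mean_vas`.
#' @param outcome `"ndi6"` or `"days"`.
#' @param min_n Below this number of complete cases the design is flagged
#'   unstable (a warning; the fit still proceeds).
#' @return A list with `x` (data frame of the 15 predictors), `y` (outcome
#'   vector), `participant_id`, `outcome`, and `unstable` (logical flag).
#' @export
build_design <- function(cohort, longitudinal, outcome = c("ndi6", "days"),
                         min_n = 10L) {
  outcome <- match.arg(outcome)
  rnp <- cohort[cohort$group == "rnp", , drop = FALSE]
  if (nrow(rnp) == 0L) stop("no recurrent-neck-pain participants", call. = FALSE)
  y <- vapply(rnp$participant_id, function(pid) {
    sub <- longitudinal[longitudinal$participant_id == pid, , drop = FALSE]
    if (outcome == "ndi6") {
      v <- sub$ndi[sub$month == 6]
      if (length(v) == 1L) v else NA_real_
    } else {
      ok <- !is.na(sub$days_with_pain) & !is.na(sub$mean_vas)
      if (!any(ok)) return(NA_real_)
      qual <- ifelse(sub$mean_vas[ok] >= 20, sub$days_with_pain[ok], 0)
      mean(qual)
    }
  }, numeric(1))
  x <- rnp[, table_predictors, drop = FALSE]
  complete <- stats::complete.cases(x) & !is.na(y)
  x <- x[complete, , drop = FALSE]
  y <- unname(y[complete])
  unstable <- nrow(x) < min_n
  if (unstable)
    warning(sprintf("only %d complete cases: model will be unstable", nrow(x)),
            call. = FALSE)
  list(x = x, y = y, participant_id = rnp$participant_id[complete],
       outcome = outcome, unstable = unstable)
}

#' LASSO candidate-predictor selection with cross-validated penalty
#'
#' Step one of the two-step prognostic workflow: an L1-penalised linear
#' regression over all candidate predictors, with the penalty chosen by
#' k-fold (default 5) cross-validated prediction error (the
#' minimum-mean-error rule). Predictors are standardised to unit variance
#' inside the fit so the penalty is not unit-dependent; reported coefficients
#' are on the original predictor scale. Predictors with coefficients shrunk
#' exactly to zero are excluded from step two.
#'
#' @param x Data frame or matrix of candidate predictors.
#' @param y Numeric outcome vector.
#' @param folds Number of cross-validation folds.
#' @param seed Integer seed for the fold assignment (selection is
#'   reproducible under the seed).
#' @param lambda Optional fixed penalty; skips cross-validation when given.
#' @param dfmax Largest active set considered on the cross-validation path.
#'   The default, two fewer than the number of observations, guarantees the
#'   subsequent least-squares step has at least one residual degree of
#'   freedom; with more observations than candidates it is not binding.
#' @return A list of class `lasso_selection` with `lambda`, `coefficients`
#'   (named, original scale, intercept included), `selected` (names of
#'   nonzero predictors), `dropped_constant` (constant columns removed before
#'   fitting), `cv_folds` and `seed`.
#' @export
lasso_select <- function(x, y, folds = 5, seed = 1, lambda = NULL,
                         dfmax = nrow(x) - 2L) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  if (nrow(x) < folds)
    stop("need at least as many observations as folds", call. = FALSE)
  const <- vapply(x, function(col) stats::var(col) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(names(x)[const], collapse = ", "), call. = FALSE)
    x <- x[, !const, drop = FALSE]
  }
  xm <- as.matrix(x)
  if (is.null(lambda)) {
    cv <- with_seed_opt(seed, {
      foldid <- sample(rep_len(seq_len(folds), nrow(xm)))
      glmnet::cv.glmnet(xm, y, alpha = 1, foldid = foldid,
                        standardize = TRUE)
    })
    # cross-validation minimiser restricted to active sets small enough for
    # the least-squares step (the path always starts at the empty set)
    ok <- cv$nzero <= dfmax
    lambda <- cv$lambda[ok][which.min(cv$cvm[ok])]
    if (lambda > cv$lambda.min)
      warning(sprintf(
        "penalty raised so that at most %d predictors are selected", dfmax),
        call. = FALSE)
    cm <- stats::coef(cv, s = lambda)
  } else {
    fit <- glmnet::glmnet(xm, y, alpha = 1, lambda = lambda, standardize = TRUE)
    cm <- stats::coef(fit)
  }
  co <- as.numeric(cm)
  names(co) <- rownames(cm)
  selected <- names(co)[-1][co[-1] != 0]
  structure(list(lambda = lambda, coefficients = co, selected = selected,
                 dropped_constant = names(const)[const], cv_folds = folds,
                 seed = seed),
            class = "lasso_selection")
}

#' @export
print.lasso_selection <- function(x, ...) {
  cat(sprintf("<lasso_selection> lambda = %.4g (%d-fold CV)\n",
              x$lambda, x$cv_folds))
  cat("selected:", if (length(x$selected)) paste(x$selected, collapse = ", ")
      else "(none - intercept only)", "\n")
  invisible(x)
}

#' Multivariate OLS with full inferential and internal-validation reporting
#'
#' Step two of the prognostic workflow: ordinary least squares with intercept
#' on the selected predictors. Reports per-term unstandardised coefficients,
#' standard errors, t statistics, two-sided p-values, and 95% confidence
#' intervals from the t distribution with `n - k - 1` degrees of freedom,
#' plus model R-squared, adjusted R-squared, the F statistic with its degrees
#' of freedom, and the in-sample RMSE on the outcome's own scale.
#'
#' @param x Data frame of the selected predictors (may have zero columns for
#'   an intercept-only model).
#' @param y Numeric outcome vector, `length(y) > ncol(x) + 1`.
#' @param conf_level Confidence level for the intervals.
#' @return An object of class `prognostic_model`: a list with `terms` (data
#'   frame: `term`, `beta`, `se`, `t`, `p`, `ci_low`, `ci_high`), `r2`,
#'   `adjusted_r2`, `f_statistic`, `df1`, `df2`, `rmse`, `n`, `fitted`,
#'   `observed`.
#' @export
fit_ols <- function(x, y, conf_level = 0.95) {
  x <- as.data.frame(x)
  n <- length(y)
  k <- ncol(x)
  if (n <= k + 1)
    stop("need more observations than predictors plus intercept", call. = FALSE)
  dat <- cbind(x, .y = y)
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  sm <- summary(fit)
  ct <- sm$coefficients
  df2 <- n - k - 1
  tq <- stats::qt(1 - (1 - conf_level) / 2, df2)
  terms <- data.frame(
    term = rownames(ct), beta = ct[, 1], se = ct[, 2], t = ct[, 3],
    p = ct[, 4], ci_low = ct[, 1] - tq * ct[, 2],
    ci_high = ct[, 1] + tq * ct[, 2],
    row.names = NULL, stringsAsFactors = FALSE)
  r2 <- sm$r.squared
  fitted <- unname(stats::fitted(fit))
  structure(list(
    terms = terms, r2 = r2,
    adjusted_r2 = if (k > 0) adjusted_r2(r2, n, k) else NA_real_,
    f_statistic = if (k > 0) f_from_r2(r2, k, df2) else NA_real_,
    df1 = k, df2 = df2,
    rmse = compute_rmse(fitted, y), n = n,
    fitted = fitted, observed = y, lm_fit = fit),
    class = "prognostic_model")
}

#' @export
print.prognostic_model <- function(x, ...) {
  cat(sprintf("<prognostic_model> n = %d, k = %d\n", x$n, x$df1))
  print(x$terms, digits = 3)
  cat(sprintf("R2 = %.3f, adjusted R2 = %.3f, F(%d, %d) = %.3f, RMSE = %.3f\n",
              x$r2, x$adjusted_r2, x$df1, x$df2, x$f_statistic, x$rmse))
  invisible(x)
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - k - 1)`: the proportion of outcome variance
#' explained, penalised for the number of predictors.
#'
#' @param r2 Unadjusted R-squared.
#' @param n Number of observations (`n > k + 1`).
#' @param k Number of predictors (intercept excluded).
#' @return The adjusted R-squared.
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("requires n > k + 1", call. = FALSE)
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

#' Model F statistic from R-squared
#'
#' `(r2 / k) / ((1 - r2) / df2)`, the overall F statistic of a linear model
#' with `k` predictors and `df2` residual degrees of freedom.
#'
#' @param r2 R-squared in `[0, 1)`; an R-squared of exactly 1 yields `Inf`.
#' @param k Numerator degrees of freedom (number of predictors, >= 1).
#' @param df2 Residual degrees of freedom (>= 1).
#' @return The F statistic.
#' @export
f_from_r2 <- function(r2, k, df2) {
  stopifnot(r2 >= 0, r2 <= 1, k >= 1, df2 >= 1)
  if (r2 == 1) return(Inf)
  (r2 / k) / ((1 - r2) / df2)
}

#' Root mean squared error between predicted and observed values
#'
#' @param predicted,observed Equal-length numeric vectors.
#' @return `sqrt(mean((predicted - observed)^2))`, on the outcome's scale.
#' @export
compute_rmse <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length", call. = FALSE)
  if (length(predicted) < 1L) stop("need at least one value", call. = FALSE)
  sqrt(mean((predicted - observed)^2))
}

#' Two-step prognostic model: LASSO selection then OLS
#'
#' Convenience wrapper running [lasso_select()] on the full candidate set and
#' [fit_ols()] on the selected predictors. With an empty selection the second
#' step is an intercept-only model (flagged in the result).
#'
#' @param design Output of [build_design()].
#' @param folds,seed Passed to [lasso_select()].
#' @return A list with `selection` (`lasso_selection`), `model`
#'   (`prognostic_model`) and `intercept_only` flag.
#' @export
fit_prognosis <- function(design, folds = 5, seed = 1) {
  sel <- lasso_select(design$x, design$y, folds = folds, seed = seed)
  xsel <- design$x[, sel$selected, drop = FALSE]
  model <- fit_ols(xsel, design$y)
  list(selection = sel, model = model,
       intercept_only = length(sel$selected) == 0L)
}

#' Predicted-versus-observed scatter report
#'
#' Draws the internal-validation scatter of model predictions against observed
#' outcomes with the identity (perfect-prediction) line and an RMSE
#' annotation. For an intercept-only model the annotation notes that
#' predictions are a constant.
#'
#' @param model A `prognostic_model` from [fit_ols()].
#' @param title Plot title.
#' @param file Optional path; when given the plot is also written there.
#' @return The ggplot object, invisibly.
#' @export
scatter_fit_report <- function(model, title = "Predicted vs observed",
                               file = NULL) {
  stopifnot(inherits(model, "prognostic_model"))
  df <- data.frame(predicted = model$fitted, observed = model$observed)
  note <- sprintf("RMSE = %.2f%s", model$rmse,
                  if (model$df1 == 0) " (intercept-only prediction)" else "")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "red") +
    ggplot2::geom_point() +
    ggplot2::labs(title = title, subtitle = note,
                  x = "Predicted", y = "Observed") +
    ggplot2::theme_minimal()
  if (!is.null(file)) ggplot2::ggsave(file, p, width = 5, height = 4)
  invisible(p)
}
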