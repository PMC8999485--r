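#' Choose the omnibus test branch for a grouped feature
#'
#' Implements the distribution-aware decision tree used for cross-sectional
#' group comparisons. Normality is assessed per group with the Shapiro-Wilk
#' test: if any group departs from normality (p <= alpha) the feature is
#' compared with the Kruskal-Wallis test. For normal data, Levene's test for
#' equality of variances decides between the ordinary one-way ANOVA
#' (homogeneous, p >= alpha) and Welch's ANOVA (heterogeneous).
#'
#' @param groups Named list of numeric vectors, one per group (each n >= 3).
#' @param alpha Significance level of the gates.
#' @param center Centring for Levene's test; `"mean"` is the classical test.
#' @return A list with `branch` (`"anova"`, `"welch_anova"` or
#'   `"kruskal_wallis"`) and `branch_log` (the Shapiro-Wilk p-value per group
#'   and the Levene p-value, `NA` when not reached).
#' @export
choose_branch <- function(groups, alpha = 0.05, center = "mean") {
  check_groups(groups, min_n = 3L)
  sw <- vapply(groups, function(x) stats::shapiro.test(x)$p.value, numeric(1))
  if (any(sw <= alpha)) {
    return(list(branch = "kruskal_wallis",
                branch_log = list(shapiro = sw, levene = NA_real_)))
  }
  lev <- car::leveneTest(
    unlist(groups, use.names = FALSE),
    factor(rep(names(groups), lengths(groups))),
    center = center
  )[["Pr(>F)"]][1]
  branch <- if (lev >= alpha) "anova" else "welch_anova"
  list(branch = branch, branch_log = list(shapiro = sw, levene = lev))
}

check_groups <- function(groups, min_n = 2L) {
  if (!is.list(groups) || length(groups) < 2L)
    stop("at least two groups are required", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be named", call. = FALSE)
  n <- lengths(groups)
  if (any(n < min_n))
    stop(sprintf("every group needs at least %d observations", min_n),
         call. = FALSE)
  if (any(!vapply(groups, function(x) all(is.finite(x)), logical(1))))
    stop("group values must be finite", call. = FALSE)
  invisible(groups)
}

#' Run the omnibus test of a chosen branch
#'
#' @param groups Named list of numeric group vectors.
#' @param branch `"anova"`, `"welch_anova"` or `"kruskal_wallis"` (as chosen
#'   by [choose_branch()]).
#' @return A list with `test`, `statistic` (F or tie-corrected H), `df`,
#'   `p_value`, and `degenerate` (`TRUE`, with `p_value = NA`, when all
#'   values are identical).
#' @export
run_omnibus <- function(groups, branch) {
  check_groups(groups)
  branch <- match.arg(branch, c("anova", "welch_anova", "kruskal_wallis"))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  if (length(unique(values)) == 1L)
    return(list(test = branch, statistic = NA_real_, df = NULL,
                p_value = NA_real_, degenerate = TRUE))
  res <- switch(branch,
    anova = {
      ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
      list(statistic = unname(ow$statistic), df = unname(ow$parameter),
           p_value = ow$p.value)
    },
    welch_anova = {
      ow <- stats::oneway.test(values ~ g, var.equal = FALSE)
      list(statistic = unname(ow$statistic), df = unname(ow$parameter),
           p_value = ow$p.value)
    },
    kruskal_wallis = {
      kw <- stats::kruskal.test(values, g)
      list(statistic = unname(kw$statistic), df = unname(kw$parameter),
           p_value = kw$p.value)
    })
  c(list(test = branch), res, list(degenerate = FALSE))
}

#' Pairwise post hoc comparisons for a branch
#'
#' Runs the post hoc matched to the omnibus branch: Tukey's honestly
#' significant difference after ANOVA, Games-Howell (Welch-df studentised
#' range) after Welch's ANOVA, and Dunn's rank-based z test with Bonferroni
#' correction over the pairs after Kruskal-Wallis. Pairs with fewer than two
#' observations on either side are skipped with a flag.
#'
#' @param groups Named list of numeric group vectors.
#' @param branch Omnibus branch name; selects the post hoc.
#' @return A data frame with columns `pair`, `statistic`, `p_adj`, `skipped`.
#' @export
run_posthoc <- function(groups, branch) {
  check_groups(groups)
  branch <- match.arg(branch, c("anova", "welch_anova", "kruskal_wallis"))
  switch(branch,
         anova = posthoc_tukey(groups),
         welch_anova = posthoc_games_howell(groups),
         kruskal_wallis = posthoc_dunn(groups))
}

pair_grid <- function(groups) {
  nm <- names(groups)
  utils::combn(nm, 2, simplify = FALSE)
}

posthoc_tukey <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), lengths(groups)))
  tk <- stats::TukeyHSD(stats::aov(values ~ g))$g
  pairs <- rownames(tk)
  data.frame(pair = gsub("-", " vs ", pairs),
             statistic = tk[, "diff"], p_adj = tk[, "p adj"],
             skipped = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

# Games-Howell: Welch t statistic per pair, referred to the studentised-range
# distribution with Welch-Satterthwaite degrees of freedom
posthoc_games_howell <- function(groups) {
  k <- length(groups)
  rows <- lapply(pair_grid(groups), function(pr) {
    x <- groups[[pr[1]]]; y <- groups[[pr[2]]]
    if (length(x) < 2L || length(y) < 2L)
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        statistic = NA_real_, p_adj = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    se2 <- stats::var(x) / length(x) + stats::var(y) / length(y)
    t_stat <- (mean(x) - mean(y)) / sqrt(se2)
    df <- se2^2 / ((stats::var(x) / length(x))^2 / (length(x) - 1) +
                   (stats::var(y) / length(y))^2 / (length(y) - 1))
    p <- stats::ptukey(abs(t_stat) * sqrt(2), nmeans = k, df = df,
                       lower.tail = FALSE)
    data.frame(pair = paste(pr, collapse = " vs "), statistic = t_stat,
               p_adj = p, skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Dunn: pairwise z on mean ranks with the tie-corrected Kruskal-Wallis
# variance, Bonferroni-adjusted over the pairs (capped at 1)
posthoc_dunn <- function(groups) {
  values <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  r <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  mean_ranks <- tapply(r, g, mean)
  n <- lengths(groups)
  m <- length(pair_grid(groups))
  rows <- lapply(pair_grid(groups), function(pr) {
    n1 <- n[[pr[1]]]; n2 <- n[[pr[2]]]
    if (n1 < 2L || n2 < 2L)
      return(data.frame(pair = paste(pr, collapse = " vs "),
                        statistic = NA_real_, p_adj = NA_real_, skipped = TRUE,
                        stringsAsFactors = FALSE))
    sigma <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n1 + 1 / n2))
    z <- (mean_ranks[[pr[1]]] - mean_ranks[[pr[2]]]) / sigma
    p <- min(2 * stats::pnorm(-abs(z)) * m, 1)
    data.frame(pair = paste(pr, collapse = " vs "), statistic = z,
               p_adj = p, skipped = FALSE, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full decision-tree comparison of one feature across groups
#'
#' Chooses the branch, runs the omnibus test, and — only when the omnibus test
#' is significant at `alpha` — the matched post hoc. Post hocs are never run
#' on non-significant omnibus results.
#'
#' @param groups Named list of numeric group vectors.
#' @param alpha Significance level for the gates and the omnibus test.
#' @return A list of class `comparison_result` with `branch`, `branch_log`,
#'   `omnibus`, and `pairwise` (`NULL` unless the omnibus p-value is
#'   <= alpha).
#' @export
compare_feature <- function(groups, alpha = 0.05) {
  br <- choose_branch(groups, alpha = alpha)
  om <- run_omnibus(groups, br$branch)
  pw <- NULL
  if (!om$degenerate && is.finite(om$p_value) && om$p_value <= alpha)
    pw <- run_posthoc(groups, br$branch)
  structure(list(branch = br$branch, branch_log = br$branch_log,
                 omnibus = om, pairwise = pw, alpha = alpha),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s: statistic = %.3f, p = %.4g\n",
              x$omnibus$test, x$omnibus$statistic, x$omnibus$p_value))
  if (!is.null(x$pairwise)) {
    cat("post hoc:\n")
    print(x$pairwise)
  } else {
    cat("post hoc: not run (omnibus not significant)\n")
  }
  invisible(x)
}

#' Descriptive group summary of a cohort table
#'
#' Mean and SD per group for every requested numeric feature (SD is `NA` with
#' a flag for single-observation groups), plus a chi-square comparison of the
#' sex distribution across groups when a `sex` column is present.
#'
#' @param cohort Cohort data frame with a `group` column.
#' @param features Character vector of numeric column names to summarise;
#'   defaults to all numeric columns.
#' @return A list with `descriptives` (feature x group long data frame with
#'   `mean`, `sd`, `n`) and `sex_test` (chi-square statistic, df and p, or
#'   `NULL`).
#' @export
summarize_cohort <- function(cohort, features = NULL) {
  stopifnot(is.data.frame(cohort), nrow(cohort) > 0, "group" %in% names(cohort))
  if (is.null(features))
    features <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                        "month")
  rows <- list()
  for (f in features) {
    for (g in unique(cohort$group)) {
      x <- cohort[[f]][cohort$group == g]
      x <- x[!is.na(x)]
      rows[[length(rows) + 1L]] <- data.frame(
        feature = f, group = g, n = length(x),
        mean = if (length(x)) mean(x) else NA_real_,
        sd = if (length(x) > 1L) stats::sd(x) else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  sex_test <- NULL
  if ("sex" %in% names(cohort)) {
    tab <- table(cohort$sex, cohort$group)
    if (all(dim(tab) >= 2)) {
      ct <- suppressWarnings(stats::chisq.test(tab))
      sex_test <- list(statistic = unname(ct$statistic),
                       df = unname(ct$parameter), p_value = ct$p.value)
    }
  }
  list(descriptives = do.call(rbind, rows), sex_test = sex_test)
}

#' Compare every feature of a cohort across its groups
#'
#' Applies [compare_feature()] to each feature column, returning a tidy table
#' of branch, omnibus statistic and p-value, and the significant post hoc
#' pairs.
#'
#' @param cohort Cohort data frame with a `group` column.
#' @param features Character vector of feature columns; defaults to all
#'   numeric columns with at least two non-empty groups.
#' @param alpha Significance level.
#' @return A data frame with one row per analysable feature.
#' @export
compare_cohort <- function(cohort, features = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(cohort), "group" %in% names(cohort))
  if (is.null(features))
    features <- setdiff(names(cohort)[vapply(cohort, is.numeric, logical(1))],
                        c("month"))
  rows <- list()
  for (f in features) {
    groups <- split(cohort[[f]], cohort$group)
    groups <- lapply(groups, function(x) x[!is.na(x)])
    groups <- groups[lengths(groups) >= 3L]
    if (length(groups) < 2L) next
    if (any(vapply(groups, function(x) length(unique(x)) == 1L, logical(1))))
      next  # constant group: normality gate undefined
    cr <- compare_feature(groups, alpha = alpha)
    sig_pairs <- if (is.null(cr$pairwise)) "" else
      paste(cr$pairwise$pair[!cr$pairwise$skipped &
                               cr$pairwise$p_adj <= alpha], collapse = "; ")
    rows[[length(rows) + 1L]] <- data.frame(
      feature = f, test = cr$omnibus$test,
      statistic = cr$omnibus$statistic, p_value = cr$omnibus$p_value,
      significant_pairs = sig_pairs,
      shapiro_min_p = min(cr$branch_log$shapiro),
      levene_p = cr$branch_log$levene,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
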