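#' @keywords internal
#' @importFrom rlang .data
"_PACKAGE"

#' Pipeline run configuration
#'
#' @param out_dir Output directory for the run.
#' @param seed Master seed; per-stage child seeds are derived from it with a
#'   fixed rule so every stage is independently reproducible.
#' @param alpha Significance level for group comparisons.
#' @param folds Cross-validation folds for predictor selection.
#' @param outcomes Which prognostic outcomes to fit.
#' @param n_healthy,n_rnp,n_cnp Group sizes for the simulated cohort.
#' @param truth A [synthetic_truth()] (ground-truth overrides).
#' @param recordings Generate and extract raw signal recordings.
#' @param feature_source Feature table used for group comparisons:
#'   `"cohort"` (the generator's drawn feature values) or `"extracted"`
#'   (values re-extracted from the raw recordings; requires `recordings`).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("neckprog_run_"), seed = 1,
                       alpha = 0.05, folds = 5,
                       outcomes = c("ndi6", "days"),
                       n_healthy = 15, n_rnp = 22, n_cnp = 8,
                       truth = synthetic_truth(), recordings = TRUE,
                       feature_source = c("cohort", "extracted")) {
  feature_source <- match.arg(feature_source)
  if (feature_source == "extracted" && !recordings)
    stop("`feature_source = \"extracted\"` requires `recordings = TRUE`",
         call. = FALSE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), alpha = alpha,
                 folds = folds, outcomes = match.arg(outcomes, several.ok = TRUE),
                 n_healthy = n_healthy, n_rnp = n_rnp, n_cnp = n_cnp,
                 truth = truth, recordings = recordings,
                 feature_source = feature_source),
            class = "run_config")
}

#' Read a flat key-value YAML/JSON-free configuration file
#'
#' Lines of `key: value`; unknown keys are rejected. Supported keys are the
#' arguments of [run_config()] except `truth` (scalar truth fields may be set
#' as `truth.<field>`).
#'
#' @param path Path to the configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)])
  kv <- strsplit(lines, ":\\s*")
  keys <- vapply(kv, `[[`, character(1), 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = ":"), character(1))
  args <- list()
  truth_args <- list()
  for (i in seq_along(keys)) {
    k <- keys[i]; v <- vals[i]
    if (startsWith(k, "truth.")) {
      truth_args[[sub("^truth\\.", "", k)]] <- as.numeric(v)
    } else if (k %in% c("out_dir", "feature_source")) {
      args[[k]] <- v
    } else if (k == "outcomes") {
      args[[k]] <- strsplit(v, ",\\s*")[[1]]
    } else if (k == "recordings") {
      args[[k]] <- as.logical(v)
    } else if (k %in% c("seed", "alpha", "folds", "n_healthy", "n_rnp", "n_cnp")) {
      args[[k]] <- as.numeric(v)
    } else {
      stop("unknown configuration key: ", k, call. = FALSE)
    }
  }
  if (length(truth_args)) args$truth <- do.call(synthetic_truth, truth_args)
  do.call(run_config, args)
}

#' Extract the feature table from raw recordings of a whole cohort
#'
#' Runs kinematic and neuromuscular extraction for every participant's
#' recordings and returns one row per participant with the candidate-predictor
#' feature columns.
#'
#' @param sim A `synthetic_cohort` with recordings.
#' @return Data frame of extracted features keyed by `participant_id`.
#' @export
extract_cohort_features <- function(sim) {
  stopifnot(inherits(sim, "synthetic_cohort"), !is.null(sim$recordings))
  rows <- lapply(names(sim$recordings), function(pid) {
    rec <- sim$recordings[[pid]]
    fe <- extract_kinematics(rec$flexion_extension)
    rot <- extract_kinematics(rec$rotation)
    jpe <- compute_jpe(rec$jpe_right, rec$jpe_left)
    nm <- extract_neuromuscular(rec)
    cbind(data.frame(
      participant_id = pid,
      rom_flexext = fe$rom_combined$flexion_extension,
      rom_rot = rot$rom_combined$rotation,
      vmean_flexion = fe$flexion$vmean,
      vmean_extension = fe$extension$vmean,
      vpeak_flexion = fe$flexion$vpeak,
      vpeak_extension = fe$extension$vpeak,
      nvp_flexext = mean(c(fe$flexion$nvp, fe$extension$nvp)),
      vmean_rotation = mean(c(rot$right_rotation$vmean, rot$left_rotation$vmean)),
      nvp_rotation = mean(c(rot$right_rotation$nvp, rot$left_rotation$nvp)),
      jpe_right = jpe$jpe_right, jpe_left = jpe$jpe_left,
      jpe = mean(c(jpe$jpe_right, jpe$jpe_left)),
      stringsAsFactors = FALSE), nm)
  })
  do.call(rbind, rows)
}

#' Run the full simulated-study pipeline
#'
#' Executes every stage in order — simulate the cohort, extract features from
#' the recordings, compare features across groups through the decision tree,
#' fit the two-step prognostic model for each requested outcome, and write a
#' report — into a run directory. Every output carries the seed and a
#' configuration hash in `manifest.json`; re-running with an identical
#' configuration reproduces identical numeric outputs. A failing stage aborts
#' with an error naming the stage; outputs of earlier stages are preserved.
#'
#' @param config A [run_config()].
#' @return The run directory path, invisibly; its contents include
#'   `cohort.csv`, `longitudinal.csv`, `features.csv` (when recordings are
#'   generated), `comparisons.csv`, `model_<outcome>.json`,
#'   `predictions_<outcome>.csv` and `manifest.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  sim <- stage("simulate", {
    s <- simulate_cohort(config$n_healthy, config$n_rnp, config$n_cnp,
                         truth = config$truth,
                         seed = derive_seed(config$seed, "simulate"),
                         recordings = config$recordings)
    write_cohort(s, config$out_dir)
    s
  })

  features <- NULL
  if (config$recordings) {
    features <- stage("extract", {
      f <- extract_cohort_features(sim)
      utils::write.csv(f, file.path(config$out_dir, "features.csv"),
                       row.names = FALSE)
      f
    })
  }

  comparisons <- stage("compare", {
    tab <- if (config$feature_source == "extracted") {
      merge(sim$cohort[, c("participant_id", "group", "ndi", "tsk",
                           "eq_vas", "eq5d")], features,
            by = "participant_id")
    } else {
      sim$cohort
    }
    n_groups <- sum(c(config$n_healthy, config$n_rnp, config$n_cnp) > 0)
    if (n_groups < 3)
      message("fewer than three groups simulated: comparisons degrade to ",
              "two-group contrasts")
    cmp <- compare_cohort(tab, alpha = config$alpha)
    utils::write.csv(cmp, file.path(config$out_dir, "comparisons.csv"),
                     row.names = FALSE)
    cmp
  })

  models <- list()
  for (oc in config$outcomes) {
    models[[oc]] <- stage(paste0("prognosis_", oc), {
      des <- build_design(sim$cohort, sim$longitudinal, outcome = oc)
      fit <- fit_prognosis(des, folds = config$folds,
                           seed = derive_seed(config$seed, paste0("lasso_", oc)))
      jsonlite::write_json(
        list(outcome = oc, n = fit$model$n,
             lasso = list(lambda = fit$selection$lambda,
                          coefficients = as.list(fit$selection$coefficients),
                          selected = fit$selection$selected),
             terms = fit$model$terms, r2 = fit$model$r2,
             adjusted_r2 = fit$model$adjusted_r2,
             f_statistic = fit$model$f_statistic,
             df1 = fit$model$df1, df2 = fit$model$df2, rmse = fit$model$rmse),
        file.path(config$out_dir, sprintf("model_%s.json", oc)),
        auto_unbox = TRUE, digits = NA, dataframe = "rows")
      utils::write.csv(
        data.frame(participant_id = des$participant_id,
                   predicted = fit$model$fitted, observed = fit$model$observed),
        file.path(config$out_dir, sprintf("predictions_%s.csv", oc)),
        row.names = FALSE)
      scatter_fit_report(fit$model,
                         title = sprintf("Outcome: %s", oc),
                         file = file.path(config$out_dir,
                                          sprintf("scatter_%s.pdf", oc)))
      fit
    })
  }

  manifest <- list(
    seed = config$seed,
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    stages = c("simulate", if (config$recordings) "extract", "compare",
               paste0("prognosis_", config$outcomes)),
    timestamp = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE)

  invisible(structure(list(dir = config$out_dir, sim = sim,
                           features = features, comparisons = comparisons,
                           models = models),
                      class = "pipeline_result"))
}
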