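#' Pipeline run configuration
#'
#' Assembles and validates the configuration for a full pipeline run.
#' Exactly one input source must be given: a directory of Depresjon-dialect
#' files (`input_dir`) or a synthetic cohort config (`synthetic`). The
#' global `seed` drives every stochastic stage: cohort generation, fold
#' assignment, ADASYN, model training, the Shapley background subsample and
#' permutations, and LIME sampling.
#'
#' @param task `"binary"` or `"severity"`.
#' @param synthetic A [synthetic_cohort_config()], or NULL.
#' @param input_dir Directory with activity CSVs and `scores.csv`, or NULL.
#' @param L Window length in minutes.
#' @param features A [feature_config()].
#' @param adasyn An [adasyn_config()].
#' @param models Classifier roster for cross-validation.
#' @param hyperparams Optional per-model hyperparameter overrides.
#' @param repeats,k,alpha Cross-validation shape and significance level.
#' @param explain_models Models to explain and compare (subset of `models`);
#'   defaults to the gradient-boosted trees and the neural network, the two
#'   architectures whose explanations are compared.
#' @param n_background,n_explain,n_permutations Shapley settings: background
#'   subsample size, instances explained, sampled permutations per instance.
#' @param lime_samples LIME perturbation sample count.
#' @param seed Global integer seed (mandatory).
#' @param out_dir Output directory, or NULL to skip writing artifacts.
#' @return A validated `run_config` list.
#' @export
run_config <- function(task = c("binary", "severity"),
                       synthetic = NULL, input_dir = NULL,
                       L = 1440L,
                       features = feature_config(),
                       adasyn = adasyn_config(),
                       models = classifier_names(),
                       hyperparams = NULL,
                       repeats = 3L, k = 10L, alpha = 0.05,
                       explain_models = NULL,
                       n_background = 50L, n_explain = 20L,
                       n_permutations = 100L,
                       lime_samples = 5000L,
                       seed = 1L, out_dir = NULL) {
  task <- match.arg(task)
  if (is.null(synthetic) == is.null(input_dir)) {
    stop_actidep("exactly one of 'synthetic' or 'input_dir' must be given",
                 class = "actidep_validation_error")
  }
  if (is.null(seed)) {
    stop_actidep("a seed is mandatory", class = "actidep_validation_error")
  }
  explain_models <- explain_models %||%
    (if (any(c("gradient_boosting", "neural_net") %in% models)) {
      intersect(c("gradient_boosting", "neural_net"), models)
    } else {
      models[1]
    })
  stopifnot(all(explain_models %in% models))
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' The file may contain any [run_config()] argument; nested blocks
#' `synthetic`, `features` and `adasyn` are passed to their constructors.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$synthetic)) {
    raw$synthetic <- do.call(synthetic_cohort_config, raw$synthetic)
  }
  if (!is.null(raw$features)) raw$features <- do.call(feature_config, raw$features)
  if (!is.null(raw$adasyn)) raw$adasyn <- do.call(adasyn_config, raw$adasyn)
  do.call(run_config, raw)
}

# Fit a model on the full (standardized, oversampled) matrix and explain
# `n_explain` seeded instances with sampled Shapley values on the score of
# `class_index`'s probability.
explain_model <- function(model_name, X, y, config, class_index = NULL) {
  scaler <- fit_scaler(X)
  Xs <- apply_scaler(scaler, X)
  cfg_ad <- config$adasyn
  cfg_ad$seed <- child_seed(config$seed, 31)
  aug <- adasyn_oversample(Xs, y, cfg_ad)
  fit <- train_classifier(model_name, aug$X, aug$y, config$hyperparams[[model_name]],
                          seed = child_seed(config$seed, 32))
  classes <- sort(unique(y))
  class_index <- class_index %||% length(classes)
  score_fn <- function(M) {
    predict(fit, M, type = "prob")[, class_index]
  }
  n_bg <- min(config$n_background, nrow(Xs))
  bg_idx <- with_seed(child_seed(config$seed, 33), sample.int(nrow(Xs), n_bg))
  background <- Xs[bg_idx, , drop = FALSE]
  n_ex <- min(config$n_explain, nrow(Xs))
  ex_idx <- with_seed(child_seed(config$seed, 34), sample.int(nrow(Xs), n_ex))
  explanations <- lapply(seq_along(ex_idx), function(i) {
    sampled_shapley(score_fn, Xs[ex_idx[i], ], background,
                    n_permutations = config$n_permutations,
                    seed = child_seed(config$seed, 100 + i))
  })
  lime <- lime_explain(score_fn, Xs[ex_idx[1], ], Xs,
                       n_samples = config$lime_samples,
                       seed = child_seed(config$seed, 35))
  list(model = fit,
       ranking = global_importance(explanations, model_tag = model_name),
       explanations = explanations,
       lime = lime,
       explained_rows = ex_idx)
}

#' Run the full pipeline
#'
#' Executes the stages in order: ingest or simulate the cohort, window the
#' recordings, extract features, run the repeated stratified CV protocol
#' (scaler and ADASYN inside each training fold), apply the paired-t + Holm
#' significance protocol, and explain the requested models with sampled
#' Shapley values and a LIME surrogate, including the cross-model importance
#' comparison. When `out_dir` is set, artifacts are written there: the
#' feature matrix and drop log (CSV), per-fold CV scores (CSV), pooled
#' metrics and the significance report (JSON), per-model importance
#' rankings (CSV), the rank-agreement comparison and LIME rules (JSON), and
#' a manifest recording the seed, config and per-stage row counts.
#'
#' @param config A [run_config()].
#' @return A `pipeline_result` list: `cohort`, `features`, `cv`,
#'   `significance`, `explanations` (per model), `comparison`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  cohort <- if (!is.null(config$synthetic)) {
    cfg <- config$synthetic
    cfg$seed <- child_seed(config$seed, 1)
    generate_cohort(cfg)
  } else {
    read_cohort(config$input_dir)
  }
  fm <- build_feature_matrix(cohort, config$features, config$L)
  y <- if (config$task == "binary") fm$binary else fm$severity
  present <- sort(unique(y[!is.na(y)]))
  needed <- if (config$task == "severity") 0:2 else 0:1
  if (!all(needed %in% present)) {
    stop_actidep("task '%s' requires class %s, absent from the cohort",
                 config$task, paste(setdiff(needed, present), collapse = ", "),
                 class = "actidep_validation_error")
  }
  cv <- repeated_stratified_cv(fm, config$task, config$models,
                               config$repeats, config$k,
                               seed = child_seed(config$seed, 2),
                               hyperparams = config$hyperparams,
                               adasyn = config$adasyn)
  reference <- if ("gradient_boosting" %in% config$models) {
    "gradient_boosting"
  } else {
    config$models[1]
  }
  sig <- significance_report(cv, reference, config$alpha)
  keep <- !is.na(y)
  expl <- lapply(config$explain_models, function(m) {
    explain_model(m, fm$X[keep, , drop = FALSE], y[keep], config)
  })
  names(expl) <- config$explain_models
  comparison <- if (length(expl) >= 2) {
    compare_model_explanations(expl[[1]]$ranking, expl[[2]]$ranking)
  } else {
    NULL
  }
  manifest <- list(
    seed = config$seed,
    task = config$task,
    n_participants = length(cohort$participants),
    n_windows = nrow(fm$X),
    n_dropped_windows = nrow(fm$drop_log),
    n_folds = config$repeats * config$k,
    models = config$models,
    explain_models = config$explain_models,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    package_version = as.character(utils::packageVersion("actidep"))
  )
  result <- structure(list(cohort = cohort, features = fm, cv = cv,
                           significance = sig, explanations = expl,
                           comparison = comparison, manifest = manifest),
                      class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config$out_dir)
  result
}

write_pipeline_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fm <- result$features
  feat_df <- data.frame(participant_id = fm$participant_id,
                        binary = fm$binary, severity = fm$severity,
                        fm$X, check.names = FALSE)
  data.table::fwrite(feat_df, file.path(out_dir, "features.csv"))
  data.table::fwrite(fm$drop_log, file.path(out_dir, "drop_log.csv"))
  scores <- do.call(cbind, lapply(result$cv$models, `[[`, "scores"))
  data.table::fwrite(data.frame(fold = seq_len(nrow(scores)), scores),
                     file.path(out_dir, "cv_scores.csv"))
  metrics <- lapply(result$cv$models, function(m) {
    avg <- if (nrow(m$pooled_cm) == 2) "binary" else "weighted"
    rep <- metric_suite(m$pooled_cm, avg)
    c(rep[c("accuracy", "precision", "recall", "specificity", "f1", "mcc")],
      list(cv_f1_mean = m$mean, cv_f1_sd = m$sd))
  })
  jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(as.list(as.data.frame(result$significance)),
                       file.path(out_dir, "significance.json"),
                       auto_unbox = TRUE, digits = NA)
  for (m in names(result$explanations)) {
    data.table::fwrite(as.data.frame(result$explanations[[m]]$ranking),
                       file.path(out_dir, sprintf("importance_%s.csv", m)))
    jsonlite::write_json(result$explanations[[m]]$lime[c("rules", "intercept",
                                                         "r_squared",
                                                         "prediction")],
                         file.path(out_dir, sprintf("lime_%s.json", m)),
                         auto_unbox = TRUE, digits = NA)
  }
  if (!is.null(result$comparison)) {
    jsonlite::write_json(result$comparison,
                         file.path(out_dir, "importance_comparison.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %s task: %d windows, %d folds\n",
              x$manifest$task, x$manifest$n_windows, x$manifest$n_folds))
  print(x$cv)
  invisible(x)
}
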