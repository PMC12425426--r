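#' Group-aware repeated stratified cross-validation
#'
#' Runs the evaluation protocol: `repeats` repetitions of stratified k-fold
#' cross-validation (default 3 x 10 = 30 folds), with every model scored on
#' the identical fold sequence so per-fold scores are paired. Stratification
#' and fold assignment operate on participants, not windows: all windows of
#' a participant stay in the same fold, preventing identity leakage from
#' adjacent days of the same person. Within each training fold the z-score
#' scaler is fitted, both partitions are standardized, and (optionally)
#' ADASYN oversamples the minority classes of the training rows only. The
#' per-fold score is the F1 of the held-out windows (binary: class 1
#' positive; multiclass: support-weighted); fold confusions are pooled per
#' model for the remaining metrics.
#'
#' @param fm A `feature_matrix` from [build_feature_matrix()].
#' @param task `"binary"` or `"severity"`.
#' @param models Character vector of model names (default: all five).
#' @param repeats,k Protocol shape (default 3 repeats of 10 folds).
#' @param seed Integer seed driving fold assignment, ADASYN and training.
#' @param use_adasyn Oversample training folds (default TRUE).
#' @param hyperparams Optional named list of per-model overrides.
#' @param adasyn A base [adasyn_config()] (its seed is re-derived per fold).
#' @return A `cv_result`: per-model list with `scores` (length repeats*k),
#'   `mean`, `sd`, and `pooled_cm`; plus the fold assignment table.
#' @export
repeated_stratified_cv <- function(fm, task = c("binary", "severity"),
                                   models = classifier_names(),
                                   repeats = 3L, k = 10L, seed = 1L,
                                   use_adasyn = TRUE,
                                   hyperparams = NULL,
                                   adasyn = adasyn_config()) {
  task <- match.arg(task)
  y_all <- if (task == "binary") fm$binary else fm$severity
  keep <- !is.na(y_all)
  X <- fm$X[keep, , drop = FALSE]
  y <- y_all[keep]
  pid <- fm$participant_id[keep]
  stopifnot(repeats * k >= 2)
  # participant-level labels (windows inherit the participant's label)
  p_tab <- unique(data.frame(pid = pid, y = y))
  if (anyDuplicated(p_tab$pid)) {
    stop_actidep("participants with inconsistent labels",
                 class = "actidep_validation_error")
  }
  cls_sizes <- table(p_tab$y)
  if (any(cls_sizes < k)) {
    stop_actidep("class %s has %d participants, fewer than k = %d folds",
                 names(cls_sizes)[which.min(cls_sizes)], min(cls_sizes), k,
                 class = "actidep_validation_error")
  }
  classes <- sort(unique(y))
  n_folds <- repeats * k
  scores <- matrix(NA_real_, n_folds, length(models),
                   dimnames = list(NULL, models))
  pooled <- lapply(models, function(m) {
    matrix(0L, length(classes), length(classes),
           dimnames = list(true = classes, predicted = classes))
  })
  names(pooled) <- models
  assignments <- list()
  fold_idx <- 0L
  for (rep_i in seq_len(repeats)) {
    fold_of <- with_seed(child_seed(seed, rep_i), {
      f <- integer(nrow(p_tab))
      for (cls in unique(p_tab$y)) {
        members <- which(p_tab$y == cls)
        f[members[sample.int(length(members))]] <-
          rep_len(seq_len(k), length(members))
      }
      f
    })
    assignments[[rep_i]] <- data.frame(pid = p_tab$pid, repeat_i = rep_i,
                                       fold = fold_of)
    for (fold in seq_len(k)) {
      fold_idx <- fold_idx + 1L
      test_pids <- p_tab$pid[fold_of == fold]
      is_test <- pid %in% test_pids
      scaler <- fit_scaler(X[!is_test, , drop = FALSE])
      Xtr <- apply_scaler(scaler, X[!is_test, , drop = FALSE])
      Xte <- apply_scaler(scaler, X[is_test, , drop = FALSE])
      ytr <- y[!is_test]
      yte <- y[is_test]
      if (use_adasyn) {
        cfg_fold <- adasyn
        cfg_fold$seed <- child_seed(seed, 1000 + fold_idx)
        aug <- adasyn_oversample(Xtr, ytr, cfg_fold)
        Xtr <- aug$X
        ytr <- aug$y
      }
      for (m in models) {
        fit <- train_classifier(m, Xtr, ytr, hyperparams[[m]],
                                seed = child_seed(seed, 2000 + fold_idx))
        pred <- predict(fit, Xte, type = "class")
        cm <- confusion(yte, pred, classes)
        pooled[[m]] <- pooled[[m]] + cm
        rep_avg <- if (length(classes) == 2) "binary" else "weighted"
        scores[fold_idx, m] <- metric_suite(cm, rep_avg)$f1
      }
    }
  }
  per_model <- lapply(models, function(m) {
    list(model = m, scores = scores[, m], mean = mean(scores[, m]),
         sd = sd(scores[, m]), pooled_cm = pooled[[m]])
  })
  names(per_model) <- models
  structure(list(task = task, models = per_model,
                 repeats = repeats, k = k, seed = seed,
                 fold_assignments = do.call(rbind, assignments)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s task, %d x %d folds\n", x$task, x$repeats, x$k))
  for (m in x$models) {
    cat(sprintf("  %-18s F1 = %.3f +/- %.3f\n", m$model, m$mean, m$sd))
  }
  invisible(x)
}

#' Paired two-tailed t test on fold scores
#'
#' Tests whether the mean of the per-fold differences `a - b` is zero,
#' using the t distribution with n - 1 degrees of freedom. Degenerate
#' cases follow explicit conventions: all differences zero gives p = 1
#' (no evidence of any difference); all differences equal and nonzero
#' gives p = 0 with a `degenerate` flag (zero variance but a systematic
#' difference). Both warn.
#'
#' @param a,b Equal-length numeric score vectors (length >= 2), paired by
#'   fold.
#' @return List with `t`, `p`, `df`, `mean_diff`, `degenerate`.
#' @export
paired_t_test <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  n <- length(d)
  if (sd(d) == 0) {
    if (all(d == 0)) {
      warning("all paired differences are zero; p = 1 by convention")
      return(list(t = NA_real_, p = 1, df = n - 1, mean_diff = 0,
                  degenerate = TRUE))
    }
    warning("paired differences identical and nonzero; p -> 0 limit")
    return(list(t = sign(d[1]) * Inf, p = 0, df = n - 1,
                mean_diff = mean(d), degenerate = TRUE))
  }
  t_stat <- mean(d) / (sd(d) / sqrt(n))
  list(t = t_stat, p = 2 * pt(-abs(t_stat), df = n - 1), df = n - 1,
       mean_diff = mean(d), degenerate = FALSE)
}

#' Holm step-down adjustment
#'
#' Adjusts a vector of p values by the Holm step-down procedure (via
#' `stats::p.adjust`), which controls the family-wise error rate and is
#' uniformly at least as powerful as Bonferroni. Rejections are flagged at
#' `alpha`.
#'
#' @param pvalues Numeric vector of raw p values in \[0, 1\].
#' @param alpha Family-wise error rate (default 0.05).
#' @param comparisons Optional labels for the rows.
#' @return Data.frame with `comparison`, `p_raw`, `p_adjusted`, `reject`,
#'   in the input order.
#' @export
holm_adjust <- function(pvalues, alpha = 0.05, comparisons = NULL) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  adj <- p.adjust(pvalues, method = "holm")
  data.frame(comparison = comparisons %||%
               paste0("comparison_", seq_along(pvalues)),
             p_raw = pvalues, p_adjusted = adj,
             reject = adj <= alpha)
}

#' Paired-t + Holm significance protocol
#'
#' Compares a reference model (default the gradient-boosted trees) against
#' every rival on the paired per-fold F1 scores of a [repeated_stratified_cv()]
#' run: one paired two-tailed t test per rival, then Holm correction at
#' `alpha`.
#'
#' @param cv A `cv_result`.
#' @param reference Model name used as the comparison anchor.
#' @param alpha Family-wise error rate.
#' @return A `significance_report` data.frame with per-comparison t, raw and
#'   Holm-adjusted p, and the rejection flag.
#' @export
significance_report <- function(cv, reference = "gradient_boosting",
                                alpha = 0.05) {
  stopifnot(reference %in% names(cv$models))
  rivals <- setdiff(names(cv$models), reference)
  if (length(rivals) == 0) {
    stop_actidep("no rival models to compare against '%s'", reference,
                 class = "actidep_validation_error")
  }
  tests <- lapply(rivals, function(m) {
    paired_t_test(cv$models[[reference]]$scores, cv$models[[m]]$scores)
  })
  out <- holm_adjust(vapply(tests, `[[`, numeric(1), "p"), alpha,
                     comparisons = paste(reference, "vs", rivals))
  out$t <- vapply(tests, `[[`, numeric(1), "t")
  out$mean_diff <- vapply(tests, `[[`, numeric(1), "mean_diff")
  out$alpha <- alpha
  class(out) <- c("significance_report", class(out))
  out
}
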