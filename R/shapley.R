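#' Exact coalitional Shapley values
#'
#' Computes the Shapley attribution of a scalar model output to each
#' feature by full subset enumeration:
#' `phi_i = sum over S subset of N\{i} of |S|!(|N|-|S|-1)!/|N|! * (v(S u {i}) - v(S))`,
#' where the coalition value `v(S)` is the mean model output over the
#' background rows with the features in S taken from the explained instance
#' and the remaining features taken from the background row. The background
#' can be a single baseline vector or a sample of training rows. Exact
#' enumeration costs `2^p` coalition evaluations and is refused above
#' `p_limit` features (use [sampled_shapley()] there).
#'
#' The returned values satisfy the efficiency axiom
#' `sum(phi) = f(x) - base_value` up to floating-point error, where
#' `base_value = v(empty set)` is the expected model output over the
#' background.
#'
#' @param model_fn Function mapping a numeric matrix (rows = instances) to a
#'   numeric score vector.
#' @param x Numeric feature vector of the instance to explain.
#' @param background Numeric matrix of background rows (or a single vector).
#' @param p_limit Maximum feature count for exact enumeration (default 16).
#' @return A `shapley_explanation`: list with `phi` (named), `base_value`,
#'   `fx`, and `method = "exact"`.
#' @export
exact_shapley <- function(model_fn, x, background, p_limit = 16L) {
  x <- as.numeric(unlist(x))
  p <- length(x)
  if (p > p_limit) {
    stop_actidep(paste0("%d features exceed the exact enumeration limit ",
                        "(%d); use sampled_shapley()"), p, p_limit,
                 class = "actidep_shapley_error")
  }
  bg <- if (is.matrix(background)) background else matrix(background, nrow = 1)
  stopifnot(ncol(bg) == p, nrow(bg) >= 1)
  B <- nrow(bg)
  n_sub <- 2^p
  # v(S) for every coalition, evaluated in one batched model call per chunk
  masks <- matrix(FALSE, n_sub, p)
  for (j in seq_len(p)) {
    masks[, j] <- bitwAnd(0:(n_sub - 1), bitwShiftL(1L, j - 1L)) > 0
  }
  v <- numeric(n_sub)
  chunk <- max(1L, floor(20000 / B))
  for (start in seq(1L, n_sub, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n_sub)
    rows <- matrix(0, length(idx) * B, p)
    for (ii in seq_along(idx)) {
      block <- bg
      s <- masks[idx[ii], ]
      if (any(s)) block[, s] <- matrix(x[s], B, sum(s), byrow = TRUE)
      rows[((ii - 1) * B + 1):(ii * B), ] <- block
    }
    colnames(rows) <- colnames(bg)
    preds <- model_fn(rows)
    v[idx] <- colMeans(matrix(preds, B, length(idx)))
  }
  sizes <- rowSums(masks)
  wts <- exp(lfactorial(0:(p - 1)) + lfactorial(p - 1 - (0:(p - 1))) -
               lfactorial(p))
  phi <- numeric(p)
  for (j in seq_len(p)) {
    bit <- bitwShiftL(1L, j - 1L)
    without <- which(!masks[, j])
    with_j <- without + bit
    phi[j] <- sum(wts[sizes[without] + 1] * (v[with_j] - v[without]))
  }
  names(phi) <- colnames(bg) %||% paste0("f", seq_len(p))
  structure(list(phi = phi, base_value = v[1], fx = v[n_sub],
                 method = "exact"),
            class = "shapley_explanation")
}

#' Permutation-sampling Shapley estimate
#'
#' Monte-Carlo estimate of the exact coalitional Shapley values: for each
#' sampled feature permutation the marginal contribution of every feature
#' is its change in coalition value when added in permutation order. The
#' estimator is unbiased; after averaging, a final additive renormalization
#' distributes the residual `f(x) - base - sum(phi)` equally so the
#' efficiency axiom holds exactly (flagged in the output).
#'
#' @inheritParams exact_shapley
#' @param n_permutations Number of sampled permutations (>= 1).
#' @param seed Integer seed; identical seeds give identical estimates.
#' @return A `shapley_explanation` with `method = "sampled"` and
#'   `renormalized = TRUE`.
#' @export
sampled_shapley <- function(model_fn, x, background, n_permutations = 200L,
                            seed = 1L) {
  stopifnot(n_permutations >= 1)
  x <- as.numeric(unlist(x))
  p <- length(x)
  bg <- if (is.matrix(background)) background else matrix(background, nrow = 1)
  B <- nrow(bg)
  base_value <- mean(model_fn(bg))
  fx <- mean(model_fn(matrix(x, B, p, byrow = TRUE,
                             dimnames = list(NULL, colnames(bg)))))
  phi <- numeric(p)
  with_seed(seed, {
    for (it in seq_len(n_permutations)) {
      perm <- sample.int(p)
      # rows: coalition grows one feature at a time; batch all p+1 stages
      rows <- matrix(0, (p + 1) * B, p)
      block <- bg
      rows[1:B, ] <- block
      for (step in seq_len(p)) {
        block[, perm[step]] <- x[perm[step]]
        rows[(step * B + 1):((step + 1) * B), ] <- block
      }
      colnames(rows) <- colnames(bg)
      vals <- colMeans(matrix(model_fn(rows), B, p + 1))
      phi[perm] <- phi[perm] + diff(vals)
    }
  })
  phi <- phi / n_permutations
  phi <- phi + (fx - base_value - sum(phi)) / p
  names(phi) <- colnames(bg) %||% paste0("f", seq_len(p))
  structure(list(phi = phi, base_value = base_value, fx = fx,
                 method = "sampled", renormalized = TRUE,
                 n_permutations = n_permutations),
            class = "shapley_explanation")
}

#' @export
print.shapley_explanation <- function(x, ...) {
  cat(sprintf("<shapley_explanation> (%s) f(x) = %.4f, base = %.4f\n",
              x$method, x$fx, x$base_value))
  ord <- order(-abs(x$phi))
  for (i in head(ord, 5)) {
    cat(sprintf("  %-20s %+0.4f\n", names(x$phi)[i], x$phi[i]))
  }
  invisible(x)
}

#' Global mean-|phi| feature importance
#'
#' Aggregates per-instance Shapley explanations into a global importance
#' ranking: the mean absolute attribution per feature, sorted descending.
#'
#' @param explanations Non-empty list of `shapley_explanation` objects with
#'   a consistent feature order.
#' @param model_tag Optional label for the model that produced them.
#' @return An `importance_ranking` data.frame with `feature`,
#'   `mean_abs_phi` and `rank`.
#' @export
global_importance <- function(explanations, model_tag = "") {
  stopifnot(length(explanations) > 0)
  feat <- names(explanations[[1]]$phi)
  mat <- vapply(explanations, function(e) {
    stopifnot(identical(names(e$phi), feat))
    abs(e$phi)
  }, numeric(length(feat)))
  mat <- matrix(mat, nrow = length(feat))
  imp <- rowMeans(mat)
  ord <- order(-imp)
  out <- data.frame(feature = feat[ord], mean_abs_phi = imp[ord],
                    rank = seq_along(feat))
  attr(out, "model_tag") <- model_tag
  class(out) <- c("importance_ranking", class(out))
  out
}

#' Compare importance rankings across models
#'
#' Rank-based agreement between two models' global importance rankings.
#' Comparisons stay within each model's own attribution scale (rankings,
#' never raw magnitudes, since attribution scales differ across model
#' families): Spearman rank correlation, top-k overlap, and per-feature
#' rank deltas.
#'
#' @param rank_a,rank_b `importance_ranking` objects over the same features.
#' @param top_k Size of the head overlap (default 5).
#' @return List with `rank_correlation`, `top_k_overlap`, `top_k`, and a
#'   per-feature `deltas` data.frame.
#' @export
compare_model_explanations <- function(rank_a, rank_b, top_k = 5L) {
  if (!setequal(rank_a$feature, rank_b$feature)) {
    stop_actidep("importance rankings cover different feature sets",
                 class = "actidep_validation_error")
  }
  ra <- rank_a$rank[match(rank_a$feature, rank_a$feature)]
  names(ra) <- rank_a$feature
  rb <- rank_b$rank[match(rank_a$feature, rank_b$feature)]
  rho <- stats::cor(ra, rb, method = "spearman")
  overlap <- length(intersect(head(rank_a$feature, top_k),
                              head(rank_b$feature, top_k)))
  list(rank_correlation = rho,
       top_k_overlap = overlap,
       top_k = top_k,
       deltas = data.frame(feature = rank_a$feature,
                           rank_a = ra, rank_b = rb,
                           delta = rb - ra))
}
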