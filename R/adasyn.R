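#' ADASYN configuration
#'
#' @param K Neighbor count for the difficulty weighting and synthesis
#'   partners (default 5).
#' @param beta Desired balance level in \[0, 1\]; 1 equalizes class counts.
#' @param seed Integer seed for the synthesis randomness.
#' @return A list of class `adasyn_config`.
#' @export
adasyn_config <- function(K = 5L, beta = 1, seed = 1L) {
  stopifnot(K >= 1, beta >= 0, beta <= 1)
  structure(list(K = as.integer(K), beta = beta, seed = seed),
            class = "adasyn_config")
}

# Squared Euclidean distances between rows of A and rows of B.
pairwise_sqdist <- function(A, B) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  outer(an, bn, "+") - 2 * tcrossprod(A, B)
}

#' Per-point ADASYN synthesis budgets
#'
#' For one minority class versus the pooled rest: each minority point i gets
#' a difficulty score `r_i` = (neighbors from other classes among its K
#' nearest neighbors in the full data) / K. The total budget
#' `G = (m_majority - m_minority) * beta` is allocated proportionally to the
#' normalized `r_i` with largest-remainder rounding, so budgets are
#' non-negative integers summing to G and non-decreasing in `r_i`. When no
#' minority point has majority neighbors (`r_i` all zero), the budget falls
#' back to a uniform allocation with a warning.
#'
#' @param X Numeric feature matrix (already standardized).
#' @param y Label vector.
#' @param minority_class The class to oversample.
#' @param cfg An [adasyn_config()].
#' @return Integer vector of synthesis counts, one per minority row (in the
#'   order the minority rows appear in `X`).
#' @export
per_class_budgets <- function(X, y, minority_class, cfg = adasyn_config()) {
  idx_min <- which(y == minority_class)
  m_min <- length(idx_min)
  m_max <- max(table(y))
  G <- round((m_max - m_min) * cfg$beta)
  if (G <= 0) return(integer(m_min))
  if (m_min < 2) {
    stop_actidep("minority class '%s' has fewer than 2 members",
                 minority_class, class = "actidep_adasyn_error")
  }
  K <- min(cfg$K, nrow(X) - 1)
  d2 <- pairwise_sqdist(X[idx_min, , drop = FALSE], X)
  r <- vapply(seq_len(m_min), function(i) {
    ord <- order(d2[i, ])
    nb <- setdiff(ord, idx_min[i])[seq_len(K)]
    sum(y[nb] != minority_class) / K
  }, numeric(1))
  if (sum(r) == 0) {
    warning("no borderline minority points (all r_i = 0); uniform budgets")
    r <- rep(1, m_min)
  }
  share <- r / sum(r) * G
  budget <- floor(share)
  remainder <- G - sum(budget)
  if (remainder > 0) {
    frac <- share - budget
    extra <- order(-frac, -r)[seq_len(remainder)]
    budget[extra] <- budget[extra] + 1
  }
  as.integer(budget)
}

#' Adaptive synthetic oversampling (ADASYN)
#'
#' Oversamples every minority class against the pooled rest until its count
#' reaches `beta` of the way to the largest class. Each synthetic point is
#' `s = x_i + lambda * (x_z - x_i)` with `lambda ~ U(0, 1)` and `x_z` a
#' random point among x_i's K nearest same-class neighbors, so synthetic
#' rows are convex combinations of two same-class points. Original rows are
#' returned unchanged and first; a logical `synthetic` marker identifies the
#' generated rows. Features should already be standardized (the neighbor
#' metric is Euclidean). Fixed seeds give bit-identical output.
#'
#' @param X Numeric feature matrix.
#' @param y Label vector (at least 2 classes; each minority class needs at
#'   least 2 members).
#' @param cfg An [adasyn_config()].
#' @return List with `X` (augmented matrix), `y` (augmented labels) and
#'   `synthetic` (logical vector marking generated rows).
#' @export
adasyn_oversample <- function(X, y, cfg = adasyn_config()) {
  X <- as.matrix(X)
  counts <- table(y)
  if (length(counts) < 2) {
    stop_actidep("ADASYN needs at least 2 classes", class = "actidep_adasyn_error")
  }
  m_max <- max(counts)
  minority_classes <- names(counts)[counts < m_max]
  synth_X <- list()
  synth_y <- list()
  with_seed(cfg$seed, {
    for (cls in minority_classes) {
      budget <- per_class_budgets(X, y, cls, cfg)
      if (sum(budget) == 0) next
      idx_min <- which(y == cls)
      Xmin <- X[idx_min, , drop = FALSE]
      Kn <- min(cfg$K, nrow(Xmin) - 1)
      d2 <- pairwise_sqdist(Xmin, Xmin)
      diag(d2) <- Inf
      nb <- t(apply(d2, 1, function(row) order(row)[seq_len(Kn)]))
      for (i in seq_along(budget)) {
        g <- budget[i]
        if (g == 0) next
        partners <- nb[i, sample.int(Kn, g, replace = TRUE)]
        lambda <- runif(g)
        base <- matrix(Xmin[i, ], g, ncol(X), byrow = TRUE)
        step <- Xmin[partners, , drop = FALSE] - base
        synth_X[[length(synth_X) + 1]] <- base + lambda * step
        synth_y[[length(synth_y) + 1]] <- rep(y[idx_min[i]], g)
      }
    }
  })
  if (length(synth_X) == 0) {
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  }
  Xs <- do.call(rbind, synth_X)
  colnames(Xs) <- colnames(X)
  list(X = rbind(X, Xs),
       y = c(y, unlist(synth_y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, nrow(Xs))))
}
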