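#' LIME-style local surrogate explanation
#'
#' Explains one prediction by fitting a proximity-weighted sparse linear
#' surrogate to perturbations around the instance. Features are discretized
#' into quartile bins of the training data; each perturbation redraws every
#' feature's bin uniformly (keeping the instance's own value when its bin is
#' redrawn, otherwise sampling uniformly inside the drawn bin), giving a
#' binary interpretable representation `z_j = 1` when feature j stays in the
#' instance's bin. Samples are weighted by an exponential kernel on the
#' binary Hamming distance, and a ridge-regularized weighted least squares
#' fit over the binary design yields one signed weight per feature. Each
#' weight is reported as a threshold rule over the instance's bin, e.g.
#' `"0.74 < autocorr <= 0.78"`.
#'
#' @param model_fn Function mapping a numeric matrix to a score vector
#'   (e.g. the probability of one class).
#' @param x Numeric feature vector of the instance.
#' @param training Numeric matrix of training rows supplying the quartiles
#'   and ranges of the perturbation space.
#' @param n_samples Number of perturbation samples (default 5000).
#' @param kernel_width Width of the exponential kernel; default
#'   `0.75 * sqrt(p)`.
#' @param ridge Ridge penalty on the surrogate coefficients (default 0.01).
#' @param top_k Number of rules to report (default 10).
#' @param seed Integer seed; fixed seeds give identical rules and weights.
#' @return A `lime_explanation`: list with `rules` (data.frame of rule
#'   strings, features and weights, by decreasing |weight|), `intercept`,
#'   `r_squared`, `prediction`, and the sampling settings.
#' @export
lime_explain <- function(model_fn, x, training, n_samples = 5000L,
                         kernel_width = NULL, ridge = 0.01, top_k = 10L,
                         seed = 1L) {
  x <- as.numeric(unlist(x))
  p <- length(x)
  training <- as.matrix(training)
  stopifnot(ncol(training) == p)
  feat <- colnames(training) %||% paste0("f", seq_len(p))
  kernel_width <- kernel_width %||% (0.75 * sqrt(p))
  # quartile discretization; degenerate features get one bin and no rule
  bins <- lapply(seq_len(p), function(j) {
    qs <- unique(quantile(training[, j], c(0.25, 0.5, 0.75), names = FALSE))
    qs[!duplicated(qs)]
  })
  usable <- vapply(bins, length, integer(1)) >= 1 &
    vapply(seq_len(p), function(j) {
      diff(range(training[, j])) > 0
    }, logical(1))
  if (any(!usable)) {
    warning(sprintf("feature(s) with degenerate spread excluded from rules: %s",
                    paste(feat[!usable], collapse = ", ")))
  }
  bin_of <- function(j, value) findInterval(value, bins[[j]]) + 1L
  lo <- apply(training, 2, min)
  hi <- apply(training, 2, max)
  bin_bounds <- function(j, b) {
    edges <- c(lo[j], bins[[j]], hi[j])
    c(edges[b], edges[b + 1])
  }
  x_bin <- vapply(seq_len(p), function(j) bin_of(j, x[j]), integer(1))
  res <- with_seed(seed, {
    Z <- matrix(1L, n_samples, p)   # first sample is the instance itself
    Xp <- matrix(x, n_samples, p, byrow = TRUE)
    for (j in which(usable)) {
      nb <- length(bins[[j]]) + 1L
      draw <- sample.int(nb, n_samples - 1, replace = TRUE)
      Z[-1, j] <- as.integer(draw == x_bin[j])
      moved <- which(draw != x_bin[j]) + 1L
      if (length(moved) > 0) {
        bd <- vapply(draw[moved - 1L], function(b) bin_bounds(j, b),
                     numeric(2))
        Xp[moved, j] <- runif(length(moved), bd[1, ], bd[2, ])
      }
    }
    colnames(Xp) <- feat
    y <- model_fn(Xp)
    d <- sqrt(rowSums((Z - 1)^2))           # binary Hamming distance
    w <- exp(-d^2 / kernel_width^2)
    # weighted ridge with unpenalized intercept
    Zu <- Z[, usable, drop = FALSE]
    A <- cbind(1, Zu)
    WA <- A * w
    gram <- crossprod(WA, A)
    pen <- diag(c(0, rep(ridge, ncol(Zu))))
    beta <- solve(gram + pen, crossprod(WA, y))
    fitted <- as.numeric(A %*% beta)
    ss_res <- sum(w * (y - fitted)^2)
    ss_tot <- sum(w * (y - sum(w * y) / sum(w))^2)
    list(beta = beta, r2 = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot,
         pred = y[1])
  })
  weights <- as.numeric(res$beta[-1])
  used <- which(usable)
  rules <- vapply(seq_along(used), function(ii) {
    j <- used[ii]
    bd <- bin_bounds(j, x_bin[j])
    b <- x_bin[j]
    nb <- length(bins[[j]]) + 1L
    if (b == 1) sprintf("%s <= %.4g", feat[j], bins[[j]][1])
    else if (b == nb) sprintf("%s > %.4g", feat[j], bins[[j]][b - 1])
    else sprintf("%.4g < %s <= %.4g", bins[[j]][b - 1], feat[j], bins[[j]][b])
  }, character(1))
  ord <- order(-abs(weights))
  keep <- head(ord, top_k)
  structure(list(rules = data.frame(feature = feat[used][keep],
                                    rule = rules[keep],
                                    weight = weights[keep]),
                 intercept = as.numeric(res$beta[1]),
                 r_squared = res$r2,
                 prediction = res$pred,
                 n_samples = n_samples, kernel_width = kernel_width,
                 seed = seed),
            class = "lime_explanation")
}

#' @export
print.lime_explanation <- function(x, ...) {
  cat(sprintf("<lime_explanation> prediction %.4f, intercept %.4f, R^2 %.3f\n",
              x$prediction, x$intercept, x$r_squared))
  for (i in seq_len(min(5, nrow(x$rules)))) {
    cat(sprintf("  %+0.4f  %s\n", x$rules$weight[i], x$rules$rule[i]))
  }
  invisible(x)
}
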