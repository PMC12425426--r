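# Independent brute-force oracle: enumerate subsets directly from the
# coalition-weight definition, evaluating the value function naively.
brute_shapley <- function(model_fn, x, bg) {
  p <- length(x)
  v <- function(S) {
    rows <- bg
    if (length(S) > 0) {
      rows[, S] <- matrix(x[S], nrow(bg), length(S), byrow = TRUE)
    }
    mean(model_fn(rows))
  }
  phi <- numeric(p)
  for (i in seq_len(p)) {
    others <- setdiff(seq_len(p), i)
    for (sz in 0:(p - 1)) {
      subsets <- if (sz == 0) list(integer(0)) else
        asplit(utils::combn(others, sz), 2)
      w <- factorial(sz) * factorial(p - sz - 1) / factorial(p)
      for (S in subsets) {
        phi[i] <- phi[i] + w * (v(c(as.integer(S), i)) - v(as.integer(S)))
      }
    }
  }
  phi
}

lin_model <- function(w) function(M) as.numeric(M %*% w)

test_that("exact Shapley recovers the linear closed form and matches brute force", {
  w <- c(1.5, -2, 0.5, 3)
  b <- c(0.2, 0.1, -0.3, 0)
  x <- c(1, 2, -1, 0.5)
  bg <- matrix(b, 1, 4, dimnames = list(NULL, paste0("f", 1:4)))
  ex <- exact_shapley(lin_model(w), x, bg)
  expect_equal(unname(ex$phi), w * (x - b), tolerance = 1e-12)
  expect_equal(unname(ex$phi), brute_shapley(lin_model(w), x, bg),
               tolerance = 1e-12)

  # nonlinear model against the brute-force oracle, multi-row background
  withr::with_seed(3, bg2 <- matrix(rnorm(12), 3, 4,
                                    dimnames = list(NULL, paste0("f", 1:4))))
  nl <- function(M) M[, 1] * M[, 2] + exp(M[, 3] / 3) - abs(M[, 4])
  ex2 <- exact_shapley(nl, x, bg2)
  expect_equal(unname(ex2$phi), brute_shapley(nl, x, bg2), tolerance = 1e-10)
})

test_that("Shapley axioms hold: efficiency, dummy, symmetry", {
  withr::with_seed(5, {
    bg <- matrix(rnorm(30), 6, 5, dimnames = list(NULL, paste0("f", 1:5)))
    x <- rnorm(5)
  })
  # dummy: a feature the model ignores gets exactly zero
  ignores_3 <- function(M) M[, 1]^2 + 2 * M[, 2] - M[, 4] * M[, 5]
  ex <- exact_shapley(ignores_3, x, bg)
  expect_equal(unname(ex$phi[3]), 0, tolerance = 1e-12)

  # efficiency for an arbitrary nonlinear model
  f <- function(M) tanh(M[, 1]) + M[, 2] * M[, 3] - 0.5 * M[, 4]^2 + M[, 5]
  ex2 <- exact_shapley(f, x, bg)
  expect_equal(sum(ex2$phi), ex2$fx - ex2$base_value, tolerance = 1e-8)

  # symmetry: two features entering identically get equal attributions
  sym <- function(M) (M[, 1] + M[, 2])^2 + M[, 3]
  x_sym <- c(0.7, 0.7, -1, 0.2, 0.4)
  bg_sym <- bg
  bg_sym[, 2] <- bg_sym[, 1]
  ex3 <- exact_shapley(sym, x_sym, bg_sym)
  expect_equal(unname(ex3$phi[1]), unname(ex3$phi[2]), tolerance = 1e-10)
})

test_that("feature counts above the enumeration limit are refused", {
  bg <- matrix(0, 1, 20)
  expect_error(exact_shapley(function(M) rowSums(M), rnorm(20), bg),
               "sampled_shapley", class = "actidep_shapley_error")
})

test_that("sampled Shapley converges to the exact values and is seeded", {
  withr::with_seed(11, {
    bg <- matrix(rnorm(18), 3, 6, dimnames = list(NULL, paste0("f", 1:6)))
    x <- rnorm(6)
  })
  f <- function(M) M[, 1] * M[, 2] - 2 * M[, 3] + M[, 4]^2 + M[, 5] - M[, 6]
  ex <- exact_shapley(f, x, bg)
  sa <- sampled_shapley(f, x, bg, n_permutations = 2000, seed = 2)
  rng <- diff(range(c(ex$fx, ex$base_value, ex$phi)))
  expect_lt(max(abs(sa$phi - ex$phi)), 0.02 * rng)
  # efficiency enforced exactly by renormalization
  expect_equal(sum(sa$phi), sa$fx - sa$base_value, tolerance = 1e-10)
  expect_true(sa$renormalized)

  sb <- sampled_shapley(f, x, bg, n_permutations = 2000, seed = 2)
  expect_identical(sa$phi, sb$phi)

  # error is non-increasing in permutations (averaged over seeds)
  err_at <- function(n) {
    mean(vapply(1:10, function(s) {
      max(abs(sampled_shapley(f, x, bg, n, seed = s)$phi - ex$phi))
    }, numeric(1)))
  }
  expect_lte(err_at(800), err_at(100) + 1e-9)
})

test_that("global importance ranks by mean |phi| and ignores list order", {
  mk <- function(phi) structure(list(phi = phi, base_value = 0, fx = sum(phi),
                                     method = "exact"),
                                class = "shapley_explanation")
  e1 <- mk(c(a = 1, b = -3, c = 0.5))
  e2 <- mk(c(a = -2, b = 1, c = 0.1))
  r <- global_importance(list(e1, e2))
  expect_identical(r$feature, c("b", "a", "c"))
  expect_equal(r$mean_abs_phi, c(2, 1.5, 0.3))
  r_perm <- global_importance(list(e2, e1))
  expect_identical(r$feature, r_perm$feature)
  expect_equal(r$mean_abs_phi, r_perm$mean_abs_phi)

  single <- global_importance(list(e1))
  expect_identical(single$feature, c("b", "a", "c"))
})

test_that("cross-model ranking comparison reports rank agreement", {
  mk_rank <- function(features) {
    structure(data.frame(feature = features,
                         mean_abs_phi = seq(1, 0.1, length.out = length(features)),
                         rank = seq_along(features)),
              class = c("importance_ranking", "data.frame"))
  }
  a <- mk_rank(c("x", "y", "z", "w"))
  expect_equal(compare_model_explanations(a, a, top_k = 3)$rank_correlation, 1)
  expect_equal(compare_model_explanations(a, a, top_k = 3)$top_k_overlap, 3)

  rev_b <- mk_rank(rev(c("x", "y", "z", "w")))
  expect_equal(compare_model_explanations(a, rev_b)$rank_correlation, -1)

  expect_error(compare_model_explanations(a, mk_rank(c("x", "y", "z", "q"))),
               class = "actidep_validation_error")
})
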