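test_that("time-domain features follow the stated conventions", {
  # constant window: degenerate conventions
  f_const <- time_domain_features(rep(7, 100))
  expect_equal(f_const[["mean"]], 7)
  expect_equal(f_const[["sd"]], 0)
  expect_equal(f_const[["entropy"]], 0)
  expect_equal(f_const[["autocorr"]], 0)
  expect_equal(f_const[["skewness"]], 0)

  # mirrored window: zero skewness
  x <- c(1, 2, 3, 7, 11, 12, 13)
  expect_equal(time_domain_features(x)[["skewness"]], 0, tolerance = 1e-12)

  # linear-interpolation quantile IQR
  expect_equal(time_domain_features(as.numeric(0:99))[["iqr"]], 49.5)
})

test_that("entropy-type features are scale invariant; moments scale linearly", {
  withr::with_seed(8, x <- rpois(1440, 20) * runif(1440, 0.5, 2))
  f1 <- time_domain_features(x)
  f3 <- time_domain_features(3 * x)
  expect_equal(f3[["entropy"]], f1[["entropy"]])
  expect_equal(f3[["mean"]], 3 * f1[["mean"]])
  expect_equal(f3[["sd"]], 3 * f1[["sd"]])
  expect_equal(transition_entropy(3 * x), transition_entropy(x))
  s1 <- frequency_domain_features(x)[["spectral_entropy"]]
  s3 <- frequency_domain_features(3 * x)[["spectral_entropy"]]
  expect_equal(s3, s1, tolerance = 1e-10)
})

test_that("spectral features identify tones and flat spectra", {
  t <- 0:1439
  cosine <- 100 * cos(2 * pi * t / 360) + 200
  fd <- frequency_domain_features(cosine)
  # dominant frequency lands on the Welch grid bin nearest 1/360 cycles/min
  grid <- (1:128) / 256
  expect_equal(fd[["dominant_frequency"]], grid[which.min(abs(grid - 1 / 360))])
  expect_lt(fd[["spectral_entropy"]], 0.2)

  # white noise: near-maximal spectral entropy in >= 95% of 200 draws
  high <- withr::with_seed(99, {
    vapply(1:200, function(i) {
      frequency_domain_features(rnorm(1440, 200, 25))[["spectral_entropy"]]
    }, numeric(1))
  })
  expect_gte(mean(high > 0.9), 0.95)

  # all-zero window: undefined dominant frequency
  fz <- frequency_domain_features(numeric(1440))
  expect_equal(fz[["psd_mean"]], 0)
  expect_true(is.na(fz[["dominant_frequency"]]))
})

test_that("PSD estimator satisfies a Parseval-style variance identity", {
  withr::with_seed(4, {
    for (i in 1:5) {
      x <- rnorm(1440)
      est <- actidep:::welch_psd(x)
      recovered <- sum(est$psd) / 256
      expect_equal(recovered, mean((x - mean(x))^2), tolerance = 0.05)
    }
  })
})

test_that("circadian onset/offset recover a square activity block", {
  sq <- square_day(on = 480, off = 1320)
  cf <- circadian_features(sq)
  expect_lt(abs(cf[["activity_onset"]] - 480), 31)
  expect_lt(abs(cf[["activity_offset"]] - 1320), 31)
  expect_lte(cf[["activity_onset"]], cf[["activity_offset"]])

  flat <- circadian_features(numeric(1440))
  expect_true(all(is.na(flat)))
})

test_that("circadian onset tracks the generator's planted phase", {
  # For the raised-cosine template the smoothed profile crosses the daily
  # mean at an analytically known offset after the configured phase:
  # the day's mean is A*f/2 (f = span/1440), and 0.5*(1 - cos(2*pi*u/span))
  # = f/2 at u = span * acos(1 - f) / (2*pi). Recovery is within the
  # smoothing half-width of that ground truth.
  span <- 960
  f <- span / 1440
  crossing <- span * acos(1 - f) / (2 * pi)
  cfg <- synthetic_cohort_config(
    n_condition = 0, n_control = 6, days_per_participant = 1,
    onset_phase = list(condition = 420, control = 420), phase_sd = 0,
    active_span = list(condition = span, control = span), span_sd = 0,
    ar_sd = 0, noise_scale = 5,
    basal_mean = list(condition = 0, control = 0), basal_sd = 0, seed = 31)
  coh <- generate_cohort(cfg)
  onsets <- vapply(coh$participants, function(r) {
    circadian_features(as.numeric(r$epochs$count))[["activity_onset"]]
  }, numeric(1))
  expect_true(all(abs(onsets - (420 + crossing)) <= 45))
})

test_that("transition entropy spans its [0, 1] range as dynamics demand", {
  expect_equal(transition_entropy(rep(5, 100)), 0)
  expect_equal(transition_entropy(rep(1:3, 100)), 0)
  withr::with_seed(6, {
    iid <- sample(1:3, 1e5, replace = TRUE)
  })
  expect_equal(transition_entropy(iid), 1, tolerance = 0.02)
  expect_warning(transition_entropy(c(1, 2, 3, 1)), "short")
})

test_that("feature matrix counts rows, drops flat days, and is deterministic", {
  cfg <- tiny_cohort_config(seed = 44, days = 2, n_cond = 1, n_ctrl = 1)
  coh <- generate_cohort(cfg)
  fm <- build_feature_matrix(coh)
  expect_identical(dim(fm$X), c(4L, 15L))
  expect_identical(colnames(fm$X), c(activity_feature_names(), "age", "gender"))

  # inject a flat day into one participant: one fewer row, one drop log entry
  coh2 <- coh
  coh2$participants[[1]]$epochs$count[1:1440] <- 0L
  fm2 <- build_feature_matrix(coh2)
  expect_identical(nrow(fm2$X), 3L)
  expect_identical(nrow(fm2$drop_log), 1L)

  fm3 <- build_feature_matrix(coh)
  expect_identical(fm$X, fm3$X)
})

test_that("z-score scaler matches its closed form and round-trips its fit set", {
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  sc <- fit_scaler(X)
  z <- apply_scaler(sc, X)
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449), tolerance = 1e-6)

  # already standardized columns are unchanged
  Z <- matrix(c(-1, 0, 1) / sqrt(2 / 3), 3, 1, dimnames = list(NULL, "a"))
  expect_equal(apply_scaler(fit_scaler(Z), Z), Z)

  # constant column maps to zeros with a warning
  Xc <- cbind(X, b = c(4, 4, 4))
  expect_warning(zc <- apply_scaler(fit_scaler(Xc), Xc), "constant")
  expect_true(all(zc[, "b"] == 0))

  # self-standardization: mean 0, population sd 1 on every non-constant column
  withr::with_seed(2, M <- matrix(rnorm(200, 5, 3), 40, 5,
                                  dimnames = list(NULL, letters[1:5])))
  Zs <- apply_scaler(fit_scaler(M), M)
  expect_true(all(abs(colMeans(Zs)) < 1e-9))
  expect_true(all(abs(sqrt(colMeans(sweep(Zs, 2, colMeans(Zs))^2)) - 1) < 1e-9))

  expect_error(apply_scaler(list(), X), class = "actidep_validation_error")
})
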