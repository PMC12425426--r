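#' Default feature-extraction configuration
#'
#' Tunable parameters of the feature extractors. Defaults: lag-1
#' autocorrelation; 16-bin histogram entropy; Welch power spectral density
#' with 256-minute Hann-tapered segments at 50% overlap; circadian
#' onset/offset from a 60-minute centered rolling mean crossing 1.0 x the
#' daily mean for at least 30 consecutive minutes; 3 activity states by
#' per-window tertiles for the transition entropy.
#'
#' @param autocorr_lag Lag (minutes) of the reported autocorrelation.
#' @param entropy_bins Histogram bin count for the distributional entropy.
#' @param psd_segment Welch segment length in minutes.
#' @param psd_overlap Fractional overlap between Welch segments.
#' @param onset_threshold Multiple of the daily mean that counts as active.
#' @param onset_persistence Minimum run length (minutes) above threshold.
#' @param onset_smoothing Rolling-mean width (minutes) before thresholding.
#' @param transition_states Number of discretized activity states.
#' @return A list of class `feature_config`.
#' @export
feature_config <- function(autocorr_lag = 1L,
                           entropy_bins = 16L,
                           psd_segment = 256L,
                           psd_overlap = 0.5,
                           onset_threshold = 1.0,
                           onset_persistence = 30L,
                           onset_smoothing = 60L,
                           transition_states = 3L) {
  structure(as.list(environment()), class = "feature_config")
}

#' Time-domain summary features of an activity window
#'
#' Mean, standard deviation (sample), adjusted Fisher-Pearson skewness,
#' excess kurtosis, interquartile range (linear-interpolation quantiles),
#' lag-`autocorr_lag` sample autocorrelation, and normalized Shannon entropy
#' of a `entropy_bins`-bin histogram (in \[0, 1\]). A constant window returns
#' sd 0 and, by convention, skewness, kurtosis, autocorrelation and entropy 0.
#'
#' @param counts Numeric vector of per-minute counts (length >= 2).
#' @param cfg A [feature_config()].
#' @return Named numeric vector of the seven features.
#' @export
time_domain_features <- function(counts, cfg = feature_config()) {
  stopifnot(length(counts) >= 2)
  m <- mean(counts)
  s <- sd(counts)
  if (s == 0) {
    return(c(mean = m, sd = 0, skewness = 0, kurtosis = 0, iqr = 0,
             autocorr = 0, entropy = 0))
  }
  q <- quantile(counts, c(0.25, 0.75), type = 7, names = FALSE)
  c(mean = m,
    sd = s,
    skewness = e1071::skewness(counts, type = 2),
    kurtosis = e1071::kurtosis(counts, type = 2),
    iqr = q[2] - q[1],
    autocorr = lag_autocorr(counts, cfg$autocorr_lag),
    entropy = hist_entropy(counts, cfg$entropy_bins))
}

lag_autocorr <- function(x, lag) {
  n <- length(x)
  if (lag >= n) return(0)
  m <- mean(x)
  denom <- sum((x - m)^2)
  if (denom == 0) return(0)
  sum((x[1:(n - lag)] - m) * (x[(lag + 1):n] - m)) / denom
}

hist_entropy <- function(x, bins) {
  rng <- range(x)
  if (diff(rng) == 0) return(0)
  breaks <- seq(rng[1], rng[2], length.out = bins + 1)
  cnt <- tabulate(findInterval(x, breaks, rightmost.closed = TRUE), bins)
  p <- cnt[cnt > 0] / length(x)
  -sum(p * log(p)) / log(bins)
}

# Welch averaged modified periodogram: Hann-tapered, mean-removed segments
# with fractional overlap; one-sided PSD scaled so that
# sum(psd) * df ~= var(x) (Parseval). fs is in cycles per minute.
welch_psd <- function(x, segment = 256L, overlap = 0.5, fs = 1) {
  n <- length(x)
  stopifnot(segment >= 8, n >= segment)
  step <- max(1L, as.integer(round(segment * (1 - overlap))))
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- 0.5 * (1 - cos(2 * pi * seq_len(segment) / (segment + 1)))  # Hann
  u <- sum(w^2)
  nfreq <- floor(segment / 2)
  acc <- numeric(nfreq + 1)
  for (s0 in starts) {
    seg <- x[s0:(s0 + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(fft(seg)[1:(nfreq + 1)])^2 / (fs * u)
    acc <- acc + sp
  }
  psd <- acc / length(starts)
  # one-sided: double interior bins (not DC; not Nyquist when segment even)
  interior <- 2:(nfreq + ifelse(segment %% 2 == 0, 0, 1))
  psd[interior] <- 2 * psd[interior]
  list(freq = (0:nfreq) * fs / segment, psd = psd)
}

#' Frequency-domain features of an activity window
#'
#' Estimates the power spectral density by Welch's averaged modified
#' periodogram and reports: `psd_mean`, the mean PSD ordinate excluding DC;
#' `dominant_frequency`, the frequency (cycles per minute) of the largest
#' DC-excluded ordinate; and `spectral_entropy`, the Shannon entropy of the
#' DC-excluded normalized PSD divided by the log of the number of retained
#' bins (near 0 for a pure tone, near 1 for white noise). An all-zero window
#' has no defined dominant frequency and returns `NA` for it.
#'
#' @inheritParams time_domain_features
#' @return Named numeric vector `psd_mean`, `dominant_frequency`,
#'   `spectral_entropy`.
#' @export
frequency_domain_features <- function(counts, cfg = feature_config()) {
  stopifnot(length(counts) >= 2 * cfg$psd_segment)
  if (all(counts == counts[1])) {
    return(c(psd_mean = 0, dominant_frequency = NA_real_,
             spectral_entropy = NA_real_))
  }
  est <- welch_psd(counts, cfg$psd_segment, cfg$psd_overlap)
  p <- est$psd[-1]
  f <- est$freq[-1]
  tot <- sum(p)
  if (tot == 0) {
    return(c(psd_mean = 0, dominant_frequency = NA_real_,
             spectral_entropy = NA_real_))
  }
  pn <- p[p > 0] / tot
  c(psd_mean = mean(p),
    dominant_frequency = f[which.max(p)],
    spectral_entropy = -sum(pn * log(pn)) / log(length(p)))
}

#' Circadian activity onset and offset
#'
#' Locates the primary daily activity period in a one-day window. Counts are
#' smoothed with a centered rolling mean (circular across midnight), then
#' compared against `onset_threshold` times the daily mean; runs of at least
#' `onset_persistence` consecutive above-threshold minutes count as active.
#' Onset is the first minute-of-day of the first such run and offset the
#' last minute of the last run. A day with no sustained crossing (e.g. flat
#' activity) yields `NA` for both, and the window is dropped downstream.
#'
#' @param counts Numeric vector of length 1440 (one day of minutes).
#' @param cfg A [feature_config()].
#' @return Named numeric vector `activity_onset`, `activity_offset`
#'   (minutes-of-day in \[0, 1440\]).
#' @export
circadian_features <- function(counts, cfg = feature_config()) {
  stopifnot(length(counts) == 1440)
  k <- cfg$onset_smoothing
  smoothed <- as.numeric(stats::filter(counts, rep(1 / k, k), sides = 2,
                                       circular = TRUE))
  thr <- cfg$onset_threshold * mean(counts)
  above <- smoothed > thr
  if (!any(above) || all(above)) {
    return(c(activity_onset = NA_real_, activity_offset = NA_real_))
  }
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  keep <- r$values & r$lengths >= cfg$onset_persistence
  if (!any(keep)) {
    return(c(activity_onset = NA_real_, activity_offset = NA_real_))
  }
  c(activity_onset = starts[which(keep)[1]] - 1,
    activity_offset = ends[tail(which(keep), 1)])
}

#' Entropy of activity-state transitions
#'
#' Discretizes the window into `transition_states` states by per-window
#' quantiles, estimates the first-order transition matrix P and the
#' empirical state frequencies pi, and returns the entropy rate
#' `H = -sum_i pi_i sum_j P_ij log P_ij` normalized by `log k` so it lies in
#' \[0, 1\]: 0 for deterministic dynamics (including a constant window),
#' 1 for uniformly random transitions.
#'
#' @inheritParams time_domain_features
#' @return A number in \[0, 1\].
#' @export
transition_entropy <- function(counts, cfg = feature_config()) {
  k <- cfg$transition_states
  n <- length(counts)
  if (n < k^2) {
    warning(sprintf("window of length %d is short for %d^2 transitions", n, k))
  }
  # quantile binning via the empirical CDF (average ranks), so heavily tied
  # values (e.g. long runs of zeros) share one state instead of splitting bins
  r <- rank(counts, ties.method = "average")
  states <- pmin(k, pmax(1L, ceiling(k * r / n)))
  n_states <- max(states)
  if (length(unique(states)) < 2) return(0)  # single occupied state
  from <- states[-n]
  to <- states[-1]
  trans <- matrix(0, n_states, n_states)
  for (i in seq_along(from)) trans[from[i], to[i]] <- trans[from[i], to[i]] + 1
  row_tot <- rowSums(trans)
  pi_hat <- tabulate(states, n_states) / n
  h <- 0
  for (i in which(row_tot > 0)) {
    p <- trans[i, ] / row_tot[i]
    p <- p[p > 0]
    h <- h + pi_hat[i] * (-sum(p * log(p)))
  }
  h / log(k)
}

# Midpoint of an age-band string like "45-49" -> 47.
age_band_midpoint <- function(band) {
  parts <- strsplit(as.character(band), "-")
  vapply(parts, function(p) {
    v <- suppressWarnings(as.numeric(p))
    if (anyNA(v)) NA_real_ else mean(v)
  }, numeric(1))
}

#' Names of the extracted activity features
#' @return Character vector of the 13 activity feature names.
#' @export
activity_feature_names <- function() {
  c("mean", "sd", "skewness", "kurtosis", "iqr", "autocorr", "entropy",
    "psd_mean", "dominant_frequency", "spectral_entropy",
    "activity_onset", "activity_offset", "transition_entropy")
}

window_features <- function(counts, cfg) {
  c(time_domain_features(counts, cfg),
    frequency_domain_features(counts, cfg),
    circadian_features(counts, cfg),
    transition_entropy = transition_entropy(counts, cfg))
}

#' Build the cohort feature matrix
#'
#' One row per retained participant-day window: the 13 activity features
#' plus the participant's age (band midpoint, years) and gender (dataset
#' coding, 1 female / 2 male). Windows yielding any undefined feature (flat
#' days, zero spectra) are dropped and logged with the reason. Binary labels
#' come from group membership; severity labels from the MADRS score
#' (controls without a recorded score are class 0).
#'
#' @param cohort A `cohort`.
#' @param cfg A [feature_config()].
#' @param L Window length in minutes.
#' @param madrs_source Which score column drives severity labels:
#'   `"madrs1"` (default, pre-assessment), `"madrs2"`, or `"mean"`.
#' @param gap_tolerance Passed to [window_recording()].
#' @return A `feature_matrix`: list with `X` (numeric matrix), `binary` and
#'   `severity` label vectors, `participant_id` per row, and `drop_log`.
#' @export
build_feature_matrix <- function(cohort, cfg = feature_config(), L = 1440L,
                                 madrs_source = c("madrs1", "madrs2", "mean"),
                                 gap_tolerance = 2L) {
  madrs_source <- match.arg(madrs_source)
  stopifnot(length(cohort$participants) > 0)
  rows <- list()
  ids <- character(0)
  binary <- integer(0)
  severity <- integer(0)
  drops <- list()
  meta <- cohort$metadata
  for (rec in cohort$participants) {
    md <- meta[meta$number == rec$participant_id, , drop = FALSE]
    madrs <- switch(madrs_source,
                    madrs1 = md$madrs1,
                    madrs2 = md$madrs2,
                    mean = mean(c(md$madrs1, md$madrs2), na.rm = TRUE))
    sev <- if (!is.na(madrs)) {
      assign_severity_label(madrs)
    } else if (rec$group == "control") 0L else NA_integer_
    bin <- assign_binary_label(rec$group)
    windows <- suppressWarnings(window_recording(rec, L, gap_tolerance))
    gap_log <- attr(windows, "drop_log")
    if (nrow(gap_log) > 0) drops[[length(drops) + 1]] <- gap_log
    for (w in windows) {
      fv <- window_features(w$counts, cfg)
      if (anyNA(fv)) {
        drops[[length(drops) + 1]] <- data.frame(
          participant_id = rec$participant_id, start = w$start,
          reason = paste("undefined feature:",
                         paste(names(fv)[is.na(fv)], collapse = ", ")))
        next
      }
      rows[[length(rows) + 1]] <- c(fv,
                                    age = age_band_midpoint(md$age_band),
                                    gender = md$gender)
      ids <- c(ids, rec$participant_id)
      binary <- c(binary, bin)
      severity <- c(severity, sev)
    }
  }
  if (length(rows) == 0) {
    stop_actidep("all windows were dropped during feature extraction",
                 class = "actidep_feature_error")
  }
  X <- do.call(rbind, rows)
  colnames(X) <- c(activity_feature_names(), "age", "gender")
  drop_log <- if (length(drops) > 0) do.call(rbind, drops) else
    data.frame(participant_id = character(0),
               start = as.POSIXct(character(0)), reason = character(0))
  structure(list(X = X, binary = binary, severity = severity,
                 participant_id = ids, drop_log = drop_log),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix> %d windows x %d features (%d participants, %d dropped windows)\n",
              nrow(x$X), ncol(x$X), length(unique(x$participant_id)),
              nrow(x$drop_log)))
  invisible(x)
}

#' Fit a z-score scaler on training rows
#'
#' Stores the per-feature population mean and population standard deviation
#' of the training matrix, for the standardization `z = (x - mu) / sigma`.
#' Fit on training data only; apply to any matrix with the same columns.
#'
#' @param X Numeric training matrix.
#' @return A `scaler_params` object (`mu`, `sigma`, feature names).
#' @export
fit_scaler <- function(X) {
  mu <- colMeans(X)
  n <- nrow(X)
  sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))  # population sd
  structure(list(mu = mu, sigma = sigma, features = colnames(X)),
            class = "scaler_params")
}

#' Apply a fitted z-score scaler
#'
#' Transforms each column to `(x - mu) / sigma` with the stored training
#' parameters. A constant training column (`sigma = 0`) maps to all zeros
#' with a warning.
#'
#' @param params A `scaler_params` from [fit_scaler()].
#' @param X Numeric matrix with the same columns as the training matrix.
#' @return The standardized matrix.
#' @export
apply_scaler <- function(params, X) {
  if (!inherits(params, "scaler_params")) {
    stop_actidep("apply_scaler requires params from fit_scaler()",
                 class = "actidep_validation_error")
  }
  if (!identical(colnames(X), params$features)) {
    stop_actidep("feature columns do not match the fitted scaler",
                 class = "actidep_validation_error")
  }
  sigma <- params$sigma
  if (any(sigma == 0)) {
    warning(sprintf("constant feature(s) mapped to zero: %s",
                    paste(params$features[sigma == 0], collapse = ", ")))
    sigma[sigma == 0] <- Inf
  }
  sweep(sweep(X, 2, params$mu), 2, sigma, "/")
}
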