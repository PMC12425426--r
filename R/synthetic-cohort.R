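#' Configuration for a synthetic circadian cohort
#'
#' Defines the generative model for a Depresjon-format cohort with planted
#' group effects. Each participant's per-minute activity is
#' `max(0, round(A * template(t - phase) + eps_t))` where `template` is a
#' raised-cosine day profile that is zero outside the active span and `eps_t`
#' is Gaussian AR(1) noise. The condition group has a lower amplitude, a
#' delayed activity onset, and stronger autocorrelation — the rest-activity
#' signatures reported for depressed cohorts. MADRS scores are drawn from
#' group-specific truncated normals (controls in \[0, 6\], conditions in
#' \[7, 34\]), and moderate cases (MADRS >= 20) receive a further amplitude
#' and phase increment so the three-class task has learnable structure.
#'
#' @param n_condition,n_control Participants per group (defaults 23 and 32,
#'   mirroring the well-known clinical actigraphy cohort's imbalance).
#' @param days_per_participant Recording length in days (default 7).
#' @param amplitude_mean Named list, mean peak amplitude in counts per group.
#'   For the condition group this is the dominant, psychomotor-retarded
#'   subtype; see `agitated_fraction`.
#' @param amplitude_sd Named list, between-participant amplitude standard
#'   deviation per group.
#' @param agitated_fraction Probability that a condition participant belongs
#'   to an agitated subtype with elevated amplitude (`agitated_amplitude`).
#'   Depressed cohorts contain both psychomotor retardation and agitation;
#'   the resulting bimodal amplitude makes the group effect non-monotone in
#'   mean activity, so the classification task is learnable but not linearly
#'   separable.
#' @param agitated_amplitude Mean peak amplitude of the agitated subtype.
#' @param agitated_phase,agitated_span Mean onset phase and active span of
#'   the agitated subtype (phase-advanced, extended activity), deviating
#'   from controls in the direction opposite to the retarded subtype.
#' @param onset_phase Named list, mean activity onset in minutes-of-day per
#'   group.
#' @param phase_sd Between-participant onset jitter (minutes).
#' @param active_span Named list, mean active period length in minutes per
#'   group.
#' @param span_sd Between-participant active-span jitter (minutes).
#' @param ar_coefficient Named list, mean AR(1) coefficient of the noise per
#'   group (in \[0, 1)).
#' @param ar_sd Between-participant jitter of the AR(1) coefficient.
#' @param noise_scale Marginal standard deviation of the AR(1) noise (counts).
#' @param basal_mean Named list, mean basal (tonic) activity level in counts
#'   per group, added uniformly across the day; a group contrast here moves
#'   mean activity without touching dispersion or spectral features.
#' @param basal_sd Between-participant standard deviation of the basal level.
#' @param madrs_mean,madrs_sd Named lists, MADRS truncated-normal parameters
#'   per group.
#' @param moderate_amplitude_factor,moderate_phase_shift Extra amplitude
#'   multiplier and phase delay (minutes) applied to moderate-severity
#'   condition participants.
#' @param age_bands,age_weights Age-band labels and sampling weights.
#' @param seed Integer seed driving all randomness.
#' @return A `synthetic_cohort_config` list.
#' @export
synthetic_cohort_config <- function(n_condition = 23L,
                                    n_control = 32L,
                                    days_per_participant = 7L,
                                    amplitude_mean = list(condition = 260, control = 300),
                                    amplitude_sd = list(condition = 35, control = 35),
                                    agitated_fraction = 0.35,
                                    agitated_amplitude = 300,
                                    agitated_phase = 300,
                                    agitated_span = 1080,
                                    onset_phase = list(condition = 510, control = 420),
                                    phase_sd = 35,
                                    active_span = list(condition = 760, control = 960),
                                    span_sd = 50,
                                    ar_coefficient = list(condition = 0.5, control = 0.4),
                                    ar_sd = 0.1,
                                    noise_scale = 50,
                                    basal_mean = list(condition = 20, control = 20),
                                    basal_sd = 8,
                                    madrs_mean = list(condition = 18, control = 2),
                                    madrs_sd = list(condition = 6, control = 2),
                                    moderate_amplitude_factor = 0.85,
                                    moderate_phase_shift = 30,
                                    age_bands = c("20-24", "25-29", "30-34", "35-39",
                                                  "40-44", "45-49", "50-54", "55-59",
                                                  "60-64"),
                                    age_weights = c(1, 1.5, 2, 2, 2, 2, 1.5, 1, 0.5),
                                    seed = 1L) {
  stopifnot(n_condition >= 0, n_control >= 0, n_condition + n_control > 0,
            days_per_participant >= 1,
            all(unlist(ar_coefficient) >= 0), all(unlist(ar_coefficient) < 1),
            noise_scale > 0, length(age_bands) == length(age_weights))
  structure(as.list(environment()), class = "synthetic_cohort_config")
}

# Raised-cosine day template: 1 at the midpoint of the active span,
# 0 outside it. `t` is minute-of-day 0..1439, onset in minutes-of-day.
raised_cosine_template <- function(t, onset, span) {
  u <- (t - onset) %% 1440
  ifelse(u < span, 0.5 * (1 - cos(2 * pi * u / span)), 0)
}

# Stationary AR(1) noise with marginal sd `scale`.
ar1_noise <- function(n, rho, scale) {
  innov_sd <- scale * sqrt(1 - rho^2)
  e <- rnorm(n, sd = innov_sd)
  if (rho == 0) return(e)
  stats::filter(e, rho, method = "recursive",
                init = rnorm(1, sd = scale))
}

# Truncated-normal draw via inverse-CDF.
rtruncnorm1 <- function(mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(1, lo, hi), mean, sd)
}

#' Generate one synthetic participant
#'
#' Draws one participant's recording and metadata under a cohort config.
#' Randomness comes from the R session RNG; [generate_cohort()] seeds it
#' per participant so cohorts are reproducible.
#'
#' @param config A [synthetic_cohort_config()].
#' @param group `"condition"` or `"control"`.
#' @param participant_id Identifier used in the recording and scores row.
#' @param start_date First calendar day of the recording.
#' @return List with `recording` (an `activity_recording`) and `metadata`
#'   (a one-row data.frame in the scores-table layout).
#' @export
generate_participant <- function(config, group,
                                 participant_id = paste0(group, "_1"),
                                 start_date = as.Date("2020-01-01")) {
  group <- match.arg(group, c("condition", "control"))
  madrs <- round(rtruncnorm1(config$madrs_mean[[group]],
                             config$madrs_sd[[group]],
                             if (group == "control") 0 else 7,
                             if (group == "control") 6 else 34))
  amp_center <- config$amplitude_mean[[group]]
  phase_center <- config$onset_phase[[group]]
  span_center <- config$active_span[[group]]
  if (group == "condition" && runif(1) < config$agitated_fraction) {
    amp_center <- config$agitated_amplitude
    phase_center <- config$agitated_phase
    span_center <- config$agitated_span
  }
  amplitude <- max(0, rnorm(1, amp_center, config$amplitude_sd[[group]]))
  phase <- rnorm(1, phase_center, config$phase_sd)
  span <- min(1380, max(120, rnorm(1, span_center, config$span_sd)))
  if (group == "condition" && madrs >= 20) {
    amplitude <- amplitude * config$moderate_amplitude_factor
    phase <- phase + config$moderate_phase_shift
  }
  n <- config$days_per_participant * 1440L
  t_of_day <- rep(0:1439, config$days_per_participant)
  basal <- max(0, rnorm(1, config$basal_mean[[group]], config$basal_sd))
  signal <- basal + amplitude * raised_cosine_template(t_of_day, phase, span)
  rho <- min(0.95, max(0, rnorm(1, config$ar_coefficient[[group]],
                                config$ar_sd)))
  eps <- ar1_noise(n, rho, config$noise_scale)
  counts <- pmax(0, round(signal + as.numeric(eps)))
  ts <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
    60 * (seq_len(n) - 1)
  recording <- new_activity_recording(participant_id, group,
                                      data.frame(timestamp = ts,
                                                 count = as.integer(counts)))
  age_band <- sample(config$age_bands, 1, prob = config$age_weights)
  metadata <- data.frame(number = participant_id,
                         days = config$days_per_participant,
                         gender = sample(1:2, 1),
                         age_band = age_band,
                         afftype = if (group == "condition") 1 else NA_real_,
                         melanch = NA_real_, inpatient = NA_real_,
                         edu = NA_real_, marriage = NA_real_, work = NA_real_,
                         madrs1 = madrs, madrs2 = madrs,
                         stringsAsFactors = FALSE)
  list(recording = recording, metadata = metadata)
}

#' Generate a synthetic cohort
#'
#' Produces `n_condition + n_control` participants under the config's
#' generative model. Identical config and seed give byte-identical cohorts.
#' Optionally writes the cohort in the Depresjon CSV dialect (one activity
#' file per participant plus a `scores.csv`) so it round-trips through the
#' readers.
#'
#' @param config A [synthetic_cohort_config()].
#' @param dir Optional directory; when given, the cohort is written there.
#' @return A `cohort` (as from [merge_cohort()]) with an empty join log.
#' @export
generate_cohort <- function(config, dir = NULL) {
  n_total <- config$n_condition + config$n_control
  if (n_total == 0) {
    stop_actidep("cohort config has zero participants",
                 class = "actidep_validation_error")
  }
  groups <- c(rep("condition", config$n_condition),
              rep("control", config$n_control))
  ids <- c(sprintf("condition_%d", seq_len(config$n_condition)),
           sprintf("control_%d", seq_len(config$n_control)))
  participants <- vector("list", n_total)
  meta_rows <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    res <- with_seed(child_seed(config$seed, i), {
      generate_participant(config, groups[i], ids[i])
    })
    participants[[i]] <- res$recording
    meta_rows[[i]] <- res$metadata
  }
  metadata <- do.call(rbind, meta_rows)
  cohort <- merge_cohort(participants, metadata)
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Write a cohort in the Depresjon CSV dialect
#'
#' One `<participant_id>.csv` activity file per participant (columns
#' `timestamp,date,activity`) plus `scores.csv`.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (rec in cohort$participants) {
    df <- data.frame(
      timestamp = format(rec$epochs$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
      date = format(rec$epochs$timestamp, "%Y-%m-%d", tz = "UTC"),
      activity = rec$epochs$count)
    data.table::fwrite(df, file.path(dir, paste0(rec$participant_id, ".csv")))
  }
  scores <- cohort$metadata
  names(scores)[names(scores) == "age_band"] <- "age"
  data.table::fwrite(scores, file.path(dir, "scores.csv"))
  invisible(dir)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory containing per-participant activity CSVs and
#'   `scores.csv`.
#' @return A `cohort`.
#' @export
read_cohort <- function(dir) {
  scores <- read_scores_table(file.path(dir, "scores.csv"))
  files <- setdiff(list.files(dir, pattern = "\\.csv$"), "scores.csv")
  recordings <- lapply(file.path(dir, files), read_activity_file)
  merge_cohort(recordings, scores)
}
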