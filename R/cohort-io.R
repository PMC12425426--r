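#' Read a per-minute activity recording
#'
#' Parses one participant's actigraphy file in the Depresjon CSV dialect:
#' a header `timestamp,date,activity`, one row per minute, `timestamp` in
#' `YYYY-MM-DD HH:MM:SS`, `activity` a non-negative integer count. Rows are
#' returned sorted by timestamp regardless of file order.
#'
#' @param path Path to the activity CSV file.
#' @param participant_id Identifier for the participant; defaults to the file
#'   name without extension (the Depresjon convention, e.g. `condition_1`).
#' @param group Group membership: `"condition"`, `"control"` or `"unknown"`.
#'   When left `NULL` it is inferred from a `condition_`/`control_` prefix of
#'   the participant id.
#' @return An `activity_recording`: a list with `participant_id`, `group`,
#'   and `epochs` (a data.frame with POSIXct `timestamp` and integer `count`).
#' @export
read_activity_file <- function(path, participant_id = NULL, group = NULL) {
  if (!file.exists(path)) {
    stop_actidep("activity file not found: %s", path, class = "actidep_io_error")
  }
  dt <- data.table::fread(path, colClasses = "character", showProgress = FALSE)
  required <- c("timestamp", "date", "activity")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0) {
    stop_actidep("activity file %s is missing column(s): %s", path,
                 paste(missing, collapse = ", "),
                 class = "actidep_format_error")
  }
  ts <- as.POSIXct(dt$timestamp, format = "%Y-%m-%d %H:%M:%S", tz = "UTC")
  bad <- which(is.na(ts))
  if (length(bad) > 0) {
    stop_actidep("unparseable timestamp at data row %d of %s: '%s'",
                 bad[1], path, dt$timestamp[bad[1]],
                 class = "actidep_format_error")
  }
  counts <- suppressWarnings(as.numeric(dt$activity))
  if (anyNA(counts)) {
    stop_actidep("non-numeric activity at data row %d of %s",
                 which(is.na(counts))[1], path, class = "actidep_format_error")
  }
  if (any(counts < 0)) {
    stop_actidep("negative activity count at data row %d of %s",
                 which(counts < 0)[1], path, class = "actidep_validation_error")
  }
  ord <- order(ts)
  id <- participant_id %||% sub("\\.[^.]*$", "", basename(path))
  new_activity_recording(id,
                         group %||% infer_group(id),
                         data.frame(timestamp = ts[ord],
                                    count = as.integer(round(counts[ord]))))
}

infer_group <- function(id) {
  if (grepl("^condition", id)) "condition"
  else if (grepl("^control", id)) "control"
  else "unknown"
}

new_activity_recording <- function(participant_id, group, epochs) {
  stopifnot(nzchar(participant_id))
  group <- match.arg(group, c("condition", "control", "unknown"))
  structure(list(participant_id = participant_id, group = group,
                 epochs = epochs),
            class = "activity_recording")
}

#' @export
print.activity_recording <- function(x, ...) {
  cat(sprintf("<activity_recording> %s (%s): %d one-minute epochs\n",
              x$participant_id, x$group, nrow(x$epochs)))
  invisible(x)
}

#' Read the clinical scores table
#'
#' Parses the Depresjon `scores.csv` dialect: one row per participant with
#' columns `number, days, gender, age, afftype, melanch, inpatient, edu,
#' marriage, work, madrs1, madrs2`. Blank clinical cells are kept as `NA`
#' (absent), never coerced to zero. MADRS scores must lie in \[0, 60\] and
#' gender must be coded 1 (female) or 2 (male).
#'
#' @param path Path to the scores CSV file.
#' @return A data.frame of participant metadata, one row per participant,
#'   with `number` as character and the remaining columns numeric (`NA`
#'   where absent).
#' @export
read_scores_table <- function(path) {
  if (!file.exists(path)) {
    stop_actidep("scores file not found: %s", path, class = "actidep_io_error")
  }
  dt <- as.data.frame(data.table::fread(path, colClasses = "character",
                                        showProgress = FALSE))
  required <- c("number", "days", "gender", "age", "madrs1", "madrs2")
  missing <- setdiff(required, names(dt))
  if (length(missing) > 0) {
    stop_actidep("scores table is missing column(s): %s",
                 paste(missing, collapse = ", "),
                 class = "actidep_format_error")
  }
  if (nrow(dt) == 0) {
    out <- data.frame(number = character(0), days = numeric(0),
                      gender = numeric(0), age_band = character(0))
    return(out)
  }
  if (anyDuplicated(dt$number)) {
    stop_actidep("duplicate participant number: %s",
                 dt$number[duplicated(dt$number)][1],
                 class = "actidep_validation_error")
  }
  num_or_na <- function(x) suppressWarnings(as.numeric(ifelse(trimws(x) == "", NA, x)))
  optional <- c("afftype", "melanch", "inpatient", "edu", "marriage", "work")
  out <- data.frame(number = dt$number,
                    days = num_or_na(dt$days),
                    gender = num_or_na(dt$gender),
                    age_band = dt$age,
                    stringsAsFactors = FALSE)
  for (col in optional) {
    out[[col]] <- if (col %in% names(dt)) num_or_na(dt[[col]]) else NA_real_
  }
  out$madrs1 <- num_or_na(dt$madrs1)
  out$madrs2 <- num_or_na(dt$madrs2)
  for (col in c("madrs1", "madrs2")) {
    v <- out[[col]]
    if (any(!is.na(v) & (v < 0 | v > 60))) {
      stop_actidep("%s outside [0, 60] for participant %s", col,
                   out$number[which(!is.na(v) & (v < 0 | v > 60))[1]],
                   class = "actidep_validation_error")
    }
  }
  bad_gender <- !is.na(out$gender) & !(out$gender %in% c(1, 2))
  if (any(bad_gender)) {
    stop_actidep("gender must be coded 1 or 2 (got %s for participant %s)",
                 out$gender[which(bad_gender)[1]],
                 out$number[which(bad_gender)[1]],
                 class = "actidep_validation_error")
  }
  out
}

#' Merge recordings and metadata into a cohort
#'
#' Joins activity recordings to the scores table on participant id. Every
#' participant in the returned cohort has both a recording and a metadata
#' row; unmatched entries on either side are reported in the join log.
#'
#' @param recordings List of `activity_recording` objects.
#' @param metadata Data.frame from [read_scores_table()].
#' @return A `cohort`: list with `participants` (named list of recordings),
#'   `metadata` (matched rows) and `join_log` (data.frame of orphans).
#' @export
merge_cohort <- function(recordings, metadata) {
  ids <- vapply(recordings, function(r) r$participant_id, character(1))
  if (anyDuplicated(ids)) {
    stop_actidep("duplicate recording ids: %s", ids[duplicated(ids)][1],
                 class = "actidep_validation_error")
  }
  matched <- intersect(ids, metadata$number)
  if (length(matched) == 0) {
    stop_actidep("no participant ids in common between recordings and scores",
                 class = "actidep_join_error")
  }
  orphans <- rbind(
    if (length(setdiff(ids, matched)) > 0)
      data.frame(id = setdiff(ids, matched), side = "recording_only"),
    if (length(setdiff(metadata$number, matched)) > 0)
      data.frame(id = setdiff(metadata$number, matched), side = "metadata_only")
  )
  if (is.null(orphans)) orphans <- data.frame(id = character(0), side = character(0))
  keep <- recordings[match(matched, ids)]
  names(keep) <- matched
  structure(list(participants = keep,
                 metadata = metadata[match(matched, metadata$number), ,
                                     drop = FALSE],
                 join_log = orphans),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  groups <- table(vapply(x$participants, `[[`, character(1), "group"))
  cat(sprintf("<cohort> %d participants (%s); %d unmatched entries\n",
              length(x$participants),
              paste(sprintf("%s=%d", names(groups), groups), collapse = ", "),
              nrow(x$join_log)))
  invisible(x)
}

#' Binary depression label from group membership
#'
#' The condition (depressed) group is labeled 1 and the control group 0.
#'
#' @param group `"condition"` or `"control"` (vectorized).
#' @return Integer vector of 0/1 labels.
#' @export
assign_binary_label <- function(group) {
  if (any(!group %in% c("condition", "control"))) {
    stop_actidep("cannot assign a binary label to group '%s'",
                 group[!group %in% c("condition", "control")][1],
                 class = "actidep_validation_error")
  }
  as.integer(group == "condition")
}

#' Severity class from a MADRS score
#'
#' Maps a Montgomery-Asberg Depression Rating Scale total to the three-class
#' severity label used throughout the package: 0-6 normal (0), 7-19 mild (1),
#' 20-34 moderate (2). Scores of 35 or above fall in the severe range, which
#' the modeled cohorts do not contain; by default they raise an error, or can
#' be mapped to a fourth class with `allow_severe = TRUE`.
#'
#' @param madrs Integer MADRS total score(s) in \[0, 60\].
#' @param allow_severe Map scores >= 35 to class 3 instead of erroring.
#' @return Integer severity label(s) in `{0, 1, 2}` (or 3 when allowed).
#' @export
assign_severity_label <- function(madrs, allow_severe = FALSE) {
  if (any(is.na(madrs))) {
    stop_actidep("MADRS score is missing", class = "actidep_validation_error")
  }
  if (any(madrs < 0)) {
    stop_actidep("MADRS score must be non-negative (got %s)", min(madrs),
                 class = "actidep_validation_error")
  }
  if (any(madrs >= 35) && !allow_severe) {
    stop_actidep(paste0("MADRS %s is in the severe range (>= 35), outside the ",
                        "supported classes; set allow_severe = TRUE to map it ",
                        "to a fourth class"), max(madrs),
                 class = "actidep_validation_error")
  }
  findInterval(madrs, c(0, 7, 20, 35)) - 1L
}

#' Segment a recording into fixed-length windows
#'
#' Cuts a recording into consecutive non-overlapping windows of exactly `L`
#' one-minute epochs (default one day). A trailing partial window is dropped.
#' Timestamp gaps up to `gap_tolerance` minutes are forward-filled with zero
#' counts; a window spanning a longer gap is dropped and logged.
#'
#' @param recording An `activity_recording`.
#' @param L Window length in minutes (default 1440, one day).
#' @param gap_tolerance Maximum gap, in minutes, that is zero-filled
#'   (default 2).
#' @return A list of `activity_window` objects (fields `participant_id`,
#'   `start`, `counts`), with a `drop_log` attribute describing dropped
#'   windows. An empty list (with a warning) if the recording is shorter
#'   than `L`.
#' @export
window_recording <- function(recording, L = 1440L, gap_tolerance = 2L) {
  stopifnot(L >= 2)
  ep <- recording$epochs
  n <- nrow(ep)
  span_min <- if (n > 0) {
    round(as.numeric(difftime(ep$timestamp[n], ep$timestamp[1],
                              units = "mins"))) + 1
  } else 0
  if (span_min < L) {
    warning(sprintf("recording %s spans %d minutes, shorter than one window (L=%d)",
                    recording$participant_id, span_min, L))
    out <- list()
    attr(out, "drop_log") <- data.frame(participant_id = character(0),
                                        start = as.POSIXct(character(0)),
                                        reason = character(0))
    return(out)
  }
  # Regularize onto a 1-minute grid from the first timestamp; fill small gaps
  # with zeros, mark long gaps invalid.
  mins <- as.numeric(difftime(ep$timestamp, ep$timestamp[1], units = "mins"))
  mins <- round(mins)
  total <- mins[n] + 1
  grid <- rep(NA_real_, total)
  grid[mins + 1] <- ep$count
  gap_starts <- which(is.na(grid))
  filled <- grid
  valid <- rep(TRUE, total)
  if (length(gap_starts) > 0) {
    runs <- split(gap_starts, cumsum(c(1, diff(gap_starts) != 1)))
    for (run in runs) {
      if (length(run) <= gap_tolerance) {
        filled[run] <- 0
      } else {
        valid[run] <- FALSE
      }
    }
  }
  n_win <- floor(total / L)
  windows <- list()
  dropped <- list()
  for (w in seq_len(n_win)) {
    idx <- ((w - 1) * L + 1):(w * L)
    start_time <- ep$timestamp[1] + ((w - 1) * L) * 60
    if (all(valid[idx])) {
      windows[[length(windows) + 1]] <- structure(
        list(participant_id = recording$participant_id,
             start = start_time,
             counts = as.numeric(filled[idx])),
        class = "activity_window")
    } else {
      dropped[[length(dropped) + 1]] <- data.frame(
        participant_id = recording$participant_id,
        start = start_time,
        reason = sprintf("gap longer than %d min", gap_tolerance))
    }
  }
  attr(windows, "drop_log") <- if (length(dropped) > 0) {
    do.call(rbind, dropped)
  } else {
    data.frame(participant_id = character(0),
               start = as.POSIXct(character(0)), reason = character(0))
  }
  windows
}
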