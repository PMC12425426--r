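test_that("activity files parse, validate their header, and sort by time", {
  dir <- withr::local_tempdir()
  write_activity_fixture(dir, "condition_1", c(0, 5, 12))
  rec <- read_activity_file(file.path(dir, "condition_1.csv"))
  expect_s3_class(rec, "activity_recording")
  expect_identical(rec$epochs$count, c(0L, 5L, 12L))
  expect_identical(rec$group, "condition")

  # header typo is a format error naming the column
  bad <- file.path(dir, "bad.csv")
  writeLines(c("timestamp,date,activty", "2020-03-01 00:00:00,2020-03-01,3"),
             bad)
  expect_error(read_activity_file(bad), "activity", class = "actidep_format_error")

  # shuffled rows come back in timestamp order
  withr::with_seed(1, {
    write_activity_fixture(dir, "control_9", 1:60, shuffle = TRUE)
  })
  rec2 <- read_activity_file(file.path(dir, "control_9.csv"))
  expect_identical(rec2$epochs$count, 1:60)
  expect_true(!is.unsorted(rec2$epochs$timestamp))
})

test_that("unparseable timestamps and negative counts are rejected", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "x.csv")
  writeLines(c("timestamp,date,activity",
               "2020-03-01 00:00:00,2020-03-01,3",
               "not-a-time,2020-03-01,4"), p)
  expect_error(read_activity_file(p), "row 2", class = "actidep_format_error")
  writeLines(c("timestamp,date,activity",
               "2020-03-01 00:00:00,2020-03-01,-2"), p)
  expect_error(read_activity_file(p), "negative",
               class = "actidep_validation_error")
})

test_that("scores table keeps blanks absent and validates code domains", {
  dir <- withr::local_tempdir()
  write_scores_fixture(dir, data.frame(number = c("condition_1", "control_1"),
                                       days = c(13, 10), gender = c(1, 2),
                                       age = c("45-49", "30-34"),
                                       madrs1 = c("19", ""),
                                       madrs2 = c("17", "")))
  md <- read_scores_table(file.path(dir, "scores.csv"))
  expect_equal(md$madrs1, c(19, NA))
  expect_equal(md$age_band, c("45-49", "30-34"))

  write_scores_fixture(dir, data.frame(number = "p1", days = 5, gender = 3,
                                       age = "20-24", madrs1 = "4", madrs2 = "4"))
  expect_error(read_scores_table(file.path(dir, "scores.csv")),
               "gender", class = "actidep_validation_error")

  write_scores_fixture(dir, data.frame(number = "p1", days = 5, gender = 1,
                                       age = "20-24", madrs1 = "65", madrs2 = ""))
  expect_error(read_scores_table(file.path(dir, "scores.csv")),
               "madrs", class = "actidep_validation_error")

  write_scores_fixture(dir, data.frame(number = c("p1", "p1"), days = c(5, 5),
                                       gender = c(1, 1), age = c("20-24", "20-24"),
                                       madrs1 = c("4", "4"), madrs2 = c("", "")))
  expect_error(read_scores_table(file.path(dir, "scores.csv")),
               "duplicate", class = "actidep_validation_error")

  # header-only table gives an empty frame
  write_scores_fixture(dir, data.frame(number = character(0), days = character(0),
                                       gender = character(0), age = character(0),
                                       madrs1 = character(0), madrs2 = character(0)))
  expect_identical(nrow(read_scores_table(file.path(dir, "scores.csv"))), 0L)
})

test_that("merge joins on id, logs orphans, and refuses empty joins", {
  dir <- withr::local_tempdir()
  write_activity_fixture(dir, "condition_1", 1:10)
  write_activity_fixture(dir, "control_1", 1:10)
  recs <- lapply(file.path(dir, c("condition_1.csv", "control_1.csv")),
                 read_activity_file)
  md <- data.frame(number = c("condition_1", "control_1"), days = c(1, 1),
                   gender = c(1, 2), age_band = c("30-34", "30-34"),
                   madrs1 = c(18, NA), madrs2 = c(18, NA))
  coh <- merge_cohort(recs, md)
  expect_length(coh$participants, 2)
  expect_identical(nrow(coh$join_log), 0L)

  coh1 <- merge_cohort(recs, md[1, , drop = FALSE])
  expect_length(coh1$participants, 1)
  expect_identical(coh1$join_log$id, "control_1")

  md$number <- c("other_1", "other_2")
  expect_error(merge_cohort(recs, md), class = "actidep_join_error")
})

test_that("binary and severity label maps reproduce the clinical cutoffs", {
  expect_identical(assign_binary_label(c("condition", "control")), c(1L, 0L))
  expect_error(assign_binary_label("unknown"),
               class = "actidep_validation_error")

  # cutoffs: 0-6 normal, 7-19 mild, 20-34 moderate; boundary pairs exact
  expect_identical(assign_severity_label(c(0, 6, 7, 15, 19, 20, 25, 34)),
                   c(0L, 0L, 1L, 1L, 1L, 2L, 2L, 2L))
  expect_error(assign_severity_label(35), "severe",
               class = "actidep_validation_error")
  expect_identical(assign_severity_label(40, allow_severe = TRUE), 3L)
  expect_error(assign_severity_label(-1), class = "actidep_validation_error")

  # totality + surjectivity over the stated domain
  all_labels <- assign_severity_label(0:34)
  expect_setequal(unique(all_labels), 0:2)
})

test_that("windowing cuts exact non-overlapping windows and handles gaps", {
  mk_rec <- function(counts) {
    ts <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") +
      60 * (seq_along(counts) - 1)
    actidep:::new_activity_recording("p", "control",
                                     data.frame(timestamp = ts,
                                                count = as.integer(counts)))
  }
  expect_length(window_recording(mk_rec(rep(1, 2880))), 2)
  expect_length(window_recording(mk_rec(rep(1, 2000))), 1)
  expect_warning(w <- window_recording(mk_rec(rep(1, 1000))), "shorter")
  expect_length(w, 0)

  # window concatenation reconstructs a prefix of the original counts
  counts <- seq_len(3000) %% 17
  wins <- window_recording(mk_rec(counts))
  expect_equal(unlist(lapply(wins, `[[`, "counts")), counts[1:2880])

  # a 1-minute gap is zero-filled; a long gap drops the window with a log
  ts <- as.POSIXct("2020-03-01 00:00:00", tz = "UTC") + 60 * (0:1440)
  rec_gap <- actidep:::new_activity_recording(
    "p", "control",
    data.frame(timestamp = ts[-5], count = rep(3L, 1440)))
  w1 <- window_recording(rec_gap)
  expect_length(w1, 1)
  expect_identical(w1[[1]]$counts[5], 0)

  rec_long <- actidep:::new_activity_recording(
    "p", "control",
    data.frame(timestamp = ts[-(5:14)], count = rep(3L, 1431)))
  w2 <- window_recording(rec_long)
  expect_length(w2, 0)
  expect_identical(nrow(attr(w2, "drop_log")), 1L)
})
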