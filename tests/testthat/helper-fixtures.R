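# Fixture builders shared across test files. Everything is generated in code;
# no data files ship with the tests.

write_activity_fixture <- function(dir, id, counts,
                                   start = as.POSIXct("2020-03-01 00:00:00",
                                                      tz = "UTC"),
                                   shuffle = FALSE) {
  ts <- start + 60 * (seq_along(counts) - 1)
  df <- data.frame(timestamp = format(ts, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
                   date = format(ts, "%Y-%m-%d", tz = "UTC"),
                   activity = counts)
  if (shuffle) df <- df[sample(nrow(df)), ]
  path <- file.path(dir, paste0(id, ".csv"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

write_scores_fixture <- function(dir, rows) {
  header <- c("number", "days", "gender", "age", "afftype", "melanch",
              "inpatient", "edu", "marriage", "work", "madrs1", "madrs2")
  for (col in setdiff(header, names(rows))) {
    rows[[col]] <- rep("", nrow(rows))
  }
  path <- file.path(dir, "scores.csv")
  utils::write.csv(rows[header], path, row.names = FALSE, quote = FALSE)
  path
}

# One day with a square activity block: `level` counts on [on, off), else 0.
square_day <- function(on = 480, off = 1320, level = 100) {
  x <- numeric(1440)
  x[(on + 1):off] <- level
  x
}

# A small standardized two-class blob matrix for model tests.
blob_data <- function(n_per_class = 30, p = 4, sep = 4, seed = 42) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per_class * p), ncol = p),
               matrix(rnorm(n_per_class * p, mean = sep), ncol = p))
    colnames(X) <- paste0("f", seq_len(p))
    list(X = scale(X), y = rep(c(0L, 1L), each = n_per_class))
  })
}

# Tiny cohort used by IO/pipeline tests: fast to generate.
tiny_cohort_config <- function(seed = 7, days = 2, n_cond = 4, n_ctrl = 5) {
  synthetic_cohort_config(n_condition = n_cond, n_control = n_ctrl,
                          days_per_participant = days, seed = seed)
}
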