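test_that("well-formed records validate cleanly", {
  corpus <- load_corpus()
  for (record in c(corpus$trials, corpus$ungraded))
    expect_length(validate_record(record), 0L)
})

test_that("validation names the broken field and rule, and never throws", {
  rec <- make_pfs_record(lower = 0.7, upper = 0.5, hr = 0.6)
  v <- validate_record(rec)
  expect_length(v, 1L)
  expect_match(v, "ConfidenceInterval ordering")

  dup <- make_pfs_record()
  dup$endpoints <- c(dup$endpoints, dup$endpoints)
  v <- validate_record(dup)
  expect_true(any(grepl("duplicate endpoint", v)))

  mangled <- make_pfs_record()
  mangled$endpoints[[1]]$hr_lower <- "not a number"
  mangled$n <- -3
  mangled$setting <- "outer_space"
  expect_no_error(v <- validate_record(mangled))
  expect_true(any(grepl("^setting", v)))
  expect_true(any(grepl("^n:", v)))

  orr <- trial_record("o", "platinum_resistant", "phase3_rct", 100, "a", "b",
                      "ORR", endpoints = list(endpoint_summary("ORR")))
  expect_true(any(grepl("orr_pct: required", validate_record(orr))))

  bad_ev <- make_pfs_record(
    evidence = evidence_flags(qol_reported = FALSE, qol_subscale_improved = TRUE))
  expect_true(any(grepl("QoL improvement flagged but QoL not reported",
                        validate_record(bad_ev))))

  hr_no_ci <- make_pfs_record()
  hr_no_ci$endpoints[[1]]$hr_lower <- NA_real_
  hr_no_ci$endpoints[[1]]$hr_upper <- NA_real_
  expect_true(any(grepl("confidence interval absent", validate_record(hr_no_ci))))
})

test_that("the packaged graded tables load as 24 records over 19 trials", {
  path <- system.file("extdata", "table1_2_trials.csv", package = "mcbscore")
  records <- read_trials(path, format = "csv")
  expect_length(records, 24L)
  studies <- unique(vapply(records, function(r)
    if (!is.na(r$study_name)) r$study_name else r$trial_id, character(1)))
  expect_length(studies, 19L)
  # absent fields are NA, not zero: cediranib OS has an HR but no median
  icon6 <- records[[which(vapply(records, `[[`, character(1), "trial_id") == "icon6")]]
  os <- get_endpoint(icon6, "OS")
  expect_true(is.na(os$control_median))
  expect_identical(os$hazard_ratio, 0.86)
})

test_that("CSV and JSON round trips are the identity, absent kept distinct from zero", {
  corpus <- load_corpus()
  records <- c(corpus$trials, corpus$ungraded)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trials(records, path, format = fmt)
    back <- read_trials(path, format = fmt)
    expect_equal(back, records)
  }
})

test_that("round trip is the identity on randomly generated records", {
  records <- generate_trials(simulation_config(seed = 42L, n_trials = 60L))
  for (record in records) expect_length(validate_record(record), 0L)
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_trials(records, path, format = fmt)
    expect_equal(read_trials(path, format = fmt), records)
  }
})

test_that("empty inputs round trip: header-only CSV gives an empty list", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(list(), path, format = "csv")
  expect_length(read_trials(path, format = "csv"), 0L)
})

test_that("schema violations raise errors naming row, column and admissible values", {
  path <- withr::local_tempfile(fileext = ".csv")
  corpus <- load_corpus()
  write_trials(corpus$trials[1:2], path, format = "csv")
  df <- read.csv(path, colClasses = "character", check.names = FALSE)
  df$setting[2] <- "platinum_allergic"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_trials(path, format = "csv"),
               "row 2, column 'setting'.*platinum_sensitive")
  df$setting[2] <- "maintenance"
  df$pfs_significant[1] <- "maybe"
  write.csv(df, path, row.names = FALSE)
  expect_error(read_trials(path, format = "csv"), "pfs_significant.*confirmed")
  write.csv(df[, 1:5], path, row.names = FALSE)
  expect_error(read_trials(path, format = "csv"), "missing columns")
})

test_that("graded results round trip with rationale preserved verbatim", {
  corpus <- load_corpus()
  results <- grade_trials(c(corpus$trials, corpus$ungraded[1:3]))
  for (fmt in c("csv", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_graded(results, path, format = fmt)
    back <- read_graded(path, format = fmt)
    expect_equal(back, results)
  }
  # 24 graded rows for the graded tables
  path <- withr::local_tempfile(fileext = ".csv")
  write_graded(grade_trials(corpus$trials), path)
  expect_identical(nrow(read.csv(path)), 24L)
  # empty list gives a header-only file
  write_graded(list(), path)
  expect_length(read_graded(path), 0L)
})
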