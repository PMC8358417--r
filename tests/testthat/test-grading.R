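test_that("evaluation form follows the primary endpoint and OS maturity", {
  corpus <- load_corpus()
  byid <- stats::setNames(corpus$trials,
                          vapply(corpus$trials, `[[`, character(1), "trial_id"))
  expect_identical(select_form(byid$icon4), "2a")           # OS primary
  expect_identical(select_form(byid$adavosertib_gem), "2a") # PFS + confirmed OS
  expect_identical(select_form(byid$solo2), "2b")           # PFS, OS not significant
  expect_identical(select_form(byid$mito16b), "2b")         # PFS, OS unreported
  expect_identical(select_form(byid$calypso), "2c")         # non-inferiority
  expect_identical(select_form(byid$topotecan_orr), "3")    # ORR primary
})

test_that("form 2a threshold bands grade overall-survival benefit", {
  g2a <- function(control, gain, lower)
    grade_form_2a(os_summary(control, gain, round(lower * 1.1, 4), lower,
                             round(lower * 1.5, 4), "confirmed"))
  expect_identical(g2a(24, 5, 0.69), 4L)    # long-survival stratum, published anchor
  expect_identical(g2a(7.2, 4.2, 0.35), 4L) # short-survival stratum, published anchor
  expect_identical(g2a(10, 1.0, 0.30), 1L)  # gain below every band
  expect_identical(g2a(24, 5, 0.71), 1L)    # CI bound fails every admissible band
  expect_identical(g2a(10, 2.7, 0.60), 3L)
  expect_identical(g2a(10, 2.0, 0.68), 2L)
  expect_identical(g2a(20, 4.0, 0.70), 3L)
  expect_identical(g2a(20, 2.0, 0.75), 2L)
  expect_error(grade_form_2a(os_summary(24, NA, 0.8, 0.7, 0.95)), "gain")
  expect_error(grade_form_2a(os_summary(NA, 5, 0.8, 0.7, 0.95)), "control_median")
})

test_that("form 2b threshold bands grade PFS-only benefit, capped at 3", {
  g2b <- function(control, gain, lower)
    grade_form_2b(endpoint_summary("PFS", control_median = control, gain = gain,
                                   hazard_ratio = round(lower * 1.1, 4),
                                   hr_lower = lower,
                                   hr_upper = round(lower * 1.5, 4),
                                   significant = "confirmed"))
  expect_identical(g2b(8.4, 4.0, 0.39), 3L)  # published anchor rows
  expect_identical(g2b(11.7, 1.7, 0.68), 1L)
  expect_identical(g2b(8.7, 2.3, 0.44), 2L)
  expect_identical(g2b(3.4, 3.3, 0.38), 3L)
  expect_identical(g2b(5.8, 1.5, 0.65), 3L)  # inclusive bounds: both exactly on the band
  expect_identical(g2b(5.8, 1.4, 0.65), 2L)
  expect_identical(g2b(6.0, 1.5, 0.65), 3L)  # control exactly on the stratum bound: low stratum
  expect_identical(g2b(6.1, 1.5, 0.65), 2L)
  expect_true(all(vapply(seq(0.5, 20, by = 0.5), function(g)
    g2b(4, g, 0.2), integer(1)) <= 3L))
  expect_error(g2b(NA, 2, 0.5), "control_median")
})

test_that("form 2c grades non-inferiority comparisons on QoL/toxicity evidence", {
  base <- trial_record("ni", "platinum_sensitive", "phase3_rct", 500,
                       "new regimen", "Carboplatin plus paclitaxel",
                       "NONINFERIORITY",
                       endpoints = list(endpoint_summary(
                         "PFS", control_median = 9, gain = 1,
                         hazard_ratio = 0.9, hr_lower = 0.8, hr_upper = 1.05,
                         significant = "confirmed")))
  with_flags <- function(...) {
    r <- base
    r$evidence <- evidence_flags(...)
    r
  }
  expect_identical(grade_form_2c(with_flags(qol_reported = TRUE,
                                            qol_global_improved = TRUE)), 4L)
  expect_identical(grade_form_2c(with_flags(toxicity_reduced = TRUE)), 4L)
  expect_identical(grade_form_2c(with_flags(qol_reported = TRUE,
                                            qol_subscale_improved = TRUE,
                                            early_discontinuation_reduced = TRUE)),
                   3L)  # published anchor (global QoL equal, better subscales)
  expect_identical(grade_form_2c(with_flags()), 2L)
  no_ni <- with_flags()
  no_ni$endpoints[[1]]$significant <- "not_significant"
  expect_error(grade_form_2c(no_ni), "non-inferior efficacy or QoL/toxicity")
})

test_that("form 3 grades objective response rate in three bands", {
  g3 <- function(orr) grade_form_3(endpoint_summary("ORR", orr_pct = orr))
  expect_identical(g3(21), 2L)    # published anchor
  expect_identical(g3(19.9), 1L)
  expect_identical(g3(60), 3L)
  expect_identical(g3(20), 2L)
  expect_error(grade_form_3(endpoint_summary("OS")), "orr_pct")
})

test_that("QoL/toxicity adjustment follows the upgrade/downgrade policy", {
  # +1 for a prespecified subscale improvement on form 2b
  up <- make_pfs_record(evidence = evidence_flags(qol_reported = TRUE,
                                                  qol_subscale_improved = TRUE))
  expect_identical(compute_adjustment("2b", 3L, up)$adjustment, 1L)
  # -1 for reported, non-significant OS with reported QoL showing no improvement
  down <- make_pfs_record(os = os_summary(30, 0.7, 0.95, 0.77, 1.18,
                                          "not_significant"),
                          evidence = evidence_flags(qol_reported = TRUE))
  expect_identical(compute_adjustment("2b", 3L, down)$adjustment, -1L)
  # no downgrade when OS is immature/unreported
  unrep <- make_pfs_record(os = os_summary(significant = "exploratory_or_unreported"))
  expect_identical(compute_adjustment("2b", 3L, unrep)$adjustment, 0L)
  expect_identical(compute_adjustment("2b", 3L, make_pfs_record())$adjustment, 0L)
  # increased toxicity without QoL benefit downgrades
  tox <- make_pfs_record(evidence = evidence_flags(toxicity_increased = TRUE))
  expect_identical(compute_adjustment("2b", 3L, tox)$adjustment, -1L)
  # conflicting evidence resolves to 0, with a rationale line
  tie <- make_pfs_record(os = os_summary(30, 0.7, 0.95, 0.77, 1.18,
                                         "not_significant"),
                         evidence = evidence_flags(qol_reported = TRUE,
                                                   qol_subscale_improved = TRUE,
                                                   toxicity_increased = TRUE))
  adj <- compute_adjustment("2b", 3L, tie)
  expect_identical(adj$adjustment, 0L)
  expect_match(adj$rationale, "conflicting")
  # form 2a only upgrades, towards grade 5
  up2a <- make_pfs_record(evidence = evidence_flags(qol_reported = TRUE,
                                                    qol_global_improved = TRUE))
  expect_identical(compute_adjustment("2a", 4L, up2a)$adjustment, 1L)
  expect_identical(compute_adjustment("2a", 4L, down)$adjustment, 0L)
  # forms 2c and 3 are never adjusted
  expect_identical(compute_adjustment("2c", 3L, up)$adjustment, 0L)
  expect_identical(compute_adjustment("3", 2L, up)$adjustment, 0L)
})

test_that("grade 5 is reachable on form 2a with QoL benefit on top of an OS gain", {
  rec <- trial_record("os5", "platinum_resistant", "phase3_rct", 400,
                      "experimental", "Paclitaxel", "OS",
                      endpoints = list(os_summary(8, 4, 0.5, 0.4, 0.65,
                                                  "confirmed")),
                      evidence = evidence_flags(qol_reported = TRUE,
                                                qol_global_improved = TRUE))
  res <- grade_trial(rec)
  expect_identical(res$preliminary, 4L)
  expect_identical(res$final, 5L)
})

test_that("grade_trial composes gate, form, grade and adjustment with a rationale", {
  corpus <- load_corpus()
  byid <- stats::setNames(c(corpus$trials, corpus$ungraded),
                          vapply(c(corpus$trials, corpus$ungraded),
                                 `[[`, character(1), "trial_id"))
  solo2 <- grade_trial(byid$solo2)
  expect_identical(solo2$form, "2b")
  expect_identical(solo2$preliminary, 3L)
  expect_identical(solo2$adjustment, -1L)
  expect_identical(solo2$final, 2L)
  mito16b <- grade_trial(byid$mito16b)
  expect_identical(mito16b$final, 3L)
  expect_identical(mito16b$adjustment, 0L)
  gog <- grade_trial(byid$gog0213)
  expect_identical(gog$form, "not_graded")
  expect_true(is.na(gog$final))
  expect_match(gog$rationale, "not significant", all = FALSE)
  # rationale is non-empty whenever a grade is produced, and traces the form
  for (record in corpus$trials) {
    res <- grade_trial(record)
    expect_gt(length(res$rationale), 0)
    expect_match(res$rationale[1], "form")
  }
})

test_that("preliminary grade is monotone where the scale is monotone", {
  # The scale is monotone under a strengthening hazard ratio everywhere, but
  # monotone in gain only where the strictest HR criterion (CI lower <= 0.65)
  # is met: at intermediate CI-lower values only the grade-2 gain window is
  # reachable, so a larger gain can legitimately leave the scored bands.
  grid <- generate_grade_grid()
  expect_length(grid, 2112L)
  res <- grade_trials(grid)
  prelim <- vapply(res, `[[`, integer(1), "preliminary")
  key <- data.frame(
    kind = vapply(grid, `[[`, character(1), "primary_endpoint"),
    control = vapply(grid, function(r) r$endpoints[[1]]$control_median, numeric(1)),
    lower = vapply(grid, function(r) r$endpoints[[1]]$hr_lower, numeric(1)),
    gain = vapply(grid, function(r) r$endpoints[[1]]$gain, numeric(1)),
    prelim = prelim)
  for (cell in split(key, list(key$kind, key$control))) {
    # decreasing CI lower bound at fixed gain never lowers the grade
    for (sub in split(cell, cell$gain)) {
      ord <- sub[order(sub$lower), ]
      expect_true(all(diff(ord$prelim) <= 0))
    }
    # increasing gain never lowers the grade while CI lower <= 0.65
    for (sub in split(cell[cell$lower <= 0.65, ], cell$lower[cell$lower <= 0.65])) {
      ord <- sub[order(sub$gain), ]
      expect_true(all(diff(ord$prelim) >= 0))
    }
  }
  # the non-monotone pocket is real and intended: looser-HR band only
  g2a <- function(control, gain, lower)
    grade_form_2a(os_summary(control, gain, round(lower * 1.02, 4), lower,
                             round(lower * 1.5, 4), "confirmed"))
  expect_identical(g2a(10, 2.0, 0.68), 2L)
  expect_identical(g2a(10, 3.5, 0.68), 1L)
})

test_that("engine agrees with the flat-conditions oracle on the grid and synthetic records", {
  grid <- generate_grade_grid()
  for (record in grid) {
    res <- grade_trial(record)
    expect_identical(res$preliminary, oracle_preliminary(record))
  }
  records <- generate_trials(simulation_config(seed = 7L, n_trials = 10000L))
  results <- grade_trials(records)
  checked <- 0L
  for (i in seq_along(records)) {
    res <- results[[i]]
    if (identical(res$form, "not_graded")) next
    exp_prelim <- oracle_preliminary(records[[i]])
    if (is.na(exp_prelim)) next
    expect_identical(res$preliminary, exp_prelim)
    expect_identical(res$adjustment, oracle_adjustment(res$form, records[[i]]))
    checked <- checked + 1L
  }
  expect_gt(checked, 2000L)  # the batch must actually exercise the engine
})

test_that("grades stay in bounds and adjustments within one point", {
  records <- c(generate_trials(simulation_config(seed = 11L, n_trials = 500L)),
               load_corpus()$trials)
  for (res in grade_trials(records)) {
    if (identical(res$form, "not_graded")) {
      expect_true(is.na(res$final))
      next
    }
    expect_true(res$preliminary >= 1L && res$preliminary <= 4L)
    expect_true(res$final >= 1L && res$final <= 5L)
    expect_lte(abs(res$final - res$preliminary), 1L)
    expect_true(res$adjustment %in% c(-1L, 0L, 1L))
  }
})
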