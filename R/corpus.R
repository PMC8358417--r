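# Curated corpus: the published phase III / phase II graded rows and the
# ungraded no-significant-benefit rows, transcribed into the record schema,
# with the printed MCBS scores as the normative expectation.

.corpus_file <- function(name) {
  path <- system.file("extdata", name, package = "mcbscore")
  if (!nzchar(path) || !file.exists(path))
    stop("packaged corpus file missing: ", name, call. = FALSE)
  path
}

#' Load the curated trial corpus
#'
#' Returns the transcribed published tables: the graded phase III rows (14
#' trials, with the niraparib cohorts and the rucaparib and olaparib-capsule
#' subgroup rows expanded to one record each), the graded phase II rows (5
#' trials), and the 27 ungraded trials without a statistically significant
#' benefit. Each graded record is paired with its printed MCBS score, form
#' and adjustment in `$expected`, which also carries a provenance note per
#' row. File integrity (row counts and schema) is checked on load.
#'
#' @return A list with elements `trials` (list of [trial_record()]s for the
#'   graded tables), `expected` (data.frame: `trial_id`, `form`,
#'   `preliminary`, `adjustment`, `final`, `provenance`), `ungraded` (list
#'   of [trial_record()]s), and `metadata` (see [corpus_metadata()]).
#' @export
load_corpus <- function() {
  trials <- read_trials(.corpus_file("table1_2_trials.csv"), format = "csv")
  ungraded <- read_trials(.corpus_file("table3_trials.csv"), format = "csv")
  expected <- utils::read.csv(.corpus_file("expected_grades.csv"),
                              colClasses = "character")
  expected$preliminary <- as.integer(expected$preliminary)
  expected$adjustment <- as.integer(expected$adjustment)
  expected$final <- as.integer(expected$final)
  need <- c("trial_id", "form", "preliminary", "adjustment", "final", "provenance")
  if (!all(need %in% names(expected)))
    stop("corpus integrity check failed: expected_grades.csv schema", call. = FALSE)
  if (length(trials) != 24L || length(ungraded) != 27L ||
      nrow(expected) != length(trials))
    stop("corpus integrity check failed: row counts do not match the curated tables",
         call. = FALSE)
  ids <- vapply(trials, `[[`, character(1), "trial_id")
  if (!setequal(ids, expected$trial_id))
    stop("corpus integrity check failed: expected grades do not cover the trial rows",
         call. = FALSE)
  list(trials = trials, expected = expected, ungraded = ungraded,
       metadata = corpus_metadata())
}

#' Literature-search bookkeeping of the source review
#'
#' These counts describe the human screening process behind the corpus
#' (papers retrieved, randomised reports of sufficient quality, inter-
#' observer agreement). They are not computable from the shipped records and
#' are carried as static metadata only.
#'
#' @return A list with `papers_screened`, `randomised_reports`,
#'   `observer_agreement_pct`, `graded_trials`, `ungraded_trials`.
#' @export
corpus_metadata <- function() {
  list(papers_screened = 1127L,
       randomised_reports = 61L,
       observer_agreement_pct = 98,
       graded_trials = 19L,
       ungraded_trials = 27L)
}

#' Check the engine against the published scores
#'
#' Grades every corpus record and compares form, preliminary grade,
#' adjustment and final grade against the printed values; also checks that
#' every ungraded row comes out `not_graded`. Mismatches are reported, not
#' thrown.
#'
#' @param corpus A corpus as returned by [load_corpus()].
#' @return data.frame of mismatches with columns `trial_id`, `field`,
#'   `expected`, `actual`; zero rows when the engine reproduces the tables.
#' @export
run_corpus_check <- function(corpus = load_corpus()) {
  mismatches <- list()
  note <- function(id, field, exp, act) {
    mismatches[[length(mismatches) + 1L]] <<- data.frame(
      trial_id = id, field = field, expected = as.character(exp),
      actual = as.character(act), stringsAsFactors = FALSE)
  }
  exp <- corpus$expected
  for (record in corpus$trials) {
    row <- exp[exp$trial_id == record$trial_id, , drop = FALSE]
    res <- grade_trial(record)
    if (!identical(res$form, row$form))
      note(record$trial_id, "form", row$form, res$form)
    if (!identical(res$preliminary, row$preliminary))
      note(record$trial_id, "preliminary", row$preliminary, res$preliminary)
    if (!identical(res$adjustment, row$adjustment))
      note(record$trial_id, "adjustment", row$adjustment, res$adjustment)
    if (!identical(res$final, row$final))
      note(record$trial_id, "final", row$final, res$final)
  }
  for (record in corpus$ungraded) {
    res <- grade_trial(record)
    if (!identical(res$form, "not_graded"))
      note(record$trial_id, "form", "not_graded", res$form)
  }
  if (length(mismatches) == 0L)
    return(data.frame(trial_id = character(), field = character(),
                      expected = character(), actual = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, mismatches)
}

#' Patients randomised per treatment setting
#'
#' Sums the printed per-row patient numbers over trials (counting each
#' multi-row trial once through its parent/cohort rows) across both the
#' graded and ungraded corpus tables.
#'
#' @param corpus A corpus as returned by [load_corpus()].
#' @return Named numeric vector over the three settings.
#' @export
setting_patient_totals <- function(corpus = load_corpus()) {
  records <- c(corpus$trials, corpus$ungraded)
  totals <- stats::setNames(numeric(length(.settings)), .settings)
  for (record in records) {
    if (!is.na(record$subgroup_of)) next  # subgroup n is contained in the parent row
    totals[[record$setting]] <- totals[[record$setting]] + record$n
  }
  totals
}
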