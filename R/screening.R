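# Eligibility pipeline: which records may be graded at all.

#' Screening category of a trial record
#'
#' Category I: large phase III randomised controlled trials in the target
#' population with an adequate comparator and a primary endpoint of OS or
#' PFS. Category III: designs outside the scorable scope (single-arm,
#' retrospective, reviews — `design = "other"`). Category II: everything
#' else that could potentially be scored (randomised phase II trials,
#' non-inferiority or response-rate primary endpoints).
#'
#' @param record A validated [trial_record()].
#' @return `"I"`, `"II"` or `"III"`.
#' @export
categorise <- function(record) {
  if (identical(record$design, "other")) return("III")
  if (identical(record$design, "phase3_rct") &&
      isTRUE(record$comparator_adequate) &&
      record$primary_endpoint %in% c("OS", "PFS")) return("I")
  "II"
}

#' Setting-specific comparator adequacy rule
#'
#' In the platinum-sensitive setting the preferred comparator is
#' platinum-based chemotherapy (non-platinum regimens proved inferior); in
#' the platinum-resistant setting any guideline-listed option is adequate;
#' for maintenance trials the comparator is placebo / no further treatment
#' after response to platinum, with a platinum-based chemotherapy backbone
#' accepted for concomitant-start designs. The comparator class is a curated
#' annotation looked up by normalized arm label; this function only applies
#' the setting rule to it.
#'
#' @param record A [trial_record()].
#' @param classes Annotation table with columns `label` (normalized arm
#'   label) and `class` (one of `platinum_based`, `guideline_listed`,
#'   `placebo_or_no_treatment`, `other`); defaults to the curated table
#'   shipped with the package.
#' @return `TRUE` or `FALSE`.
#' @export
comparator_is_adequate <- function(record, classes = comparator_classes()) {
  label <- normalize_arm_label(record$comparator_label)
  hit <- match(label, classes$label)
  if (is.na(hit))
    stop("comparator annotation missing for label '", label,
         "': curation required", call. = FALSE)
  cls <- classes$class[hit]
  switch(record$setting,
    platinum_sensitive = identical(cls, "platinum_based"),
    platinum_resistant = cls %in% c("guideline_listed", "platinum_based"),
    maintenance = cls %in% c("placebo_or_no_treatment", "platinum_based"),
    FALSE)
}

#' Curated comparator annotation table
#'
#' @return data.frame with columns `label`, `class`.
#' @export
comparator_classes <- function() {
  path <- system.file("extdata", "comparator_classes.csv", package = "mcbscore")
  utils::read.csv(path, colClasses = "character")
}

#' Gradeability gate
#'
#' A record may be graded iff it is category I or II, was not terminated
#' early, is not superseded by a higher-quality trial, and its primary
#' endpoint (or a confirmed secondary OS analysis) shows a statistically
#' significant benefit of the study arm under a prespecified,
#' multiplicity-controlled test. Exploratory or unreported significance
#' never passes. Failing records carry at least one reason.
#'
#' @param record A validated [trial_record()].
#' @return A list of class `screening_decision` with fields `trial_id`,
#'   `category`, `included`, `reasons`.
#' @export
gradeability_gate <- function(record) {
  reasons <- character()
  category <- categorise(record)
  if (identical(category, "III"))
    reasons <- c(reasons, "category III: design not eligible for scoring")
  if (isTRUE(record$terminated_early))
    reasons <- c(reasons, "trial terminated prematurely")
  if (isTRUE(record$superseded))
    reasons <- c(reasons, "superseded by a higher-quality trial of the same treatment")
  prim <- primary_summary(record)
  if (is.null(prim)) {
    reasons <- c(reasons, "no summary available for the primary endpoint")
  } else if (!identical(prim$significant, "confirmed")) {
    os <- get_endpoint(record, "OS")
    os_confirmed <- !is.null(os) && identical(os$significant, "confirmed")
    if (!os_confirmed)
      reasons <- c(reasons,
                   if (identical(prim$significant, "not_significant"))
                     "primary result not significant"
                   else "primary result exploratory or unreported")
  }
  structure(list(trial_id = record$trial_id, category = category,
                 included = length(reasons) == 0L, reasons = reasons),
            class = "screening_decision")
}

#' @export
print.screening_decision <- function(x, ...) {
  cat(sprintf("<screening_decision %s> category %s, %s\n", x$trial_id,
              x$category, if (x$included) "included" else "excluded"))
  for (r in x$reasons) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

#' Admissibility of a subgroup set
#'
#' The scale allows grading of at most three prespecified subgroups per
#' trial (with multiplicity control); larger or post-hoc subgroup sets are
#' reported but not graded.
#'
#' @param parent The parent [trial_record()].
#' @param subgroups List of subgroup [trial_record()]s, each with
#'   `subgroup_of` equal to `parent$trial_id`.
#' @return `TRUE` or `FALSE`.
#' @export
subgroup_admissible <- function(parent, subgroups) {
  for (sg in subgroups) {
    if (is.na(sg$subgroup_of) || !identical(sg$subgroup_of, parent$trial_id))
      stop("subgroup record '", sg$trial_id, "' does not reference parent '",
           parent$trial_id, "'", call. = FALSE)
  }
  length(subgroups) <= 3L &&
    all(vapply(subgroups, function(sg) isTRUE(sg$subgroup_prespecified), logical(1)))
}

#' Screen a list of records
#'
#' @param records List of [trial_record()]s.
#' @return data.frame with columns `trial_id`, `category`, `included`,
#'   `reasons` (semicolon-joined).
#' @export
screen_trials <- function(records) {
  decisions <- lapply(records, gradeability_gate)
  data.frame(
    trial_id = vapply(decisions, `[[`, character(1), "trial_id"),
    category = vapply(decisions, `[[`, character(1), "category"),
    included = vapply(decisions, `[[`, logical(1), "included"),
    reasons = vapply(decisions, function(d) paste(d$reasons, collapse = "; "),
                     character(1)),
    stringsAsFactors = FALSE)
}
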