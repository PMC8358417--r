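# Domain model: trial summary records and graded results.
#
# All "absent" scalar values are NA; NA is semantically distinct from 0
# (e.g. an unreported overall-survival gain must never be read as a 0-month
# gain, because the downgrade rule keys on "unreported").

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0L) b else a

.endpoint_kinds <- c("OS", "PFS", "ORR", "QOL_TOX")
.primary_endpoints <- c(.endpoint_kinds, "NONINFERIORITY")
.settings <- c("platinum_sensitive", "maintenance", "platinum_resistant")
.designs <- c("phase3_rct", "phase2_rct", "other")
.significance <- c("confirmed", "not_significant", "exploratory_or_unreported")
.forms <- c("2a", "2b", "2c", "3", "not_graded")
.flag_names <- c("qol_reported", "qol_global_improved", "qol_subscale_improved",
                 "toxicity_reduced", "toxicity_increased",
                 "early_discontinuation_reduced")

.as_num <- function(x) {
  if (is.null(x) || length(x) == 0L) return(NA_real_)
  suppressWarnings(as.numeric(x[[1L]]))
}

.as_flag <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[[1L]])) return(FALSE)
  isTRUE(as.logical(x[[1L]]))
}

.as_chr <- function(x) {
  if (is.null(x) || length(x) == 0L || is.na(x[[1L]]) || !nzchar(as.character(x[[1L]])))
    return(NA_character_)
  as.character(x[[1L]])
}

#' Summary of one trial endpoint
#'
#' Bundles the published summary statistics for a single endpoint of a
#' randomised trial: the control-arm median (months), the absolute median
#' gain of the experimental arm (months, may be negative), the hazard ratio
#' with its 95% confidence interval, the objective response rate (percent),
#' and the curated significance status of the comparison.
#'
#' `significant` is a tri-state: `"confirmed"` means a prespecified,
#' multiplicity-controlled test met its significance criterion;
#' `"not_significant"` means the comparison was reported and failed it;
#' `"exploratory_or_unreported"` means no confirmatory result is available
#' (immature, unpublished, or an uncorrected exploratory analysis).
#'
#' @param endpoint One of `"OS"`, `"PFS"`, `"ORR"`, `"QOL_TOX"`.
#' @param control_median Control-arm median in months, or `NA`.
#' @param gain Absolute median gain in months (experimental minus control), or `NA`.
#' @param hazard_ratio Hazard ratio point estimate, or `NA`.
#' @param hr_lower,hr_upper 95% confidence bounds for the hazard ratio, or `NA`.
#' @param orr_pct Objective response rate, percent in `[0, 100]`, or `NA`.
#' @param significant Significance status; see Details.
#' @return An object of class `endpoint_summary`.
#' @export
#' @examples
#' endpoint_summary("OS", control_median = 24, gain = 5,
#'                  hazard_ratio = 0.82, hr_lower = 0.69, hr_upper = 0.97,
#'                  significant = "confirmed")
endpoint_summary <- function(endpoint, control_median = NA, gain = NA,
                             hazard_ratio = NA, hr_lower = NA, hr_upper = NA,
                             orr_pct = NA,
                             significant = "exploratory_or_unreported") {
  structure(list(
    endpoint = as.character(endpoint[[1L]]),
    control_median = .as_num(control_median),
    gain = .as_num(gain),
    hazard_ratio = .as_num(hazard_ratio),
    hr_lower = .as_num(hr_lower),
    hr_upper = .as_num(hr_upper),
    orr_pct = .as_num(orr_pct),
    significant = as.character(significant[[1L]])
  ), class = "endpoint_summary")
}

#' Quality-of-life and toxicity evidence flags
#'
#' Curated booleans driving the one-grade adjustment of a preliminary MCBS
#' grade. Improvement flags are only set when the supporting analysis was
#' prespecified; `qol_reported` records whether any quality-of-life analysis
#' was published at all (the downgrade for a PFS-only benefit applies only
#' when QoL was reported and showed no improvement).
#'
#' @param qol_reported QoL results published for the trial.
#' @param qol_global_improved Prespecified global QoL improvement.
#' @param qol_subscale_improved Prespecified QoL symptom-subscale improvement.
#' @param toxicity_reduced Reduction in grade 3-4 toxicity affecting daily well-being.
#' @param toxicity_increased Clinically relevant increase in toxicity.
#' @param early_discontinuation_reduced Less early treatment discontinuation.
#' @return An object of class `evidence_flags`.
#' @export
evidence_flags <- function(qol_reported = FALSE, qol_global_improved = FALSE,
                           qol_subscale_improved = FALSE, toxicity_reduced = FALSE,
                           toxicity_increased = FALSE,
                           early_discontinuation_reduced = FALSE) {
  structure(list(
    qol_reported = .as_flag(qol_reported),
    qol_global_improved = .as_flag(qol_global_improved),
    qol_subscale_improved = .as_flag(qol_subscale_improved),
    toxicity_reduced = .as_flag(toxicity_reduced),
    toxicity_increased = .as_flag(toxicity_increased),
    early_discontinuation_reduced = .as_flag(early_discontinuation_reduced)
  ), class = "evidence_flags")
}

#' One trial (or prespecified subgroup) record
#'
#' A curated summary of one randomised-trial comparison in recurrent ovarian
#' cancer, or of one prespecified subgroup of such a trial (one record per
#' graded table row; subgroup rows set `subgroup_of` to the parent record's
#' `trial_id`).
#'
#' @param trial_id Unique identifier for the record.
#' @param setting `"platinum_sensitive"`, `"maintenance"` or `"platinum_resistant"`.
#' @param design `"phase3_rct"`, `"phase2_rct"` or `"other"`.
#' @param n Number of randomised patients covered by the row.
#' @param experimental_label,comparator_label Free-text arm descriptions.
#' @param primary_endpoint `"OS"`, `"PFS"`, `"ORR"`, `"QOL_TOX"` or
#'   `"NONINFERIORITY"` (a non-inferiority design graded on QoL/toxicity; its
#'   primary analysis is carried by the PFS endpoint summary).
#' @param endpoints List of [endpoint_summary()] objects, at most one per kind.
#' @param evidence An [evidence_flags()] object.
#' @param study_name Published study name, or `NA`.
#' @param subgroup_of `trial_id` of the parent record, or `NA`.
#' @param subgroup_prespecified Was the subgroup analysis prespecified?
#' @param comparator_adequate Curated flag: comparator meets the
#'   setting-specific adequacy rule (see [comparator_is_adequate()]).
#' @param terminated_early Curated flag: trial stopped prematurely.
#' @param superseded Curated flag: a higher-quality trial of the same
#'   treatment exists.
#' @return An object of class `trial_record`.
#' @export
trial_record <- function(trial_id, setting, design, n,
                         experimental_label, comparator_label, primary_endpoint,
                         endpoints = list(), evidence = evidence_flags(),
                         study_name = NA, subgroup_of = NA,
                         subgroup_prespecified = FALSE, comparator_adequate = TRUE,
                         terminated_early = FALSE, superseded = FALSE) {
  structure(list(
    trial_id = as.character(trial_id[[1L]]),
    study_name = .as_chr(study_name),
    setting = as.character(setting[[1L]]),
    design = as.character(design[[1L]]),
    n = .as_num(n),
    experimental_label = as.character(experimental_label[[1L]]),
    comparator_label = as.character(comparator_label[[1L]]),
    primary_endpoint = as.character(primary_endpoint[[1L]]),
    endpoints = endpoints,
    evidence = evidence,
    subgroup_of = .as_chr(subgroup_of),
    subgroup_prespecified = .as_flag(subgroup_prespecified),
    comparator_adequate = .as_flag(comparator_adequate),
    terminated_early = .as_flag(terminated_early),
    superseded = .as_flag(superseded)
  ), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf("<trial_record %s>%s %s, %s, n=%s\n", x$trial_id,
              if (!is.na(x$study_name)) paste0(" [", x$study_name, "]") else "",
              x$setting, x$design, format(x$n)))
  cat(sprintf("  %s vs %s; primary endpoint %s\n",
              x$experimental_label, x$comparator_label, x$primary_endpoint))
  for (ep in x$endpoints) {
    cat(sprintf("  %s: control %s, gain %s, HR %s (%s-%s), ORR %s, %s\n",
                ep$endpoint, format(ep$control_median), format(ep$gain),
                format(ep$hazard_ratio), format(ep$hr_lower), format(ep$hr_upper),
                format(ep$orr_pct), ep$significant))
  }
  invisible(x)
}

#' Extract one endpoint summary from a record
#'
#' @param record A [trial_record()].
#' @param kind Endpoint kind (`"OS"`, `"PFS"`, `"ORR"`, `"QOL_TOX"`).
#' @return The matching [endpoint_summary()], or `NULL` if absent.
#' @export
get_endpoint <- function(record, kind) {
  for (ep in record$endpoints) if (identical(ep$endpoint, kind)) return(ep)
  NULL
}

#' Endpoint summary carrying the primary analysis
#'
#' Non-inferiority designs are graded on QoL/toxicity but their primary
#' statistical comparison is the (non-inferiority) PFS analysis, so
#' `NONINFERIORITY` maps to the PFS summary.
#'
#' @inheritParams get_endpoint
#' @return An [endpoint_summary()] or `NULL`.
#' @export
primary_summary <- function(record) {
  kind <- if (identical(record$primary_endpoint, "NONINFERIORITY")) "PFS"
          else record$primary_endpoint
  get_endpoint(record, kind)
}

#' A graded-result record
#'
#' The outcome of grading one trial record: the evaluation form used, the
#' preliminary grade from the form's threshold table, the QoL/toxicity
#' adjustment in `{-1, 0, +1}`, the final grade (preliminary + adjustment,
#' clamped to `[1, 5]`), and an ordered rationale trace of every rule that
#' fired. `form = "not_graded"` (with `final = NA`) is a first-class outcome
#' for records failing the eligibility/significance gate.
#'
#' @param trial_id Record identifier.
#' @param form `"2a"`, `"2b"`, `"2c"`, `"3"` or `"not_graded"`.
#' @param preliminary Integer 1-4, or `NA` when not graded.
#' @param adjustment Integer in `{-1, 0, 1}`.
#' @param final Integer 1-5, or `NA` when not graded.
#' @param rationale Character vector of rule firings, in order.
#' @return An object of class `graded_result`.
#' @export
graded_result <- function(trial_id, form, preliminary = NA, adjustment = 0L,
                          final = NA, rationale = character()) {
  structure(list(
    trial_id = as.character(trial_id[[1L]]),
    form = as.character(form[[1L]]),
    preliminary = if (is.na(preliminary[[1L]])) NA_integer_ else as.integer(preliminary[[1L]]),
    adjustment = as.integer(adjustment[[1L]]),
    final = if (is.na(final[[1L]])) NA_integer_ else as.integer(final[[1L]]),
    rationale = as.character(rationale)
  ), class = "graded_result")
}

#' @export
print.graded_result <- function(x, ...) {
  if (identical(x$form, "not_graded")) {
    cat(sprintf("<graded_result %s> not graded\n", x$trial_id))
  } else {
    cat(sprintf("<graded_result %s> MCBS %d (form %s): preliminary %d, adjustment %+d\n",
                x$trial_id, x$final, x$form, x$preliminary, x$adjustment))
  }
  for (r in x$rationale) cat("  - ", r, "\n", sep = "")
  invisible(x)
}

# ---- validation -------------------------------------------------------------

.check_num <- function(value, field, violations, lower = -Inf, upper = Inf,
                       positive = FALSE) {
  if (is.na(value)) return(violations)
  if (!is.numeric(value)) return(c(violations, sprintf("%s: not numeric", field)))
  if (positive && value <= 0)
    violations <- c(violations, sprintf("%s: must be strictly positive", field))
  if (value < lower || value > upper)
    violations <- c(violations, sprintf("%s: outside [%s, %s]", field,
                                        format(lower), format(upper)))
  violations
}

.validate_endpoint <- function(ep, violations) {
  pre <- sprintf("endpoint[%s]", ep$endpoint %||% "?")
  if (!ep$endpoint %in% .endpoint_kinds)
    violations <- c(violations, sprintf("%s.endpoint: unknown kind (admissible: %s)",
                                        pre, paste(.endpoint_kinds, collapse = ", ")))
  violations <- .check_num(ep$control_median, paste0(pre, ".control_median"),
                           violations, lower = 0)
  violations <- .check_num(ep$hazard_ratio, paste0(pre, ".hazard_ratio"),
                           violations, positive = TRUE)
  violations <- .check_num(ep$hr_lower, paste0(pre, ".hr_lower"), violations,
                           positive = TRUE)
  violations <- .check_num(ep$hr_upper, paste0(pre, ".hr_upper"), violations,
                           positive = TRUE)
  violations <- .check_num(ep$orr_pct, paste0(pre, ".orr_pct"), violations,
                           lower = 0, upper = 100)
  if (!is.na(ep$hr_lower) && !is.na(ep$hr_upper) && ep$hr_lower > ep$hr_upper)
    violations <- c(violations,
                    sprintf("%s.hr_ci: ConfidenceInterval ordering violated (lower %s > upper %s)",
                            pre, format(ep$hr_lower), format(ep$hr_upper)))
  if (!is.na(ep$hazard_ratio)) {
    if (is.na(ep$hr_lower) || is.na(ep$hr_upper)) {
      violations <- c(violations,
                      sprintf("%s.hr_ci: hazard_ratio present but confidence interval absent", pre))
    } else if (ep$hr_lower <= ep$hr_upper &&
               (ep$hazard_ratio < ep$hr_lower || ep$hazard_ratio > ep$hr_upper)) {
      violations <- c(violations,
                      sprintf("%s.hazard_ratio: point estimate outside its confidence interval", pre))
    }
  }
  if (identical(ep$endpoint, "ORR") && is.na(ep$orr_pct))
    violations <- c(violations, sprintf("%s.orr_pct: required for ORR endpoint", pre))
  if (!identical(ep$significant, ep$significant[[1L]]) ||
      !ep$significant %in% .significance)
    violations <- c(violations,
                    sprintf("%s.significant: unknown status (admissible: %s)",
                            pre, paste(.significance, collapse = ", ")))
  violations
}

#' Validate a trial record
#'
#' Total validation: never throws, even on malformed contents; every broken
#' invariant is returned as one violation string naming the field and rule.
#'
#' @param record A [trial_record()].
#' @return Character vector of violations; empty when the record is valid.
#' @export
#' @examples
#' rec <- trial_record("t1", "maintenance", "phase3_rct", 100, "drug", "placebo",
#'                     "PFS", endpoints = list(endpoint_summary("PFS",
#'                     control_median = 5, gain = 2, hazard_ratio = 0.5,
#'                     hr_lower = 0.4, hr_upper = 0.7, significant = "confirmed")))
#' validate_record(rec)  # character(0)
validate_record <- function(record) {
  tryCatch({
    v <- character()
    if (!is.list(record)) return("record: not a trial_record")
    if (is.na(.as_chr(record$trial_id))) v <- c(v, "trial_id: missing")
    if (!record$setting %in% .settings)
      v <- c(v, sprintf("setting: unknown value (admissible: %s)",
                        paste(.settings, collapse = ", ")))
    if (!record$design %in% .designs)
      v <- c(v, sprintf("design: unknown value (admissible: %s)",
                        paste(.designs, collapse = ", ")))
    if (!record$primary_endpoint %in% .primary_endpoints)
      v <- c(v, sprintf("primary_endpoint: unknown value (admissible: %s)",
                        paste(.primary_endpoints, collapse = ", ")))
    n <- .as_num(record$n)
    if (is.na(n) || n < 1) v <- c(v, "n: must be a count >= 1")
    kinds <- vapply(record$endpoints, function(ep) ep$endpoint %||% NA_character_,
                    character(1))
    if (anyDuplicated(kinds))
      v <- c(v, sprintf("endpoints: duplicate endpoint kind (%s)",
                        paste(unique(kinds[duplicated(kinds)]), collapse = ", ")))
    for (ep in record$endpoints) v <- .validate_endpoint(ep, v)
    ev <- record$evidence
    for (f in .flag_names)
      if (!is.logical(ev[[f]]) || is.na(ev[[f]]))
        v <- c(v, sprintf("evidence.%s: not a flag", f))
    if ((isTRUE(ev$qol_global_improved) || isTRUE(ev$qol_subscale_improved)) &&
        !isTRUE(ev$qol_reported))
      v <- c(v, "evidence.qol_reported: QoL improvement flagged but QoL not reported")
    v
  }, error = function(e) sprintf("record: unvalidatable (%s)", conditionMessage(e)))
}

# ---- number formatting for lossless text round trips ------------------------

.fmt_num <- function(x) {
  if (is.na(x)) return("")
  s <- format(x, digits = 15, scientific = FALSE, trim = TRUE)
  if (!isTRUE(as.numeric(s) == x)) s <- sprintf("%.17g", x)
  s
}

.fmt_flag <- function(x) if (isTRUE(x)) "true" else "false"

.parse_flag <- function(s) {
  if (is.na(s) || !nzchar(s)) return(FALSE)
  tolower(s) %in% c("true", "t", "1", "yes")
}

# ---- CSV serialization ------------------------------------------------------

.trial_csv_columns <- c(
  "trial_id", "study_name", "setting", "design", "n",
  "experimental_label", "comparator_label", "primary_endpoint",
  "pfs_control", "pfs_gain", "pfs_hr", "pfs_hr_lo", "pfs_hr_hi", "pfs_significant",
  "os_control", "os_gain", "os_hr", "os_hr_lo", "os_hr_hi", "os_significant",
  "orr_pct", "orr_significant",
  "qol_reported", "qol_global_improved", "qol_subscale_improved",
  "toxicity_reduced", "toxicity_increased", "early_discontinuation_reduced",
  "subgroup_of", "subgroup_prespecified", "comparator_adequate",
  "terminated_early", "superseded")

.record_to_row <- function(record) {
  pfs <- get_endpoint(record, "PFS")
  os <- get_endpoint(record, "OS")
  orr <- get_endpoint(record, "ORR")
  ev <- record$evidence
  c(trial_id = record$trial_id,
    study_name = if (is.na(record$study_name)) "" else record$study_name,
    setting = record$setting,
    design = record$design,
    n = .fmt_num(record$n),
    experimental_label = record$experimental_label,
    comparator_label = record$comparator_label,
    primary_endpoint = record$primary_endpoint,
    pfs_control = .fmt_num(if (is.null(pfs)) NA else pfs$control_median),
    pfs_gain = .fmt_num(if (is.null(pfs)) NA else pfs$gain),
    pfs_hr = .fmt_num(if (is.null(pfs)) NA else pfs$hazard_ratio),
    pfs_hr_lo = .fmt_num(if (is.null(pfs)) NA else pfs$hr_lower),
    pfs_hr_hi = .fmt_num(if (is.null(pfs)) NA else pfs$hr_upper),
    pfs_significant = if (is.null(pfs)) "" else pfs$significant,
    os_control = .fmt_num(if (is.null(os)) NA else os$control_median),
    os_gain = .fmt_num(if (is.null(os)) NA else os$gain),
    os_hr = .fmt_num(if (is.null(os)) NA else os$hazard_ratio),
    os_hr_lo = .fmt_num(if (is.null(os)) NA else os$hr_lower),
    os_hr_hi = .fmt_num(if (is.null(os)) NA else os$hr_upper),
    os_significant = if (is.null(os)) "" else os$significant,
    orr_pct = .fmt_num(if (is.null(orr)) NA else orr$orr_pct),
    orr_significant = if (is.null(orr)) "" else orr$significant,
    qol_reported = .fmt_flag(ev$qol_reported),
    qol_global_improved = .fmt_flag(ev$qol_global_improved),
    qol_subscale_improved = .fmt_flag(ev$qol_subscale_improved),
    toxicity_reduced = .fmt_flag(ev$toxicity_reduced),
    toxicity_increased = .fmt_flag(ev$toxicity_increased),
    early_discontinuation_reduced = .fmt_flag(ev$early_discontinuation_reduced),
    subgroup_of = if (is.na(record$subgroup_of)) "" else record$subgroup_of,
    subgroup_prespecified = .fmt_flag(record$subgroup_prespecified),
    comparator_adequate = .fmt_flag(record$comparator_adequate),
    terminated_early = .fmt_flag(record$terminated_early),
    superseded = .fmt_flag(record$superseded))
}

.check_enum <- function(value, admissible, column, row) {
  if (!value %in% admissible)
    stop(sprintf("row %d, column '%s': unknown value '%s' (admissible: %s)",
                 row, column, value, paste(admissible, collapse = ", ")),
         call. = FALSE)
  value
}

.row_to_record <- function(row, i) {
  num <- function(col) if (nzchar(row[[col]])) .as_num(row[[col]]) else NA_real_
  chr <- function(col) if (nzchar(row[[col]])) row[[col]] else NA_character_
  endpoints <- list()
  if (any(nzchar(unlist(row[c("pfs_control", "pfs_gain", "pfs_hr", "pfs_hr_lo",
                              "pfs_hr_hi", "pfs_significant")])))) {
    endpoints <- c(endpoints, list(endpoint_summary(
      "PFS", control_median = num("pfs_control"), gain = num("pfs_gain"),
      hazard_ratio = num("pfs_hr"), hr_lower = num("pfs_hr_lo"),
      hr_upper = num("pfs_hr_hi"),
      significant = if (nzchar(row[["pfs_significant"]]))
        .check_enum(row[["pfs_significant"]], .significance, "pfs_significant", i)
      else "exploratory_or_unreported")))
  }
  if (any(nzchar(unlist(row[c("os_control", "os_gain", "os_hr", "os_hr_lo",
                              "os_hr_hi", "os_significant")])))) {
    endpoints <- c(endpoints, list(endpoint_summary(
      "OS", control_median = num("os_control"), gain = num("os_gain"),
      hazard_ratio = num("os_hr"), hr_lower = num("os_hr_lo"),
      hr_upper = num("os_hr_hi"),
      significant = if (nzchar(row[["os_significant"]]))
        .check_enum(row[["os_significant"]], .significance, "os_significant", i)
      else "exploratory_or_unreported")))
  }
  if (nzchar(row[["orr_pct"]]) || nzchar(row[["orr_significant"]])) {
    endpoints <- c(endpoints, list(endpoint_summary(
      "ORR", orr_pct = num("orr_pct"),
      significant = if (nzchar(row[["orr_significant"]]))
        .check_enum(row[["orr_significant"]], .significance, "orr_significant", i)
      else "exploratory_or_unreported")))
  }
  trial_record(
    trial_id = row[["trial_id"]],
    study_name = chr("study_name"),
    setting = .check_enum(row[["setting"]], .settings, "setting", i),
    design = .check_enum(row[["design"]], .designs, "design", i),
    n = num("n"),
    experimental_label = row[["experimental_label"]],
    comparator_label = row[["comparator_label"]],
    primary_endpoint = .check_enum(row[["primary_endpoint"]], .primary_endpoints,
                                   "primary_endpoint", i),
    endpoints = endpoints,
    evidence = evidence_flags(
      qol_reported = .parse_flag(row[["qol_reported"]]),
      qol_global_improved = .parse_flag(row[["qol_global_improved"]]),
      qol_subscale_improved = .parse_flag(row[["qol_subscale_improved"]]),
      toxicity_reduced = .parse_flag(row[["toxicity_reduced"]]),
      toxicity_increased = .parse_flag(row[["toxicity_increased"]]),
      early_discontinuation_reduced = .parse_flag(row[["early_discontinuation_reduced"]])),
    subgroup_of = chr("subgroup_of"),
    subgroup_prespecified = .parse_flag(row[["subgroup_prespecified"]]),
    comparator_adequate = .parse_flag(row[["comparator_adequate"]]),
    terminated_early = .parse_flag(row[["terminated_early"]]),
    superseded = .parse_flag(row[["superseded"]]))
}

.record_to_list <- function(record) {
  null_na <- function(x) if (length(x) == 1L && is.na(x)) NULL else x
  list(
    trial_id = record$trial_id,
    study_name = null_na(record$study_name),
    setting = record$setting,
    design = record$design,
    n = record$n,
    experimental_label = record$experimental_label,
    comparator_label = record$comparator_label,
    primary_endpoint = record$primary_endpoint,
    endpoints = lapply(record$endpoints, function(ep) {
      out <- list(endpoint = ep$endpoint)
      for (f in c("control_median", "gain", "hazard_ratio", "hr_lower",
                  "hr_upper", "orr_pct"))
        if (!is.na(ep[[f]])) out[[f]] <- ep[[f]]
      out$significant <- ep$significant
      out
    }),
    evidence = record$evidence[.flag_names],
    subgroup_of = null_na(record$subgroup_of),
    subgroup_prespecified = record$subgroup_prespecified,
    comparator_adequate = record$comparator_adequate,
    terminated_early = record$terminated_early,
    superseded = record$superseded)
}

.list_to_record <- function(x) {
  trial_record(
    trial_id = x$trial_id,
    study_name = x$study_name %||% NA,
    setting = x$setting, design = x$design, n = x$n,
    experimental_label = x$experimental_label,
    comparator_label = x$comparator_label,
    primary_endpoint = x$primary_endpoint,
    endpoints = lapply(x$endpoints %||% list(), function(ep)
      endpoint_summary(ep$endpoint,
                       control_median = ep$control_median %||% NA,
                       gain = ep$gain %||% NA,
                       hazard_ratio = ep$hazard_ratio %||% NA,
                       hr_lower = ep$hr_lower %||% NA,
                       hr_upper = ep$hr_upper %||% NA,
                       orr_pct = ep$orr_pct %||% NA,
                       significant = ep$significant %||% "exploratory_or_unreported")),
    evidence = do.call(evidence_flags, lapply(x$evidence %||% list(), isTRUE)),
    subgroup_of = x$subgroup_of %||% NA,
    subgroup_prespecified = isTRUE(x$subgroup_prespecified),
    comparator_adequate = isTRUE(x$comparator_adequate),
    terminated_early = isTRUE(x$terminated_early),
    superseded = isTRUE(x$superseded))
}

#' Read trial records from CSV or JSON
#'
#' The CSV dialect is UTF-8, comma-separated, mandatory header, with `""`
#' meaning absent (distinct from `0`). Unknown enum literals raise an error
#' naming the row, column and admissible values.
#'
#' @param path File path.
#' @param format `"csv"` or `"json"`; default inferred from the file extension.
#' @return A list of [trial_record()] objects.
#' @export
read_trials <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(lapply(raw, .list_to_record))
  }
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        na.strings = NULL, fileEncoding = "UTF-8")
  missing_cols <- setdiff(.trial_csv_columns, names(df))
  if (length(missing_cols))
    stop("CSV schema violation: missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  lapply(seq_len(nrow(df)), function(i) .row_to_record(as.list(df[i, ]), i))
}

#' Write trial records to CSV or JSON
#'
#' Lossless inverse of [read_trials()]: reading back yields an identical
#' record list, with absent fields kept distinct from zeros.
#'
#' @param records List of [trial_record()] objects.
#' @inheritParams read_trials
#' @export
write_trials <- function(records, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(lapply(records, .record_to_list), path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(NULL))
  }
  rows <- t(vapply(records, .record_to_row,
                   setNames(character(length(.trial_csv_columns)), .trial_csv_columns)))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (length(records) == 0L) {
    df <- as.data.frame(setNames(rep(list(character()), length(.trial_csv_columns)),
                                 .trial_csv_columns))
  }
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

# ---- graded-result serialization -------------------------------------------

.rationale_sep <- " | "

#' Write graded results to CSV or JSON
#'
#' @param results List of [graded_result()] objects.
#' @inheritParams read_trials
#' @export
write_graded <- function(results, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    jsonlite::write_json(lapply(results, function(r) {
      out <- list(trial_id = r$trial_id, form = r$form)
      if (!is.na(r$preliminary)) out$preliminary <- r$preliminary
      out$adjustment <- r$adjustment
      if (!is.na(r$final)) out$final <- r$final
      out$rationale <- as.list(r$rationale)
      out
    }), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(NULL))
  }
  cols <- c("trial_id", "form", "preliminary", "adjustment", "final", "rationale")
  rows <- t(vapply(results, function(r)
    c(trial_id = r$trial_id, form = r$form,
      preliminary = if (is.na(r$preliminary)) "" else as.character(r$preliminary),
      adjustment = as.character(r$adjustment),
      final = if (is.na(r$final)) "" else as.character(r$final),
      rationale = paste(r$rationale, collapse = .rationale_sep)),
    setNames(character(6), cols)))
  df <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (length(results) == 0L)
    df <- as.data.frame(setNames(rep(list(character()), 6), cols))
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(NULL)
}

#' Read graded results written by [write_graded()]
#'
#' @inheritParams read_trials
#' @return A list of [graded_result()] objects.
#' @export
read_graded <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  if (format == "json") {
    raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    return(lapply(raw, function(x)
      graded_result(x$trial_id, x$form,
                    preliminary = x$preliminary %||% NA,
                    adjustment = x$adjustment %||% 0L,
                    final = x$final %||% NA,
                    rationale = unlist(x$rationale %||% list(), use.names = FALSE) %||% character())))
  }
  df <- utils::read.csv(path, colClasses = "character", na.strings = NULL,
                        fileEncoding = "UTF-8")
  lapply(seq_len(nrow(df)), function(i) {
    row <- as.list(df[i, ])
    graded_result(row$trial_id, row$form,
                  preliminary = if (nzchar(row$preliminary)) as.integer(row$preliminary) else NA,
                  adjustment = as.integer(row$adjustment),
                  final = if (nzchar(row$final)) as.integer(row$final) else NA,
                  rationale = if (nzchar(row$rationale))
                    strsplit(row$rationale, .rationale_sep, fixed = TRUE)[[1L]]
                  else character())
  })
}
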