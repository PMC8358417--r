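# Independent brute-force oracle for the grading rules: every band written
# out as one flat, fully spelled-out condition, no shared threshold table
# with the engine. Used only as a cross-check.

oracle_2a <- function(control, gain, lower) {
  if (control <= 12) {
    if (lower <= 0.65 && gain >= 3) return(4L)
    if (lower <= 0.65 && gain >= 2.5 && gain < 3) return(3L)
    if (lower <= 0.70 && gain >= 1.5 && gain < 2.5) return(2L)
    return(1L)
  }
  if (lower <= 0.70 && gain >= 5) return(4L)
  if (lower <= 0.70 && gain >= 3 && gain < 5) return(3L)
  if (lower <= 0.75 && gain >= 1.5 && gain < 3) return(2L)
  1L
}

oracle_2b <- function(control, gain, lower) {
  if (control <= 6) {
    if (lower <= 0.65 && gain >= 1.5) return(3L)
    if (lower <= 0.65 && gain < 1.5) return(2L)
    return(1L)
  }
  if (lower <= 0.65 && gain >= 3) return(3L)
  if (lower <= 0.65 && gain < 3) return(2L)
  1L
}

oracle_2c <- function(noninferior, global_qol, tox_reduced, subscale, less_discontinuation) {
  if (noninferior && (global_qol || tox_reduced)) return(4L)
  if (noninferior && (subscale || less_discontinuation)) return(3L)
  if (noninferior) return(2L)
  1L
}

oracle_3 <- function(orr_pct) {
  if (orr_pct >= 60) return(3L)
  if (orr_pct >= 20 && orr_pct < 60) return(2L)
  1L
}

# Oracle preliminary grade for a record already known to pass the gate.
# Returns NA when the record cannot be graded on a threshold form (missing
# inputs), which callers skip.
oracle_preliminary <- function(record) {
  pe <- record$primary_endpoint
  os <- get_endpoint(record, "OS")
  pfs <- get_endpoint(record, "PFS")
  orr <- get_endpoint(record, "ORR")
  os_confirmed <- !is.null(os) && os$significant == "confirmed"
  if (pe == "OS" || (pe == "PFS" && os_confirmed)) {
    if (is.null(os) || is.na(os$control_median) || is.na(os$gain) ||
        is.na(os$hr_lower)) return(NA_integer_)
    return(oracle_2a(os$control_median, os$gain, os$hr_lower))
  }
  if (pe == "PFS") {
    if (is.null(pfs) || is.na(pfs$control_median) || is.na(pfs$gain) ||
        is.na(pfs$hr_lower)) return(NA_integer_)
    return(oracle_2b(pfs$control_median, pfs$gain, pfs$hr_lower))
  }
  if (pe %in% c("QOL_TOX", "NONINFERIORITY")) {
    prim <- if (is.null(pfs)) NULL else pfs
    ev <- record$evidence
    return(oracle_2c(!is.null(prim) && prim$significant == "confirmed",
                     ev$qol_global_improved, ev$toxicity_reduced,
                     ev$qol_subscale_improved, ev$early_discontinuation_reduced))
  }
  if (pe == "ORR") {
    if (is.null(orr) || is.na(orr$orr_pct)) return(NA_integer_)
    return(oracle_3(orr$orr_pct))
  }
  NA_integer_
}

oracle_adjustment <- function(form, record) {
  ev <- record$evidence
  if (form %in% c("2c", "3")) return(0L)
  up <- ev$qol_global_improved || ev$qol_subscale_improved || ev$toxicity_reduced
  if (form == "2a") return(if (up) 1L else 0L)
  os <- get_endpoint(record, "OS")
  qol_improved <- ev$qol_global_improved || ev$qol_subscale_improved
  down <- FALSE
  if (!is.null(os) && os$significant == "not_significant" &&
      ev$qol_reported && !qol_improved) down <- TRUE
  if (ev$toxicity_increased) down <- TRUE
  if (up && down) return(0L)
  if (up) return(1L)
  if (down) return(-1L)
  0L
}
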