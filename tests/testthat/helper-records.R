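# Small record builders reused across test files.

make_pfs_record <- function(id = "t", control = 5, gain = 2, lower = 0.4,
                            upper = NULL, hr = NULL,
                            pfs_significant = "confirmed",
                            os = NULL, evidence = evidence_flags(),
                            setting = "maintenance", design = "phase3_rct",
                            n = 300, ...) {
  hr <- hr %||% round(lower * 1.2, 4)
  upper <- upper %||% round(hr * 1.3, 4)
  eps <- list(endpoint_summary("PFS", control_median = control, gain = gain,
                               hazard_ratio = hr, hr_lower = lower,
                               hr_upper = upper, significant = pfs_significant))
  if (!is.null(os)) eps <- c(eps, list(os))
  trial_record(id, setting, design, n, "experimental", "placebo", "PFS",
               endpoints = eps, evidence = evidence, ...)
}

os_summary <- function(control = NA, gain = NA, hr = NA, lower = NA, upper = NA,
                       significant = "not_significant") {
  endpoint_summary("OS", control_median = control, gain = gain,
                   hazard_ratio = hr, hr_lower = lower, hr_upper = upper,
                   significant = significant)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
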