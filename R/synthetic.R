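# Seeded generator of synthetic trial records with the statistical structure
# the grading pipeline assumes, for property testing without any download.

.generator_id <- "mcbscore-synthetic-trials v1"

#' Configuration for the synthetic trial generator
#'
#' Defaults emulate the published record population: progression-free
#' survival is the dominant primary endpoint, control-arm medians span the
#' observed 2-12 month range per setting, hazard ratios span clearly active
#' to null treatments, and confidence-interval width is driven by a nominal
#' event count through the standard log-hazard-ratio normal approximation
#' with standard error `2/sqrt(events)`.
#'
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @param n_trials Number of records to generate.
#' @param control_median_range Named list of `c(lo, hi)` month ranges for the
#'   control-arm median of the graded (PFS-scale) endpoint, per setting.
#' @param true_hr_range `c(lo, hi)` range of the drawn hazard ratio.
#' @param events_range `c(lo, hi)` range of the nominal event count driving
#'   the confidence-interval width.
#' @param endpoint_mix Named probabilities over primary endpoints
#'   `OS`, `PFS`, `ORR`; must sum to 1.
#' @param evidence_flag_rates Named Bernoulli rates for the evidence flags.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L, n_trials = 100L,
                              control_median_range = list(
                                platinum_sensitive = c(5, 12),
                                maintenance = c(3, 10),
                                platinum_resistant = c(2, 6)),
                              true_hr_range = c(0.3, 1.1),
                              events_range = c(50, 400),
                              endpoint_mix = c(OS = 0.2, PFS = 0.7, ORR = 0.1),
                              evidence_flag_rates = c(
                                qol_reported = 0.6,
                                qol_global_improved = 0.05,
                                qol_subscale_improved = 0.15,
                                toxicity_reduced = 0.05,
                                toxicity_increased = 0.2,
                                early_discontinuation_reduced = 0.1)) {
  cfg <- list(seed = as.integer(seed), n_trials = as.integer(n_trials),
              control_median_range = control_median_range,
              true_hr_range = as.numeric(true_hr_range),
              events_range = as.numeric(events_range),
              endpoint_mix = endpoint_mix,
              evidence_flag_rates = evidence_flag_rates,
              generator = .generator_id)
  for (s in .settings) {
    r <- cfg$control_median_range[[s]]
    if (is.null(r) || length(r) != 2L || r[1] > r[2] || r[1] <= 0)
      stop("invalid config field 'control_median_range$", s,
           "': need an ordered positive pair", call. = FALSE)
  }
  if (cfg$true_hr_range[1] > cfg$true_hr_range[2] || cfg$true_hr_range[1] <= 0)
    stop("invalid config field 'true_hr_range': need an ordered positive pair",
         call. = FALSE)
  if (cfg$events_range[1] > cfg$events_range[2] || cfg$events_range[1] < 1)
    stop("invalid config field 'events_range': need an ordered pair >= 1",
         call. = FALSE)
  if (abs(sum(cfg$endpoint_mix) - 1) > 1e-8 || any(cfg$endpoint_mix < 0) ||
      !all(c("OS", "PFS", "ORR") %in% names(cfg$endpoint_mix)))
    stop("invalid config field 'endpoint_mix': probabilities over OS/PFS/ORR summing to 1",
         call. = FALSE)
  if (any(cfg$evidence_flag_rates < 0 | cfg$evidence_flag_rates > 1))
    stop("invalid config field 'evidence_flag_rates': rates must lie in [0, 1]",
         call. = FALSE)
  structure(cfg, class = "simulation_config")
}

.runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

.synthetic_survival_endpoint <- function(kind, control, hr, events) {
  se <- 2 / sqrt(events)
  lo <- hr * exp(-1.96 * se)
  hi <- hr * exp(1.96 * se)
  gain <- control * (1 / hr - 1) * exp(stats::rnorm(1, 0, 0.1))
  endpoint_summary(kind,
                   control_median = round(control, 2),
                   gain = round(gain, 2),
                   hazard_ratio = round(hr, 4),
                   hr_lower = round(lo, 4), hr_upper = round(hi, 4),
                   significant = if (hi < 1) "confirmed" else "not_significant")
}

#' Generate synthetic trial records
#'
#' Deterministic for a fixed seed. Control medians are drawn log-uniformly
#' within the setting's range; the hazard ratio uniformly within
#' `true_hr_range`; the 95% CI from the log-HR normal approximation with
#' standard error `2/sqrt(events)`; the absolute gain as
#' `control * (1/HR - 1)` with multiplicative log-normal noise; significance
#' is confirmed exactly when the CI excludes 1 in favour of the study arm;
#' evidence flags are independent Bernoulli draws (improvement flags force
#' `qol_reported`). Every generated record passes [validate_record()].
#'
#' @param config A [simulation_config()].
#' @return List of [trial_record()]s of length `config$n_trials`.
#' @export
generate_trials <- function(config = simulation_config()) {
  if (!inherits(config, "simulation_config"))
    config <- do.call(simulation_config, config)
  set.seed(config$seed)
  rates <- config$evidence_flag_rates
  lapply(seq_len(config$n_trials), function(i) {
    setting <- sample(.settings, 1L)
    design <- sample(c("phase3_rct", "phase2_rct"), 1L, prob = c(0.6, 0.4))
    events <- round(stats::runif(1, config$events_range[1], config$events_range[2]))
    n <- max(2L, round(events * stats::runif(1, 1.2, 2)))
    primary <- sample(names(config$endpoint_mix), 1L, prob = config$endpoint_mix)
    cm_range <- config$control_median_range[[setting]]
    flags <- stats::setNames(
      stats::runif(length(rates)) < rates, names(rates))
    if (flags[["qol_global_improved"]] || flags[["qol_subscale_improved"]])
      flags[["qol_reported"]] <- TRUE
    endpoints <- list()
    if (primary == "ORR") {
      orr <- round(stats::runif(1, 5, 70), 1)
      endpoints <- list(endpoint_summary(
        "ORR", orr_pct = orr,
        significant = sample(c("confirmed", "not_significant"), 1L)))
    } else {
      pfs_control <- .runif_log(1, cm_range[1], cm_range[2])
      hr <- stats::runif(1, config$true_hr_range[1], config$true_hr_range[2])
      pfs <- .synthetic_survival_endpoint("PFS", pfs_control, hr, events)
      endpoints <- list(pfs)
      # OS is reported for about half of the survival-endpoint trials, with
      # its own (typically attenuated, rarely confirmed) hazard ratio.
      if (primary == "OS" || stats::runif(1) < 0.5) {
        os_control <- pfs_control * stats::runif(1, 2, 4)
        os_hr <- min(hr * stats::runif(1, 1.0, 1.4), 1.5)
        os <- .synthetic_survival_endpoint("OS", os_control, os_hr, events)
        endpoints <- if (primary == "OS") list(os) else list(pfs, os)
      } else if (primary == "PFS") {
        endpoints <- list(pfs)
      }
    }
    trial_record(
      trial_id = sprintf("syn-%04d", i),
      setting = setting, design = design, n = n,
      experimental_label = sprintf("agent-%04d plus backbone", i),
      comparator_label = "backbone",
      primary_endpoint = primary,
      endpoints = endpoints,
      evidence = do.call(evidence_flags, as.list(flags)),
      comparator_adequate = stats::runif(1) < 0.9,
      terminated_early = stats::runif(1) < 0.02,
      superseded = stats::runif(1) < 0.02)
  })
}

#' Deterministic grading grid for boundary testing
#'
#' Exhaustive grid over hazard-ratio CI lower bound (0.30 to 0.80 by 0.05),
#' absolute gain (0.5 to 6.0 months by 0.5), control-arm median (3, 5.9, 6,
#' 6.1, 11.9, 12, 12.1, 24 months — straddling both stratum bounds) and
#' endpoint (OS, PFS): 11 x 12 x 8 x 2 = 2112 records probing every
#' threshold edge of forms 2a and 2b. All evidence flags are off, so the
#' final grade equals the preliminary grade.
#'
#' @return List of 2112 [trial_record()]s.
#' @export
generate_grade_grid <- function() {
  lowers <- seq(0.30, 0.80, by = 0.05)
  gains <- seq(0.5, 6.0, by = 0.5)
  controls <- c(3, 5.9, 6, 6.1, 11.9, 12, 12.1, 24)
  kinds <- c("OS", "PFS")
  grid <- expand.grid(lower = lowers, gain = gains, control = controls,
                      kind = kinds, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    hr <- round(min(g$lower * 1.1, g$lower + 0.1), 4)
    ep <- endpoint_summary(g$kind, control_median = g$control, gain = g$gain,
                           hazard_ratio = hr, hr_lower = g$lower,
                           hr_upper = round(hr * 1.3, 4),
                           significant = "confirmed")
    trial_record(
      trial_id = sprintf("grid-%04d", i),
      setting = "maintenance", design = "phase3_rct", n = 400,
      experimental_label = "experimental", comparator_label = "placebo",
      primary_endpoint = g$kind, endpoints = list(ep))
  })
}
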