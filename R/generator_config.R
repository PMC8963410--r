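#' Default synthetic-cohort generator configuration
#'
#' Returns the configuration for the synthetic ED-sepsis encounter generator.
#' The defaults encode the study conditions the analysis assumes:
#'
#' * `target_class_mix` — outcome-class proportions of the emulated cohort
#'   (Non-VP 0.26, VP>24h 0.40, VP 8-24h 0.10, VP<8h 0.15, ICU-start 0.09).
#' * `vital_marginals` — per-predictor mean and SD targeted at the final
#'   decision time (exp-weighted RR 21 (4.7) min^-1, fluids while SBP<90
#'   890 (1200) mL, elapsed time 6.4 (6.1) h, min GCS 13 (3.7), min SpO2
#'   92 (5.7) %, SBP 80.0 (8.6) mmHg).
#' * `decision_coefficients` — the clinician decision policy's log-odds per
#'   natural unit for the six final-model predictors, the natural log of the
#'   published odds ratios divided by their unit increments: RR 1.55 per
#'   5 min^-1, fluids 1.41 per 1000 mL, elapsed time 0.40 per hour, GCS 0.40
#'   per unit, SpO2 0.63 per 5%, SBP 0.10 per 5 mmHg. The policy intercept is
#'   calibrated so the firing probability is 0.5 when every predictor sits at
#'   its marginal mean.
#'
#' @param n_encounters number of encounters to generate.
#' @param seed integer seed; identical configurations generate identical
#'   cohorts.
#' @return a list of class `ucv_generator_config`.
#' @export
default_generator_config <- function(n_encounters = 2000, seed = 1L) {
  cfg <- list(
    n_encounters = as.integer(n_encounters),
    seed = as.integer(seed),
    target_class_mix = c(NON_VP = 0.26, VP_GT24 = 0.40, VP_8_24 = 0.10,
                         VP_LT8 = 0.15, VP_ICU = 0.09),
    severity_dynamics = list(
      # two presentation phenotypes: rapidly progressing encounters arrive
      # early in their course and settle at a severe (but bounded) state;
      # the rest hover near their presenting severity. Severity follows a
      # discrete-time mean-reverting random walk toward the phenotype
      # asymptote.
      p_deteriorate = 0.45,
      baseline_deteriorate = c(mean = -1.2, sd = 0.5),
      asymptote_deteriorate = c(mean = 0.8, sd = 0.5),
      baseline_stabilize = c(mean = -0.4, sd = 0.35),
      asymptote_stabilize = c(mean = -0.3, sd = 0.4),
      reversion_rate = 0.5,
      noise_scale = 0.30
    ),
    observation_cadence = list(median_h = 0.5, sdlog = 0.5),
    vital_marginals = list(
      rr_expw = c(mean = 21, sd = 4.7),
      fluids_hypo = c(mean = 890, sd = 1200),
      elapsed_time = c(mean = 6.4, sd = 6.1),
      gcs_min = c(mean = 13, sd = 3.7),
      spo2_min = c(mean = 92, sd = 5.7),
      sbp_recent = c(mean = 80.0, sd = 8.6)
    ),
    decision_coefficients = c(
      rr_expw = log(1.55) / 5,
      fluids_hypo = log(1.41) / 1000,
      elapsed_time = log(0.40) / 1,
      gcs_min = log(0.40) / 1,
      spo2_min = log(0.63) / 5,
      sbp_recent = log(0.10) / 5
    ),
    fluid_policy = list(
      volumes_mL = c(250, 500, 1000, 1500), volume_probs = c(0.12, 0.38, 0.35, 0.15),
      bolus_prob = 0.40, bolus_prob_after_cap = 0.12, cap_mL = 2500,
      min_gap_h = 0.75
    ),
    icu_deferral_prob = 0.12,
    late_icu_prob = 0.05,
    ed_stay_hours = list(meanlog = log(5.5), sdlog = 0.75, min_h = 2.5, max_h = 30),
    duration_model = list(meanlog = 3.9, sdlog = 2.3, severity_coef = 0.08,
                          min_h = 0.5, max_h = 336),
    missing_vital_prob = 0.15,
    missing_lab_prob = 0.20
  )
  class(cfg) <- "ucv_generator_config"
  validate_generator_config(cfg)
}

#' Validate a generator configuration
#'
#' Checks the configuration invariants: class proportions sum to 1 (within
#' 1e-9), non-negative encounter count, strictly positive dispersions, and
#' probabilities in \[0, 1\].
#' @param config a generator configuration.
#' @return `config`, invisibly validated, or a configuration error.
#' @export
validate_generator_config <- function(config) {
  mix <- config$target_class_mix
  if (!setequal(names(mix), OUTCOME_CLASSES)) {
    stop("configuration error: target_class_mix must name the five outcome classes")
  }
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("configuration error: target_class_mix must sum to 1")
  }
  if (any(mix < 0)) stop("configuration error: negative class proportion")
  if (config$n_encounters < 0) stop("configuration error: n_encounters must be >= 0")
  sds <- c(
    vapply(config$vital_marginals, function(v) v[["sd"]], numeric(1)),
    config$observation_cadence$sdlog,
    config$severity_dynamics$noise_scale,
    config$ed_stay_hours$sdlog,
    config$duration_model$sdlog
  )
  if (any(sds <= 0)) stop("configuration error: all dispersions must be > 0")
  if (config$icu_deferral_prob < 0 || config$icu_deferral_prob > 1) {
    stop("configuration error: icu_deferral_prob must be in [0, 1]")
  }
  if (config$late_icu_prob < 0 || config$late_icu_prob > 1) {
    stop("configuration error: late_icu_prob must be in [0, 1]")
  }
  if (abs(sum(config$fluid_policy$volume_probs) - 1) > 1e-9) {
    stop("configuration error: fluid volume probabilities must sum to 1")
  }
  invisible(config)
}

#' Decision-policy intercept
#'
#' The intercept placing the firing probability at 0.5 when each predictor is
#' at its configured marginal mean: minus the sum of coefficient times mean.
#' @param config a generator configuration.
#' @return intercept on the log-odds scale.
#' @export
policy_intercept <- function(config) {
  beta <- config$decision_coefficients
  mu <- vapply(config$vital_marginals[names(beta)], function(v) v[["mean"]], numeric(1))
  -sum(beta * mu)
}

#' Decision-policy logit for a feature vector
#'
#' Evaluates the clinician decision policy: intercept plus the sum of
#' coefficient times value in natural units over the six policy predictors.
#' The generator samples a vasopressor start at the decisive (terminal)
#' hypotensive observation of the untreated trajectory with probability
#' `plogis(decision_logit(...))`.
#'
#' @param features named numeric vector (or a `values` element of an
#'   assembled feature vector) containing the six policy predictors.
#' @param config a generator configuration.
#' @return the logit (log-odds) of vasopressor initiation.
#' @export
decision_logit <- function(features, config = default_generator_config()) {
  if (is.list(features) && !is.null(features$values)) features <- features$values
  beta <- config$decision_coefficients
  missing <- setdiff(names(beta), names(features))
  if (length(missing)) {
    stop(sprintf("decision_logit: missing predictor(s): %s",
                 paste(missing, collapse = ", ")))
  }
  policy_intercept(config) + sum(beta * features[names(beta)])
}
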