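#' Synthetic ED-sepsis cohort generation
#'
#' Generates encounter cohorts with the longitudinal structure the usual-care
#' analysis assumes: irregular observation cadence, a latent severity random
#' walk driving correlated vital signs, hypotensive (SBP < 90 mmHg) episodes,
#' missing vitals and labs, an IV-fluid bolus policy active while
#' hypotensive, and a known clinician decision policy. At the decisive
#' moment — the terminal hypotensive observation of the untreated
#' trajectory, where escalation either happens or hypotension is about to
#' conclusively resolve — the policy fires with probability
#' `plogis(decision_logit(x))`, where `x` holds the six policy predictors
#' computed from the documented chart exactly as the downstream feature
#' engineering computes them. The probability that an encounter becomes a
#' sustained-vasopressor case given its decision-time feature vector is
#' therefore exactly logistic in those features, so the full pipeline can be
#' tested for parameter recovery against the configured coefficients.
#'
#' @name synthetic-cohort
NULL

# Internal vital-sign process constants mapping latent severity to observed
# vitals. Calibrated once so that the six policy predictors, evaluated at the
# final decision time over a default cohort, match the configured
# `vital_marginals` (means within 0.25 SD).
#' @keywords internal
vital_process <- function() {
  list(
    # enc = SD of a per-encounter organ-specific offset, independent of the
    # shared severity latent; keeps the candidate pool from collapsing onto
    # one collinear severity axis
    sbp = c(base = 87.0, sev = 9.0, noise = 4.3),
    rr = c(base = 20.0, sev = 3.0, noise = 4.5, enc = 3.5),
    hr = c(base = 96, sev = 9, noise = 12),
    temp = c(base = 37.2, sev = 0.35, noise = 0.7),
    spo2 = c(base = 98.0, sev = 3.5, noise = 3.0, enc = 3.5),
    gcs = c(scale = 0.85, noise = 0.62, shift = 1.5),
    pain = c(base = 3.5, noise = 2.5)
  )
}

# Simulate one candidate encounter; returns list(encounter, class) or NULL
# when the candidate fails the two-hypotensive-reading inclusion rule.
#' @keywords internal
sim_candidate <- function(config, id) {
  sd_ <- config$severity_dynamics
  vp_ <- vital_process()

  # ED stay and observation grid
  stay <- config$ed_stay_hours
  t_dep0 <- min(max(exp(stats::rnorm(1, stay$meanlog, stay$sdlog)), stay$min_h), stay$max_h)
  cad <- config$observation_cadence
  gaps <- stats::rlnorm(120, log(cad$median_h), cad$sdlog)
  times <- c(0, cumsum(gaps))
  times <- times[times <= t_dep0]
  n <- length(times)
  if (n < 3L) return(NULL)

  # latent severity: mean-reverting random walk toward a phenotype asymptote
  det <- stats::runif(1) < sd_$p_deteriorate
  grp <- if (det) "deteriorate" else "stabilize"
  base <- sd_[[paste0("baseline_", grp)]]
  asym <- sd_[[paste0("asymptote_", grp)]]
  a <- stats::rnorm(1, asym[["mean"]], asym[["sd"]])
  dt <- diff(times)
  s <- numeric(n)
  s[1] <- stats::rnorm(1, base[["mean"]], base[["sd"]])
  if (n > 1L) {
    eps <- stats::rnorm(n - 1L)
    for (j in seq_len(n - 1L)) {
      pull <- min(sd_$reversion_rate * dt[j], 1)
      s[j + 1L] <- s[j] + pull * (a - s[j]) + sd_$noise_scale * sqrt(dt[j]) * eps[j]
    }
  }

  # observed vitals
  o_rr <- stats::rnorm(1, 0, vp_$rr[["enc"]])
  o_spo2 <- stats::rnorm(1, 0, vp_$spo2[["enc"]])
  sbp <- vp_$sbp[["base"]] - vp_$sbp[["sev"]] * s + stats::rnorm(n, 0, vp_$sbp[["noise"]])
  rr <- vp_$rr[["base"]] + o_rr + vp_$rr[["sev"]] * s + stats::rnorm(n, 0, vp_$rr[["noise"]])
  hr <- vp_$hr[["base"]] + vp_$hr[["sev"]] * s + stats::rnorm(n, 0, vp_$hr[["noise"]])
  temp <- vp_$temp[["base"]] + vp_$temp[["sev"]] * s + stats::rnorm(n, 0, vp_$temp[["noise"]])
  spo2 <- pmin(100, pmax(50, vp_$spo2[["base"]] + o_spo2 - vp_$spo2[["sev"]] * pmax(s, 0) +
                           stats::rnorm(n, 0, vp_$spo2[["noise"]])))
  gcs <- pmin(15, pmax(3, 15 - floor(pmax(0,
    exp(vp_$gcs[["scale"]] * s + stats::rnorm(n, 0, vp_$gcs[["noise"]])) - vp_$gcs[["shift"]]
  ))))
  pain <- pmin(10, pmax(0, round(vp_$pain[["base"]] + stats::rnorm(n, 0, vp_$pain[["noise"]]))))
  rr <- pmax(rr, 6)
  sbp <- pmax(sbp, 40)
  hr <- pmax(hr, 30)

  # missingness: triage row fully documented, later non-SBP vitals drop out
  miss_p <- config$missing_vital_prob
  for (v in c("rr", "hr", "temp", "spo2", "gcs", "pain")) {
    vec <- get(v)
    drop <- c(FALSE, stats::runif(n - 1L) < miss_p)
    vec[drop] <- NA_real_
    assign(v, vec)
  }

  # IV-fluid boluses while hypotensive (placed strictly between observations)
  fp <- config$fluid_policy
  bolus_t <- numeric(0)
  bolus_v <- numeric(0)
  last_bolus <- -Inf
  cum <- 0
  aggressiveness <- stats::runif(1, 0.05, 1.95)
  for (j in seq_len(n)) {
    if (sbp[j] < 90 && times[j] - last_bolus >= fp$min_gap_h) {
      # resuscitation is front-loaded: bolus propensity decays over the stay
      p_b <- aggressiveness * exp(-0.12 * times[j]) *
        (if (cum < fp$cap_mL) fp$bolus_prob else fp$bolus_prob_after_cap)
      if (stats::runif(1) < p_b) {
        gap_next <- if (j < n) times[j + 1L] - times[j] else 0.4
        bt <- times[j] + 0.25 * gap_next
        bv <- sample(fp$volumes_mL, 1L, prob = fp$volume_probs)
        bolus_t <- c(bolus_t, bt)
        bolus_v <- c(bolus_v, bv)
        last_bolus <- bt
        cum <- cum + bv
      }
    }
  }

  hyp <- which(sbp < 90)
  if (length(hyp) < 2L) return(NULL)
  # the decisive moment: the terminal hypotensive observation of the
  # untreated trajectory (either escalation happens here, or hypotension is
  # about to conclusively resolve / the patient leaves the ED without it)
  f <- hyp[length(hyp)]

  # policy predictors at the decisive observation, from documented values
  rr_obs <- rr[seq_len(f)][!is.na(rr[seq_len(f)])]
  mu <- vapply(config$vital_marginals, function(v) v[["mean"]], numeric(1))
  x_rr <- if (length(rr_obs)) exp_weighted(rr_obs) else mu[["rr_expw"]]
  gcs_obs <- gcs[seq_len(f)][!is.na(gcs[seq_len(f)])]
  x_gcs <- if (length(gcs_obs)) min(gcs_obs) else mu[["gcs_min"]]
  spo2_obs <- spo2[seq_len(f)][!is.na(spo2[seq_len(f)])]
  x_spo2 <- if (length(spo2_obs)) min(spo2_obs) else mu[["spo2_min"]]
  x_fl <- sum(bolus_v[bolus_t < times[f] - 1e-9])
  logit <- decision_logit(c(
    rr_expw = x_rr, fluids_hypo = x_fl, elapsed_time = times[f],
    gcs_min = x_gcs, spo2_min = x_spo2, sbp_recent = sbp[f]
  ), config)
  fired <- stats::runif(1) < logistic(logit)

  vaso <- empty_vasopressors()
  cls <- NULL
  dep <- times[n] + stats::runif(1, 0.1, 0.4)
  if (fired) {
    t_fire <- times[f]
    dur <- duration_draw(config, s[f])
    if (stats::runif(1) < config$icu_deferral_prob) {
      # policy fired but escalation deferred until after ED departure
      start <- min(dep + stats::runif(1, 0.5, 3), 47.5)
      vaso <- fast_df(start_h = start, end_h = start + dur, location = "ICU")
      cls <- "VP_ICU"
    } else {
      gap_next <- if (f < n) times[f + 1L] - times[f] else 0.5
      start <- t_fire + stats::runif(1, 0.05, max(0.1, min(0.35, 0.8 * gap_next)))
      keep <- seq_len(f)
      times <- times[keep]; sbp <- sbp[keep]; rr <- rr[keep]; hr <- hr[keep]
      temp <- temp[keep]; spo2 <- spo2[keep]; gcs <- gcs[keep]; pain <- pain[keep]
      kb <- bolus_t < start
      bolus_t <- bolus_t[kb]; bolus_v <- bolus_v[kb]
      # a few post-initiation observations with recovering pressure
      k_post <- sample(2:4, 1L)
      t_post <- start + cumsum(stats::runif(k_post, 0.3, 0.8))
      sbp_post <- pmin(130, sbp[f] + 12 + cumsum(stats::runif(k_post, 2, 6)))
      times <- c(times, t_post)
      sbp <- c(sbp, sbp_post)
      rr_base <- if (is.na(rr[f])) 20 else rr[f]
      rr <- c(rr, pmax(6, rr_base - cumsum(rep(0.5, k_post)) + stats::rnorm(k_post, 0, 2)))
      hr <- c(hr, rep(NA_real_, k_post)); temp <- c(temp, rep(NA_real_, k_post))
      spo2 <- c(spo2, rep(NA_real_, k_post)); gcs <- c(gcs, rep(NA_real_, k_post))
      pain <- c(pain, rep(NA_real_, k_post))
      dep <- t_post[k_post] + stats::runif(1, 0.2, 0.8)
      vaso <- fast_df(start_h = start, end_h = start + dur, location = "ED")
      cls <- if (dur > 24) "VP_GT24" else if (dur >= 8) "VP_8_24" else "VP_LT8"
    }
  } else if (stats::runif(1) < config$late_icu_prob) {
    # deterioration after leaving the ED; initiation in the ICU
    start <- min(dep + stats::runif(1, 1, 6), 47.5)
    dur <- duration_draw(config, s[n])
    vaso <- fast_df(start_h = start, end_h = start + dur, location = "ICU")
    cls <- "VP_ICU"
  } else {
    cls <- "NON_VP"
  }

  if (sum(sbp < 90, na.rm = TRUE) < 2L) return(NULL)

  obs <- fast_df(time_h = times, sbp = sbp, hr = hr, rr = rr, temp = temp,
                 spo2 = spo2, gcs = gcs, pain = pain)
  labs <- sim_labs(config, s[1], s[length(s)], dep)
  e <- new_encounter(
    id = id,
    age = min(100, max(18, round(stats::rnorm(1, 66, 16)))),
    gender = if (stats::runif(1) < 0.52) "male" else "female",
    race = if (stats::runif(1) < 0.30) "nonwhite" else "white",
    comorbidities = stats::setNames(
      stats::runif(length(COMORBIDITY_NAMES)) <
        c(0.18, 0.08, 0.30, 0.06, 0.15, 0.12, 0.25),
      COMORBIDITY_NAMES
    ),
    symptoms = stats::setNames(
      stats::runif(length(SYMPTOM_NAMES)) <
        c(0.30, 0.35, 0.20, 0.10, 0.25, 0.30, 0.10, 0.15),
      SYMPTOM_NAMES
    ),
    referral_for_infection = stats::runif(1) < 0.12,
    cmo_in_ed = FALSE,
    ed_departure_h = dep,
    observations = obs,
    fluids = fast_df(time_h = bolus_t, volume_mL = bolus_v),
    vasopressors = vaso,
    labs = labs
  )
  list(encounter = e, class = cls)
}

#' @keywords internal
duration_draw <- function(config, severity) {
  dm <- config$duration_model
  d <- exp(stats::rnorm(1, dm$meanlog + dm$severity_coef * severity, dm$sdlog))
  min(max(d, dm$min_h), dm$max_h)
}

#' @keywords internal
sim_labs <- function(config, s0, s_end, dep) {
  nm <- character(0); tt <- numeric(0); vv <- numeric(0)
  mp <- config$missing_lab_prob
  if (stats::runif(1) >= mp) {
    t1 <- min(stats::runif(1, 0.2, 0.6), dep)
    v1 <- exp(stats::rnorm(1, log(2.3 + 0.6 * pmax(s0, 0)), 0.35))
    nm <- c(nm, "lactate"); tt <- c(tt, t1); vv <- c(vv, v1)
    if (dep > 3 && stats::runif(1) < 0.7) {
      nm <- c(nm, "lactate")
      tt <- c(tt, stats::runif(1, 2, dep))
      vv <- c(vv, v1 * exp(0.25 * pmax(s_end - s0, 0) + stats::rnorm(1, 0, 0.3)))
    }
  }
  if (stats::runif(1) >= mp) {
    nm <- c(nm, "wbc"); tt <- c(tt, min(stats::runif(1, 0.3, 0.8), dep))
    vv <- c(vv, exp(stats::rnorm(1, log(12), 0.45)))
  }
  if (stats::runif(1) >= mp) {
    nm <- c(nm, "creatinine"); tt <- c(tt, min(stats::runif(1, 0.3, 0.8), dep))
    vv <- c(vv, exp(stats::rnorm(1, log(1.3) + 0.15 * pmax(s0, 0), 0.45)))
  }
  if (!length(nm)) return(empty_labs())
  fast_df(name = nm, time_h = tt, value = vv)
}

#' Generate a synthetic encounter cohort
#'
#' Simulates encounters under the configured decision policy and
#' rejection-samples them toward `target_class_mix`: each candidate's outcome
#' class emerges from the policy and the realized vasopressor duration, and
#' candidates are kept only while their class quota is unfilled. Identical
#' configurations (including the seed) generate identical cohorts, and every
#' generated encounter satisfies the two-hypotensive-reading inclusion rule.
#'
#' @param config generator configuration from [default_generator_config()].
#' @return list of encounters of length `config$n_encounters`.
#' @export
generate_cohort <- function(config = default_generator_config()) {
  validate_generator_config(config)
  n <- config$n_encounters
  if (n == 0L) return(list())
  # largest-remainder quotas over the five classes
  raw <- config$target_class_mix * n
  quota <- floor(raw)
  rem <- n - sum(quota)
  if (rem > 0) {
    idx <- order(raw - quota, decreasing = TRUE)[seq_len(rem)]
    quota[idx] <- quota[idx] + 1
  }
  out <- vector("list", n)
  with_seed(config$seed, {
    filled <- 0L
    attempts <- 0L
    max_attempts <- 200L + 60L * n
    while (filled < n) {
      attempts <- attempts + 1L
      if (attempts > max_attempts) {
        stop("generate_cohort: could not satisfy target_class_mix; check configuration")
      }
      cand <- sim_candidate(config, id = sprintf("e%06d", filled + 1L))
      if (is.null(cand)) next
      if (quota[[cand$class]] > 0L) {
        quota[[cand$class]] <- quota[[cand$class]] - 1L
        filled <- filled + 1L
        cand$encounter$id <- sprintf("e%06d", filled)
        out[[filled]] <- cand$encounter
      }
    }
  })
  out
}

#' Summarize decision-time marginals of a cohort
#'
#' Means and standard deviations of the six policy predictors evaluated at
#' the final decision time over the model-development classes (`VP_GT24` and
#' `NON_VP`), used to verify generator calibration against the configured
#' targets. SDs use the population (n-denominator) convention; a single-row
#' summary is flagged degenerate (SD reported as 0).
#'
#' @param cohort list of encounters.
#' @param classes outcome classes included in the summary.
#' @return data.frame with columns `feature`, `mean`, `sd`, `n`,
#'   `degenerate`.
#' @export
summarize_marginals <- function(cohort, classes = c("VP_GT24", "NON_VP")) {
  if (!length(cohort)) stop("summarize_marginals: empty cohort")
  info <- classify_cohort(cohort)
  keep <- info$class %in% classes & !is.na(info$tf_h)
  if (!any(keep)) stop("summarize_marginals: no encounter with a valid decision time")
  specs <- build_feature_specs()
  specs <- specs[specs$name %in% POLICY_FEATURES, , drop = FALSE]
  tab <- build_feature_table(cohort[keep], info$tf_h[keep], specs)
  m <- as.matrix(tab$features)[, POLICY_FEATURES, drop = FALSE]
  mu <- colMeans(m)
  sdev <- sqrt(colMeans(sweep(m, 2, mu)^2))
  data.frame(
    feature = POLICY_FEATURES, mean = mu, sd = sdev, n = nrow(m),
    degenerate = nrow(m) < 2L, row.names = NULL
  )
}
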