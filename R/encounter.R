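#' Encounter data model
#'
#' An encounter is one ED visit: demographics, comorbidity and symptom flags,
#' time-stamped vital-sign observations, IV-fluid bolus events, vasopressor
#' episodes, and time-stamped labs. Times are real-valued hours since triage
#' (hour 0); vasopressor starts may be negative (pre-ED administration).
#'
#' @name encounter-model
NULL

COMORBIDITY_NAMES <- c(
  "active_cancer", "chronic_liver_disease", "diabetes", "esrd",
  "immune_compromise", "physical_disability", "chf_or_ckd"
)

SYMPTOM_NAMES <- c(
  "gi", "fatigue_malaise", "mental_status_change", "neurological",
  "pain", "respiratory", "skin", "urinary"
)

VITAL_NAMES <- c("sbp", "hr", "rr", "temp", "spo2", "gcs", "pain")

#' Outcome classes
#'
#' Five mutually exclusive outcome classes by vasopressor course within 48 h of
#' ED presentation, plus exclusion reasons applied before classification.
#' @export
OUTCOME_CLASSES <- c("NON_VP", "VP_GT24", "VP_8_24", "VP_LT8", "VP_ICU")

EXCLUSION_CLASSES <- c("EXCLUDED_PRIOR_VP", "EXCLUDED_CMO", "EXCLUDED_NO_TF")

#' Construct a validated encounter
#'
#' @param id unique encounter identifier.
#' @param age age in years (>= 18).
#' @param gender `"male"` or `"female"`.
#' @param race race label; `"nonwhite"` or `"white"` in generated data.
#' @param comorbidities named logical vector over the seven comorbidity flags.
#' @param symptoms named logical vector over the eight symptom-group flags.
#' @param referral_for_infection logical; presented by referral for an
#'   infectious reason.
#' @param cmo_in_ed logical; made comfort-measures-only in the ED.
#' @param ed_departure_h ED departure time, hours since triage.
#' @param observations data.frame with columns `time_h` and the vitals
#'   `sbp, hr, rr, temp, spo2, gcs, pain` (NA = not documented). Must be
#'   strictly time-sorted and each row must document at least one vital.
#' @param fluids data.frame with columns `time_h`, `volume_mL` (> 0).
#' @param vasopressors data.frame with columns `start_h`, `end_h` (NA = open
#'   course) and `location` in `PRE_ED`, `ED`, `ICU`, `OR`.
#' @param labs data.frame with columns `name` (`lactate`, `wbc`,
#'   `creatinine`), `time_h`, `value`.
#' @return an object of class `ucv_encounter`.
#' @export
new_encounter <- function(id, age, gender, race,
                          comorbidities, symptoms,
                          referral_for_infection, cmo_in_ed,
                          ed_departure_h, observations,
                          fluids = empty_fluids(),
                          vasopressors = empty_vasopressors(),
                          labs = empty_labs()) {
  e <- structure(
    list(
      id = as.character(id), age = as.numeric(age),
      gender = gender, race = race,
      comorbidities = comorbidities, symptoms = symptoms,
      referral_for_infection = isTRUE(referral_for_infection),
      cmo_in_ed = isTRUE(cmo_in_ed),
      ed_departure_h = as.numeric(ed_departure_h),
      observations = observations, fluids = fluids,
      vasopressors = vasopressors, labs = labs
    ),
    class = "ucv_encounter"
  )
  validate_encounter(e)
}

#' @keywords internal
empty_fluids <- function() data.frame(time_h = numeric(0), volume_mL = numeric(0))

#' @keywords internal
empty_vasopressors <- function() {
  data.frame(start_h = numeric(0), end_h = numeric(0), location = character(0))
}

#' @keywords internal
empty_labs <- function() {
  data.frame(name = character(0), time_h = numeric(0), value = numeric(0))
}

#' Validate encounter invariants
#'
#' Checks the structural invariants: strictly sorted observation times,
#' non-negative times, GCS in 3..15, SpO2 in (0, 100], at least one vital per
#' observation row, positive bolus volumes, and closed vasopressor episodes
#' with `end_h >= start_h`.
#' @param e an encounter.
#' @return `e`, invisibly unchanged, or an error describing the violation.
#' @export
validate_encounter <- function(e) {
  obs <- e$observations
  if (!is.data.frame(obs) || nrow(obs) < 1L) {
    stop(sprintf("encounter %s: needs at least one observation", e$id))
  }
  if (any(obs$time_h < 0)) stop(sprintf("encounter %s: negative observation time", e$id))
  if (is.unsorted(obs$time_h, strictly = TRUE)) {
    stop(sprintf("encounter %s: observations must be strictly time-sorted", e$id))
  }
  vit <- as.matrix(obs[, intersect(VITAL_NAMES, names(obs)), drop = FALSE])
  if (any(rowSums(!is.na(vit)) == 0L)) {
    stop(sprintf("encounter %s: observation row with no vitals", e$id))
  }
  if (any(!is.na(obs$gcs) & (obs$gcs < 3 | obs$gcs > 15))) {
    stop(sprintf("encounter %s: GCS outside 3..15", e$id))
  }
  if (any(!is.na(obs$spo2) & (obs$spo2 <= 0 | obs$spo2 > 100))) {
    stop(sprintf("encounter %s: SpO2 outside (0, 100]", e$id))
  }
  if (any(e$fluids$volume_mL <= 0)) {
    stop(sprintf("encounter %s: non-positive fluid volume", e$id))
  }
  vp <- e$vasopressors
  if (nrow(vp)) {
    closed <- !is.na(vp$end_h)
    if (any(vp$end_h[closed] < vp$start_h[closed])) {
      stop(sprintf("encounter %s: vasopressor episode ends before it starts", e$id))
    }
    if (!all(vp$location %in% c("PRE_ED", "ED", "ICU", "OR"))) {
      stop(sprintf("encounter %s: unknown vasopressor location", e$id))
    }
  }
  if (e$age < 18) stop(sprintf("encounter %s: age below 18", e$id))
  invisible(e)
}

#' @export
print.ucv_encounter <- function(x, ...) {
  cat(sprintf(
    "<ucv_encounter %s> age %g, %d obs over %.2f h, %d boluses, %d vasopressor episode(s)\n",
    x$id, x$age, nrow(x$observations),
    max(x$observations$time_h), nrow(x$fluids), nrow(x$vasopressors)
  ))
  invisible(x)
}

# ---- outcome classification -------------------------------------------------

#' Assign the outcome class of an encounter
#'
#' Classifies one encounter into one of the five mutually exclusive outcome
#' classes, or an exclusion reason:
#' * `EXCLUDED_PRIOR_VP` — a vasopressor episode started within 12 h before
#'   ED presentation;
#' * `EXCLUDED_CMO` — made comfort-measures-only in the ED;
#' * `NON_VP` — no vasopressor episode starting within `horizon_h` of triage;
#' * `VP_GT24`, `VP_8_24`, `VP_LT8` — first in-horizon episode started in the
#'   ED, classed by total course duration (sum over ED and subsequent ICU
#'   episodes): > 24 h, in the closed interval [8, 24] h, or < 8 h;
#' * `VP_ICU` — first in-horizon episode started after ED departure (ICU or
#'   operating room).
#'
#' Open-ended episodes (missing `end_h`) count as longer than 24 h.
#'
#' @param e an encounter.
#' @param horizon_h classification horizon in hours since triage (default 48).
#' @return one of the class strings above.
#' @export
classify_outcome <- function(e, horizon_h = 48) {
  vp <- e$vasopressors
  if (nrow(vp) > 1L) {
    o <- order(vp$start_h)
    vp <- vp[o, , drop = FALSE]
    ends <- ifelse(is.na(vp$end_h), Inf, vp$end_h)
    if (any(vp$start_h[-1L] < ends[-nrow(vp)] - 1e-9)) {
      stop(sprintf("encounter %s: overlapping vasopressor episodes", e$id))
    }
  }
  if (nrow(vp) && any(vp$start_h < 0 & vp$start_h >= -12)) {
    return("EXCLUDED_PRIOR_VP")
  }
  if (e$cmo_in_ed) return("EXCLUDED_CMO")
  in_horizon <- vp[vp$start_h >= 0 & vp$start_h <= horizon_h, , drop = FALSE]
  if (!nrow(in_horizon)) return("NON_VP")
  first <- in_horizon[which.min(in_horizon$start_h), ]
  if (first$location %in% c("ICU", "OR")) return("VP_ICU")
  # ED start: total course duration summed across all in-horizon-onset episodes
  dur <- sum(ifelse(is.na(in_horizon$end_h), Inf, in_horizon$end_h) - in_horizon$start_h)
  if (dur > 24) "VP_GT24" else if (dur >= 8) "VP_8_24" else "VP_LT8"
}

# ---- decision time ----------------------------------------------------------

#' Times of hypotensive observations
#'
#' Observation times with a measured SBP strictly below 90 mmHg, at or before
#' `through` (a time in hours, or `"ed_stay"` for the entire ED stay).
#' @param e an encounter.
#' @param through upper time bound in hours, or `"ed_stay"`.
#' @return numeric vector of times (possibly empty).
#' @export
hypotensive_observations <- function(e, through = "ed_stay") {
  lim <- if (identical(through, "ed_stay")) e$ed_departure_h else as.numeric(through)
  obs <- e$observations
  keep <- !is.na(obs$sbp) & obs$sbp < 90 & obs$time_h <= lim + 1e-12
  obs$time_h[keep]
}

#' Locate the final decision time t_f
#'
#' For encounters started on ED vasopressors, `t_f` is the latest observation
#' with measured SBP < 90 mmHg strictly before the first ED vasopressor start.
#' For `NON_VP` and `VP_ICU` encounters, it is the latest ED observation with
#' SBP < 90 mmHg. Returns `NA` when no qualifying observation exists; such
#' encounters are dropped from model development.
#'
#' @param e an encounter.
#' @param cls outcome class, from [classify_outcome()].
#' @return time in hours, or `NA_real_`.
#' @export
final_decision_time <- function(e, cls = classify_outcome(e)) {
  if (startsWith(cls, "EXCLUDED")) return(NA_real_)
  if (cls %in% c("VP_GT24", "VP_8_24", "VP_LT8")) {
    ed <- e$vasopressors[e$vasopressors$location == "ED" & e$vasopressors$start_h >= 0, , drop = FALSE]
    lim <- min(ed$start_h)
    t <- hypotensive_observations(e, through = "ed_stay")
    t <- t[t < lim - 1e-12]
  } else {
    t <- hypotensive_observations(e, through = "ed_stay")
  }
  if (!length(t)) NA_real_ else max(t)
}

#' Resolve the k-th timepoint before t_f
#'
#' `k = 0` is `t_f` itself; `k = j` is the j-th vital-sign observation
#' strictly before `t_f`. Returns `NA` (the row is excluded from analysis)
#' when fewer than `k` prior observations exist, or when the resolved
#' observation has a measured SBP at or above 90 mmHg (observations without a
#' measured SBP inherit the carried-forward SBP status).
#'
#' @param e an encounter.
#' @param tf the final decision time, from [final_decision_time()].
#' @param k non-negative integer index.
#' @return time in hours, or `NA_real_`.
#' @export
timepoint <- function(e, tf, k) {
  if (k < 0) stop("timepoint: k must be >= 0")
  if (is.na(tf)) return(NA_real_)
  if (k == 0) return(tf)
  prior <- e$observations$time_h[e$observations$time_h < tf - 1e-12]
  if (length(prior) < k) return(NA_real_)
  t_k <- prior[length(prior) - k + 1L]
  sbp <- carried_sbp(e, t_k)
  if (is.na(sbp) || sbp >= 90) return(NA_real_)
  t_k
}

# Carried-forward SBP status at time t: the most recent measured SBP at or
# before t (NA when none exists yet).
#' @keywords internal
carried_sbp <- function(e, t) {
  obs <- e$observations
  idx <- which(!is.na(obs$sbp) & obs$time_h <= t + 1e-12)
  if (!length(idx)) NA_real_ else obs$sbp[max(idx)]
}

#' Classify a whole cohort
#'
#' Applies [classify_outcome()] and [final_decision_time()] across a cohort,
#' marking encounters whose class is valid but that lack a qualifying
#' hypotensive observation as `EXCLUDED_NO_TF`.
#'
#' @param cohort list of encounters.
#' @param horizon_h classification horizon in hours.
#' @return data.frame with columns `id`, `class`, `tf_h`.
#' @export
classify_cohort <- function(cohort, horizon_h = 48) {
  cls <- vapply(cohort, classify_outcome, character(1), horizon_h = horizon_h)
  tf <- rep(NA_real_, length(cohort))
  ok <- !startsWith(cls, "EXCLUDED")
  tf[ok] <- mapply(function(e, cl) final_decision_time(e, cl), cohort[ok], cls[ok])
  cls[ok & is.na(tf)] <- "EXCLUDED_NO_TF"
  data.frame(
    id = vapply(cohort, function(e) e$id, character(1)),
    class = cls, tf_h = tf, stringsAsFactors = FALSE
  )
}
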