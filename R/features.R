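#' Candidate-predictor feature specifications
#'
#' Builds the candidate pool evaluated at an anchor timepoint: for every vital
#' and lab both the most recent documented value and an exponentially weighted
#' average; running extrema for GCS, SpO2, SBP, heart rate and pain; IV-fluid
#' totals (overall and while hypotensive); elapsed time from triage; and
#' static demographics, comorbidity flags, symptom-group flags, and referral
#' status. `natural_unit_increment` is the unit step used when reporting odds
#' ratios (e.g. per 5 mmHg, per 1000 mL).
#'
#' @param include_fluid_responsiveness reserved flag; fluid-responsiveness
#'   derived features are excluded from the default pool.
#' @return data.frame with columns `name`, `signal`, `transform`,
#'   `increment`.
#' @export
build_feature_specs <- function(include_fluid_responsiveness = FALSE) {
  spec <- function(name, signal, transform, increment) {
    data.frame(name = name, signal = signal, transform = transform,
               increment = increment, stringsAsFactors = FALSE)
  }
  vit_inc <- c(sbp = 5, hr = 10, rr = 5, temp = 1, spo2 = 5, gcs = 1, pain = 1)
  rows <- list()
  for (v in names(vit_inc)) {
    rows[[length(rows) + 1L]] <- spec(paste0(v, "_recent"), v, "most_recent", vit_inc[[v]])
    rows[[length(rows) + 1L]] <- spec(paste0(v, "_expw"), v, "exp_weighted", vit_inc[[v]])
  }
  rows[[length(rows) + 1L]] <- spec("sbp_min", "sbp", "running_min", 5)
  rows[[length(rows) + 1L]] <- spec("gcs_min", "gcs", "running_min", 1)
  rows[[length(rows) + 1L]] <- spec("spo2_min", "spo2", "running_min", 5)
  rows[[length(rows) + 1L]] <- spec("hr_max", "hr", "running_max", 10)
  rows[[length(rows) + 1L]] <- spec("pain_max", "pain", "running_max", 1)
  rows[[length(rows) + 1L]] <- spec("fluids_hypo", "fluid", "cumulative_hypotensive", 1000)
  rows[[length(rows) + 1L]] <- spec("fluids_total", "fluid", "cumulative", 1000)
  rows[[length(rows) + 1L]] <- spec("elapsed_time", "time", "elapsed", 1)
  rows[[length(rows) + 1L]] <- spec("lactate_initial", "lactate", "first", 1)
  rows[[length(rows) + 1L]] <- spec("lactate_worst", "lactate", "running_max", 1)
  rows[[length(rows) + 1L]] <- spec("wbc_recent", "wbc", "most_recent", 1)
  rows[[length(rows) + 1L]] <- spec("creatinine_recent", "creatinine", "most_recent", 1)
  rows[[length(rows) + 1L]] <- spec("age", "age", "static", 10)
  rows[[length(rows) + 1L]] <- spec("gender_male", "gender", "static", 1)
  rows[[length(rows) + 1L]] <- spec("race_nonwhite", "race", "static", 1)
  rows[[length(rows) + 1L]] <- spec("referral_infection", "referral", "static", 1)
  for (cm in COMORBIDITY_NAMES) {
    rows[[length(rows) + 1L]] <- spec(paste0("cm_", cm), cm, "static", 1)
  }
  for (sy in SYMPTOM_NAMES) {
    rows[[length(rows) + 1L]] <- spec(paste0("sym_", sy), sy, "static", 1)
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$name))
  rownames(out) <- NULL
  out
}

#' The six decision-policy predictors
#'
#' Names of the final usual-care model covariates: exponentially weighted
#' respiratory rate, fluids given while SBP < 90 mmHg, elapsed time from
#' triage, running-minimum GCS, running-minimum SpO2, and most recent SBP.
#' @export
POLICY_FEATURES <- c("rr_expw", "fluids_hypo", "elapsed_time",
                     "gcs_min", "spo2_min", "sbp_recent")

#' Exponentially weighted average of an observation series
#'
#' The most recent observation has weight 1 and the observation j steps
#' earlier has weight 2^-j (so the third-most-recent carries one-eighth the
#' weight of the current one); the result is the weight-normalized average.
#'
#' @param values numeric vector ordered oldest to newest, up to the anchor.
#' @return weighted average, or `NA_real_` for an empty series (signals the
#'   imputation path).
#' @export
exp_weighted <- function(values) {
  n <- length(values)
  if (!n) return(NA_real_)
  w <- 2^-((n - 1):0)
  sum(w * values) / sum(w)
}

#' IV-fluid volume administered while hypotensive
#'
#' Total bolus volume at or before `anchor` whose administration time falls in
#' a carried-forward SBP < 90 mmHg interval (SBP status at any time is the
#' most recent measured SBP).
#'
#' @param e an encounter.
#' @param anchor time in hours (>= 0).
#' @return volume in mL.
#' @export
fluids_while_hypotensive <- function(e, anchor) {
  fl <- e$fluids
  if (!nrow(fl)) return(0)
  keep <- fl$time_h <= anchor + 1e-12
  if (!any(keep)) return(0)
  obs <- e$observations
  sbp_t <- obs$time_h[!is.na(obs$sbp)]
  sbp_v <- obs$sbp[!is.na(obs$sbp)]
  status <- vapply(fl$time_h[keep], function(t) {
    idx <- which(sbp_t <= t + 1e-12)
    length(idx) > 0 && sbp_v[max(idx)] < 90
  }, logical(1))
  sum(fl$volume_mL[keep][status])
}

# Observed series (times, values) of a signal at or before the anchor.
#' @keywords internal
signal_series <- function(e, signal, anchor) {
  if (signal %in% VITAL_NAMES) {
    obs <- e$observations
    keep <- obs$time_h <= anchor + 1e-12 & !is.na(obs[[signal]])
    return(list(time = obs$time_h[keep], value = obs[[signal]][keep]))
  }
  if (signal %in% c("lactate", "wbc", "creatinine")) {
    lb <- e$labs[e$labs$name == signal & e$labs$time_h <= anchor + 1e-12, , drop = FALSE]
    return(list(time = lb$time_h, value = lb$value))
  }
  stop(sprintf("unknown series signal '%s'", signal))
}

#' @keywords internal
static_value <- function(e, signal) {
  switch(signal,
    age = e$age,
    gender = as.numeric(identical(e$gender, "male")),
    race = as.numeric(!identical(e$race, "white")),
    referral = as.numeric(e$referral_for_infection),
    {
      if (signal %in% COMORBIDITY_NAMES) return(as.numeric(isTRUE(e$comorbidities[[signal]])))
      if (signal %in% SYMPTOM_NAMES) return(as.numeric(isTRUE(e$symptoms[[signal]])))
      stop(sprintf("unknown static signal '%s'", signal))
    }
  )
}

#' Assemble a feature vector at an anchor timepoint
#'
#' Computes every feature in `specs` from data at or before `anchor`.
#' Missing values are carried forward from earlier observations; a signal
#' never documented through the anchor is imputed with its population median
#' (from `medians`, computed on the training split). Per-feature provenance
#' records `measured`, `carried_forward`, or `population_median`.
#'
#' @param e an encounter.
#' @param anchor anchor time in hours (a valid observation time).
#' @param specs feature specifications, from [build_feature_specs()].
#' @param medians named numeric vector of population medians, or `NULL`
#'   during the first (median-collection) pass, in which case
#'   never-documented signals yield `NA`.
#' @return list with `anchor_time_h`, named `values`, named `provenance`.
#' @export
assemble <- function(e, anchor, specs = build_feature_specs(), medians = NULL) {
  n <- nrow(specs)
  values <- numeric(n)
  prov <- character(n)
  for (i in seq_len(n)) {
    tr <- specs$transform[i]
    sg <- specs$signal[i]
    if (tr == "static") {
      values[i] <- static_value(e, sg); prov[i] <- "measured"; next
    }
    if (tr == "elapsed") {
      values[i] <- anchor; prov[i] <- "measured"; next
    }
    if (tr == "cumulative") {
      values[i] <- sum(e$fluids$volume_mL[e$fluids$time_h <= anchor + 1e-12])
      prov[i] <- "measured"; next
    }
    if (tr == "cumulative_hypotensive") {
      values[i] <- fluids_while_hypotensive(e, anchor)
      prov[i] <- "measured"; next
    }
    ser <- signal_series(e, sg, anchor)
    if (!length(ser$value)) {
      if (is.null(medians)) {
        values[i] <- NA_real_
      } else {
        nm <- specs$name[i]
        if (is.na(medians[nm])) {
          stop(sprintf("population median missing for feature '%s'", nm))
        }
        values[i] <- medians[[nm]]
      }
      prov[i] <- "population_median"
      next
    }
    values[i] <- switch(tr,
      most_recent = ser$value[length(ser$value)],
      exp_weighted = exp_weighted(ser$value),
      running_min = min(ser$value),
      running_max = max(ser$value),
      first = ser$value[1L],
      stop(sprintf("unknown transform '%s'", tr))
    )
    at_anchor <- abs(ser$time[length(ser$time)] - anchor) < 1e-9
    prov[i] <- if (at_anchor) "measured" else "carried_forward"
  }
  names(values) <- specs$name
  names(prov) <- specs$name
  list(anchor_time_h = anchor, values = values, provenance = prov)
}

#' Build a feature table for a set of encounters at given anchors
#'
#' Two-pass assembly: a first pass collects values with `NA` for signals
#' never documented, population medians are taken column-wise (or supplied,
#' for test/application data, to avoid leakage), and the second pass fills
#' the gaps.
#'
#' @param cohort list of encounters.
#' @param anchors numeric vector of anchor times, one per encounter (`NA`
#'   rows are skipped).
#' @param specs feature specifications.
#' @param medians frozen medians from a training table, or `NULL` to compute
#'   them from these rows.
#' @return list with `features` (data.frame, one row per valid anchor),
#'   `provenance` (parallel data.frame), `ids`, `anchors`, `medians`.
#' @export
build_feature_table <- function(cohort, anchors, specs = build_feature_specs(),
                                medians = NULL) {
  stopifnot(length(cohort) == length(anchors))
  keep <- which(!is.na(anchors))
  raw <- lapply(keep, function(i) assemble(cohort[[i]], anchors[i], specs, medians = NULL))
  mat <- do.call(rbind, lapply(raw, function(r) r$values))
  prov <- do.call(rbind, lapply(raw, function(r) r$provenance))
  if (is.null(medians)) {
    medians <- apply(mat, 2, stats::median, na.rm = TRUE)
    medians[is.nan(medians)] <- NA_real_
  }
  for (j in seq_len(ncol(mat))) {
    miss <- is.na(mat[, j])
    if (any(miss)) {
      nm <- colnames(mat)[j]
      if (is.na(medians[nm])) {
        stop(sprintf("population median missing for feature '%s'", nm))
      }
      mat[miss, j] <- medians[[nm]]
    }
  }
  list(
    features = as.data.frame(mat),
    provenance = as.data.frame(prov, stringsAsFactors = FALSE),
    ids = vapply(cohort[keep], function(e) e$id, character(1)),
    anchors = anchors[keep],
    medians = medians
  )
}

# ---- standardization --------------------------------------------------------

#' Fit and apply z-score standardization
#'
#' `fit_standardizer()` computes per-column means and population
#' (n-denominator) standard deviations from a training table;
#' `apply_standardizer()` centers and scales any table with those parameters.
#' Zero-variance columns are flagged degenerate and map to 0 (with a warning
#' at fit time).
#'
#' @param rows data.frame or matrix of numeric feature columns (>= 2 rows).
#' @return `fit_standardizer()`: list with `mean`, `sd`, `degenerate`;
#'   `apply_standardizer()`: data.frame of standardized columns.
#' @export
fit_standardizer <- function(rows) {
  rows <- as.matrix(rows)
  if (nrow(rows) < 2L) stop("fit_standardizer: need at least 2 rows")
  mu <- colMeans(rows)
  sdev <- sqrt(colMeans(sweep(rows, 2, mu)^2))
  degen <- sdev <= 0
  if (any(degen)) {
    warning(sprintf("zero-variance feature(s): %s",
                    paste(colnames(rows)[degen], collapse = ", ")))
  }
  list(mean = mu, sd = sdev, degenerate = degen)
}

#' @rdname fit_standardizer
#' @param params standardization parameters from `fit_standardizer()`.
#' @export
apply_standardizer <- function(params, rows) {
  rows <- as.matrix(rows)
  cols <- colnames(rows)
  stopifnot(all(cols %in% names(params$mean)))
  out <- sweep(rows, 2, params$mean[cols])
  sd_safe <- ifelse(params$degenerate[cols], 1, params$sd[cols])
  out <- sweep(out, 2, sd_safe, "/")
  degen <- which(params$degenerate[cols])
  if (length(degen)) out[, degen] <- 0
  as.data.frame(out)
}
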