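#' Score every hypotensive observation of a set of encounters
#'
#' Applies the usual-care model at all observation times with measured
#' SBP < 90 mmHg over the entire ED stay (through ED departure).
#'
#' @param model a `ucv_model`.
#' @param encounters list of encounters.
#' @return data.frame with columns `id`, `time_h`, `score`.
#' @export
score_observations <- function(model, encounters) {
  specs <- model$specs[model$specs$name %in% model$features, , drop = FALSE]
  rows <- lapply(encounters, function(e) {
    t <- hypotensive_observations(e, through = "ed_stay")
    if (!length(t)) return(NULL)
    data.frame(id = e$id, time_h = t, stringsAsFactors = FALSE)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(id = character(0), time_h = numeric(0), score = numeric(0)))
  }
  by_id <- stats::setNames(encounters, vapply(encounters, function(e) e$id, character(1)))
  enc_list <- by_id[rows$id]
  tab <- build_feature_table(enc_list, rows$time_h, specs, medians = model$medians)
  rows$score <- score_rows(model, tab$features)
  rows
}

#' Select a high-specificity operating point
#'
#' Negatives are the observation-level scores of `NON_VP` encounters at all
#' hypotensive timepoints over their ED stays. Returns the smallest score
#' threshold whose recomputed specificity (fraction of negatives strictly
#' below the threshold; a crossing is score >= threshold) meets the target —
#' i.e. the sensitivity-maximizing threshold subject to the specificity
#' constraint.
#'
#' @param model a `ucv_model`.
#' @param cohort list of encounters.
#' @param specificity_target required specificity in \[0, 1\] (default 0.90).
#' @return list with `threshold`, `specificity` (recomputed), `n_negative`.
#' @export
select_threshold <- function(model, cohort, specificity_target = 0.90) {
  info <- classify_cohort(cohort)
  neg_enc <- cohort[info$class == "NON_VP"]
  if (!length(neg_enc)) stop("select_threshold: no NON_VP encounters (no negatives)")
  neg <- score_observations(model, neg_enc)$score
  if (!length(neg)) stop("select_threshold: no hypotensive negative observations")
  cand <- sort(unique(c(neg, max(neg) + 1e-9)))
  spec_at <- vapply(cand, function(t) mean(neg < t), numeric(1))
  ok <- which(spec_at >= specificity_target)
  t_star <- cand[ok[1L]]
  list(threshold = t_star, specificity = mean(neg < t_star), n_negative = length(neg))
}

#' First threshold crossing of one encounter
#'
#' Earliest hypotensive observation (over the entire ED stay) whose score
#' meets the threshold. For encounters started on ED vasopressors only
#' observations at or before the start count (a crossing after treatment
#' began is not a "crossed before treatment"; one at the start instant is a
#' zero-delay crossing).
#'
#' @param model a `ucv_model`.
#' @param e an encounter.
#' @param threshold operating-point threshold.
#' @return time in hours, or `NA_real_` when the threshold is never reached.
#' @export
first_crossing <- function(model, e, threshold) {
  obs <- score_observations(model, list(e))
  if (!nrow(obs)) return(NA_real_)
  start <- ed_vp_start(e)
  if (!is.na(start)) obs <- obs[obs$time_h <= start + 1e-12, , drop = FALSE]
  hit <- obs$time_h[obs$score >= threshold]
  if (!length(hit)) NA_real_ else min(hit)
}

#' @keywords internal
ed_vp_start <- function(e) {
  vp <- e$vasopressors
  ed <- vp[vp$location == "ED" & vp$start_h >= 0, , drop = FALSE]
  if (!nrow(ed)) NA_real_ else min(ed$start_h)
}

#' @keywords internal
any_vp_start <- function(e, horizon_h = 48) {
  vp <- e$vasopressors
  vp <- vp[vp$start_h >= 0 & vp$start_h <= horizon_h, , drop = FALSE]
  if (!nrow(vp)) NA_real_ else min(vp$start_h)
}

#' Vasopressor-timing outlier report
#'
#' Applies the operating point across all non-excluded encounters: locates
#' each encounter's first threshold crossing, relates it to the (first
#' in-horizon) vasopressor start, classes the delay, and totals the IV fluid
#' given in the interim (crossing, start\] interval. Delay bins: within 1 h,
#' 1-2 h (boundaries to the smaller bin), more than 2 h; a vasopressor start
#' with no prior crossing is an early start; untreated encounters split into
#' crossed/never-crossed concordance groups.
#'
#' Patient-level sensitivity is the fraction of ED-treated encounters that
#' crossed before their vasopressor start. Positive predictive value is the
#' fraction of crossing encounters treated within the horizon, reported both
#' over all classes (`ppv`) and restricted to the development classes
#' (`ppv_development`).
#'
#' @param model a `ucv_model`.
#' @param cohort list of encounters.
#' @param threshold operating point, e.g. from [select_threshold()].
#' @param horizon_h treatment horizon in hours (default 48).
#' @return list with `per_encounter` (data.frame), `threshold`,
#'   `sensitivity`, `ppv`, `ppv_development`.
#' @export
timing_report <- function(model, cohort, threshold, horizon_h = 48) {
  info <- classify_cohort(cohort)
  keep <- !startsWith(info$class, "EXCLUDED")
  enc <- cohort[keep]
  cls <- info$class[keep]
  per <- lapply(seq_along(enc), function(i) {
    e <- enc[[i]]
    cross <- first_crossing(model, e, threshold)
    start <- any_vp_start(e, horizon_h)
    if (is.na(start)) {
      cat_ <- if (is.na(cross)) "NO_CROSS_NO_VP" else "CROSSED_NO_VP"
      delay <- NA_real_
      ivf <- NA_real_
    } else if (is.na(cross)) {
      cat_ <- "EARLY_START"
      delay <- NA_real_
      ivf <- NA_real_
    } else {
      delay <- start - cross
      cat_ <- if (delay <= 1) "WITHIN_1H" else if (delay <= 2) "DELAY_1_2H" else "DELAY_GT2H"
      fl <- e$fluids
      ivf <- sum(fl$volume_mL[fl$time_h > cross + 1e-12 & fl$time_h <= start + 1e-12])
    }
    data.frame(id = e$id, class = cls[i], first_crossing_h = cross,
               vp_start_h = start, delay_h = delay, category = cat_,
               interim_ivf_mL = ivf, stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  ed_treated <- per$class %in% c("VP_GT24", "VP_8_24", "VP_LT8")
  crossed_before <- ed_treated & !is.na(per$first_crossing_h)
  sens <- if (any(ed_treated)) sum(crossed_before) / sum(ed_treated) else NA_real_
  crossed <- !is.na(per$first_crossing_h)
  treated_any <- !is.na(per$vp_start_h)
  ppv <- if (any(crossed)) sum(crossed & treated_any) / sum(crossed) else NA_real_
  dev <- per$class %in% c("VP_GT24", "NON_VP")
  ppv_dev <- if (any(crossed & dev)) {
    sum(crossed & treated_any & dev) / sum(crossed & dev)
  } else NA_real_
  list(per_encounter = per, threshold = threshold,
       sensitivity = sens, ppv = ppv, ppv_development = ppv_dev)
}
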