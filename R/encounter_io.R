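#' Read and write encounter cohorts as JSON Lines
#'
#' One encounter object per line, field names exactly as in the encounter
#' type, all times in decimal hours since triage. The reader validates every
#' encounter and reports errors with line numbers; the writer round-trips
#' losslessly (to double precision).
#'
#' @param cohort list of encounters.
#' @param path file path.
#' @return `write_cohort_jsonl()` returns `path` invisibly;
#'   `read_cohort_jsonl()` returns a list of validated encounters.
#' @export
write_cohort_jsonl <- function(cohort, path) {
  lines <- vapply(cohort, function(e) {
    jsonlite::toJSON(list(
      id = e$id, age = e$age, gender = e$gender, race = e$race,
      comorbidities = as.list(e$comorbidities),
      symptoms = as.list(e$symptoms),
      referral_for_infection = e$referral_for_infection,
      cmo_in_ed = e$cmo_in_ed,
      ed_departure_h = e$ed_departure_h,
      observations = e$observations,
      fluids = e$fluids,
      vasopressors = e$vasopressors,
      labs = e$labs
    ), auto_unbox = TRUE, digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_cohort_jsonl
#' @export
read_cohort_jsonl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  out <- vector("list", length(lines))
  ids <- character(length(lines))
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyDataFrame = TRUE),
      error = function(err) stop(sprintf("line %d: malformed JSON (%s)", i, conditionMessage(err)))
    )
    e <- tryCatch(
      new_encounter(
        id = rec$id, age = rec$age, gender = rec$gender, race = rec$race,
        comorbidities = unlist(rec$comorbidities),
        symptoms = unlist(rec$symptoms),
        referral_for_infection = rec$referral_for_infection,
        cmo_in_ed = rec$cmo_in_ed,
        ed_departure_h = rec$ed_departure_h,
        observations = coerce_table(rec$observations, c("time_h", VITAL_NAMES)),
        fluids = coerce_table(rec$fluids, c("time_h", "volume_mL")),
        vasopressors = coerce_vp(rec$vasopressors),
        labs = coerce_labs(rec$labs)
      ),
      error = function(err) stop(sprintf("line %d: %s", i, conditionMessage(err)))
    )
    ids[i] <- e$id
    out[[i]] <- e
  }
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate encounter id '%s'", ids[anyDuplicated(ids)][1]))
  }
  out
}

#' @keywords internal
coerce_table <- function(x, cols) {
  if (is.null(x) || (is.data.frame(x) && !nrow(x)) || !length(x)) {
    x <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
  }
  x <- as.data.frame(x)
  for (cl in setdiff(cols, names(x))) x[[cl]] <- NA_real_
  for (cl in cols) x[[cl]] <- as.numeric(x[[cl]])
  x[, cols, drop = FALSE]
}

#' @keywords internal
coerce_vp <- function(x) {
  if (is.null(x) || !length(x) || (is.data.frame(x) && !nrow(x))) return(empty_vasopressors())
  x <- as.data.frame(x)
  if (is.null(x$end_h)) x$end_h <- NA_real_
  data.frame(
    start_h = as.numeric(x$start_h), end_h = as.numeric(x$end_h),
    location = as.character(x$location), stringsAsFactors = FALSE
  )
}

#' @keywords internal
coerce_labs <- function(x) {
  if (is.null(x) || !length(x) || (is.data.frame(x) && !nrow(x))) return(empty_labs())
  x <- as.data.frame(x)
  data.frame(
    name = as.character(x$name), time_h = as.numeric(x$time_h),
    value = as.numeric(x$value), stringsAsFactors = FALSE
  )
}
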