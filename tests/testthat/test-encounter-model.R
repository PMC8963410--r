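test_that("encounter invariants are enforced", {
  expect_error(make_encounter(observations = make_obs(c(1, 1), sbp = c(85, 84))),
               "time-sorted")
  expect_error(make_encounter(observations = make_obs(c(0, 1), sbp = c(85, 84),
                                                      gcs = c(2, 14))), "GCS")
  expect_error(make_encounter(observations = make_obs(c(0, 1), sbp = c(85, 84),
                                                      spo2 = c(101, 95))), "SpO2")
  expect_error(make_encounter(fluids = data.frame(time_h = 1, volume_mL = 0)),
               "fluid")
  expect_error(make_encounter(vasopressors = vp_episode(5, 3)), "ends before")
  expect_error(make_encounter(age = 16), "age")
})

test_that("outcome classification follows the course-duration definitions", {
  # ED start at 3 h for 30 h: sustained course
  expect_identical(classify_outcome(make_encounter(vasopressors = vp_episode(3, 33))),
                   "VP_GT24")
  # no episodes at all
  expect_identical(classify_outcome(make_encounter()), "NON_VP")
  # initiation in the ICU within the horizon
  expect_identical(classify_outcome(make_encounter(vasopressors = vp_episode(20, 30, "ICU"))),
                   "VP_ICU")
  # vasopressors before arrival
  expect_identical(classify_outcome(make_encounter(vasopressors = vp_episode(-6, 2, "PRE_ED"))),
                   "EXCLUDED_PRIOR_VP")
  # pre-ED use more than 12 h before presentation does not exclude
  expect_identical(classify_outcome(make_encounter(
    vasopressors = rbind(vp_episode(-20, -15, "PRE_ED"), vp_episode(3, 40))
  )), "VP_GT24")
  # comfort measures only
  expect_identical(classify_outcome(make_encounter(cmo = TRUE)), "EXCLUDED_CMO")
  # episode beyond the horizon
  expect_identical(classify_outcome(make_encounter(vasopressors = vp_episode(50, 80, "ICU"))),
                   "NON_VP")
  # open-ended course counts as sustained
  expect_identical(classify_outcome(make_encounter(vasopressors = vp_episode(3, NA))),
                   "VP_GT24")
  expect_error(classify_outcome(make_encounter(
    vasopressors = rbind(vp_episode(3, 10), vp_episode(8, 12))
  )), "overlapping")
})

test_that("duration boundaries are closed at [8, 24]", {
  dur_class <- function(d) classify_outcome(make_encounter(vasopressors = vp_episode(2, 2 + d)))
  expect_identical(dur_class(7.99), "VP_LT8")
  expect_identical(dur_class(8), "VP_8_24")
  expect_identical(dur_class(24), "VP_8_24")
  expect_identical(dur_class(24.01), "VP_GT24")
  # total course duration sums ED and subsequent ICU episodes
  expect_identical(classify_outcome(make_encounter(
    vasopressors = rbind(vp_episode(2, 8), vp_episode(9, 30, "ICU"))
  )), "VP_GT24")
})

test_that("final decision time anchors to the last qualifying observation", {
  # treated: last SBP < 90 strictly before the ED start
  e <- make_encounter(observations = make_obs(c(1, 2), sbp = c(85, 86)),
                      vasopressors = vp_episode(2.5, 40))
  expect_equal(final_decision_time(e), 2)
  # a later hypotensive reading before the start moves t_f to it
  e1b <- make_encounter(observations = make_obs(c(1, 2, 2.4), sbp = c(85, 86, 84)),
                        vasopressors = vp_episode(2.5, 40))
  expect_equal(final_decision_time(e1b), 2.4)

  # untreated: last hypotensive observation even if later SBPs recovered
  e2 <- make_encounter(observations = make_obs(c(1, 3, 5, 6), sbp = c(85, 88, 95, 99)))
  expect_equal(final_decision_time(e2), 3)

  # immediate vasopressors without documented prior hypotension: no t_f
  e3 <- make_encounter(observations = make_obs(c(0, 1, 2), sbp = c(120, 85, 84)),
                       vasopressors = vp_episode(0.2, 40))
  expect_true(is.na(final_decision_time(e3)))
})

test_that("timepoint resolution excludes rows without history or without hypotension", {
  e <- make_encounter(observations = make_obs(c(0.5, 1.0, 1.5), sbp = c(85, 86, 84)))
  expect_equal(timepoint(e, 1.5, 0), 1.5)
  expect_equal(timepoint(e, 1.5, 1), 1.0)
  expect_equal(timepoint(e, 1.5, 2), 0.5)
  expect_true(is.na(timepoint(e, 1.5, 4)))
  expect_error(timepoint(e, 1.5, -1), "k")

  # the prior observation carries SBP at or above 90: row excluded
  e2 <- make_encounter(observations = make_obs(c(0.5, 1.0, 1.5), sbp = c(85, 95, 84)))
  expect_true(is.na(timepoint(e2, 1.5, 1)))
  expect_equal(timepoint(e2, 1.5, 2), 0.5)

  # observation without measured SBP inherits carried-forward hypotension
  e3 <- make_encounter(observations = make_obs(c(0.5, 1.0, 1.5), sbp = c(85, NA, 84),
                                               hr = c(NA, 100, NA)))
  expect_equal(timepoint(e3, 1.5, 1), 1.0)
})

test_that("hypotensive observations use a strict 90 mmHg cut", {
  e <- make_encounter(observations = make_obs(1:4, sbp = c(95, 85, 88, 92)), departure = 10)
  expect_equal(hypotensive_observations(e), c(2, 3))
  expect_equal(hypotensive_observations(e, through = 2), 2)
  e2 <- make_encounter(observations = make_obs(1:3, sbp = c(95, 92, 90)), departure = 10)
  expect_length(hypotensive_observations(e2), 0)
})

test_that("classes plus exclusions partition any cohort", {
  cohort <- small_cohort_fixture()
  info <- classify_cohort(cohort)
  counts <- table(info$class)
  expect_identical(sum(counts), length(cohort))
  expect_true(all(names(counts) %in% c(OUTCOME_CLASSES,
                                       "EXCLUDED_PRIOR_VP", "EXCLUDED_CMO", "EXCLUDED_NO_TF")))
  # t_f never at or after the first ED vasopressor start
  for (i in seq_along(cohort)) {
    if (!info$class[i] %in% c("VP_GT24", "VP_8_24", "VP_LT8")) next
    vp <- cohort[[i]]$vasopressors
    start <- min(vp$start_h[vp$location == "ED"])
    expect_lt(info$tf_h[i], start)
  }
})

test_that("JSON Lines round-trips losslessly and reports line errors", {
  cohort <- generate_cohort(default_generator_config(n_encounters = 15, seed = 12))
  path <- tempfile(fileext = ".jsonl")
  write_cohort_jsonl(cohort, path)
  back <- read_cohort_jsonl(path)
  expect_identical(length(back), length(cohort))
  for (i in seq_along(cohort)) {
    expect_equal(back[[i]]$observations, cohort[[i]]$observations, tolerance = 1e-12)
    expect_equal(back[[i]]$fluids, cohort[[i]]$fluids, tolerance = 1e-12)
    expect_identical(back[[i]]$id, cohort[[i]]$id)
    expect_identical(back[[i]]$comorbidities, cohort[[i]]$comorbidities)
  }
  lines <- readLines(path)
  writeLines(c(lines[1], "{not json", lines[2]), path)
  expect_error(read_cohort_jsonl(path), "line 2")
})
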