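# Builders for hand-crafted encounters and memoized heavyweight fixtures
# shared across test files.

make_obs <- function(time_h, sbp = NA, hr = NA, rr = NA, temp = NA,
                     spo2 = NA, gcs = NA, pain = NA) {
  data.frame(time_h = time_h, sbp = sbp, hr = hr, rr = rr, temp = temp,
             spo2 = spo2, gcs = gcs, pain = pain)
}

make_encounter <- function(id = "t1",
                           observations = make_obs(c(0, 1, 2), sbp = c(95, 85, 88), hr = 90),
                           fluids = NULL, vasopressors = NULL,
                           cmo = FALSE, departure = 8, age = 60) {
  new_encounter(
    id = id, age = age, gender = "female", race = "white",
    comorbidities = stats::setNames(rep(FALSE, length(dynpract:::COMORBIDITY_NAMES)),
                                    dynpract:::COMORBIDITY_NAMES),
    symptoms = stats::setNames(rep(FALSE, length(dynpract:::SYMPTOM_NAMES)),
                               dynpract:::SYMPTOM_NAMES),
    referral_for_infection = FALSE, cmo_in_ed = cmo,
    ed_departure_h = departure, observations = observations,
    fluids = if (is.null(fluids)) dynpract:::empty_fluids() else fluids,
    vasopressors = if (is.null(vasopressors)) dynpract:::empty_vasopressors() else vasopressors,
    labs = dynpract:::empty_labs()
  )
}

vp_episode <- function(start, end = NA, location = "ED") {
  data.frame(start_h = start, end_h = end, location = location,
             stringsAsFactors = FALSE)
}

# memoized fixtures: generated once per test run
.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

default_cohort_fixture <- function() {
  memo("cohort2000", generate_cohort(default_generator_config(n_encounters = 2000, seed = 1)))
}

default_model_fixture <- function() {
  memo("model2000", {
    cohort <- default_cohort_fixture()
    split <- split_cohort(cohort, 0.9, seed = 1)
    model <- train_ucv(split$train, seed = 1)
    list(cohort = cohort, split = split, model = model)
  })
}

small_cohort_fixture <- function() {
  memo("cohort300", generate_cohort(default_generator_config(n_encounters = 300, seed = 42)))
}

# a transparent single-covariate scoring model: score = plogis(-(sbp - 85) / 5)
toy_sbp_model <- function() {
  specs <- build_feature_specs()
  structure(list(
    features = "sbp_recent",
    intercept = 0,
    coefficients = c(sbp_recent = -1),
    standardizer = list(mean = c(sbp_recent = 85), sd = c(sbp_recent = 5),
                        degenerate = c(sbp_recent = FALSE)),
    specs = specs,
    odds_ratios = NULL,
    medians = c(sbp_recent = 85),
    penalized = FALSE,
    metadata = list()
  ), class = "ucv_model")
}
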