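test_that("exponential weighting halves at each step back", {
  # an impulse three observations back carries one eighth the current weight
  w3 <- exp_weighted(c(1, 0, 0, 0)) # oldest-first: impulse 3 steps back
  w0 <- exp_weighted(c(0, 0, 0, 1))
  expect_equal(w3 / w0, 1 / 8, tolerance = 1e-12)

  expect_equal(exp_weighted(42), 42)
  expect_equal(exp_weighted(c(2, 4, 8)), (1 * 8 + 0.5 * 4 + 0.25 * 2) / 1.75)
  expect_true(is.na(exp_weighted(numeric(0))))

  # a constant series is a fixed point for any length
  for (n in c(1, 2, 5, 17)) expect_equal(exp_weighted(rep(3.7, n)), 3.7)
  # single observation equals most-recent
  expect_equal(exp_weighted(9.1), 9.1)
})

test_that("fluid accounting respects carried-forward hypotension intervals", {
  e <- make_encounter(
    observations = make_obs(c(0.5, 1.5, 3), sbp = c(85, 95, 84)),
    fluids = data.frame(time_h = c(1.0, 2.0), volume_mL = c(500, 500)),
    departure = 6
  )
  # bolus at 1.0 h falls in an SBP 85 interval; bolus at 2.0 h in an SBP 95 one
  expect_equal(fluids_while_hypotensive(e, 3), 500)
  expect_equal(fluids_while_hypotensive(e, 0.9), 0)
  expect_equal(fluids_while_hypotensive(make_encounter(), 5), 0)

  e2 <- make_encounter(observations = make_obs(c(0, 1), sbp = c(95, 92)),
                       fluids = data.frame(time_h = 0.5, volume_mL = 1000))
  expect_equal(fluids_while_hypotensive(e2, 2), 0)

  # non-decreasing in the anchor
  e3 <- small_cohort_fixture()[[3]]
  anchors <- sort(e3$observations$time_h)
  vals <- vapply(anchors, function(a) fluids_while_hypotensive(e3, a), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("feature assembly records imputation provenance", {
  specs <- build_feature_specs()
  e <- make_encounter(observations = make_obs(c(0, 1, 2), sbp = c(85, 84, 83),
                                              spo2 = c(94, NA, NA), rr = c(18, NA, 20)))
  fv <- assemble(e, 2, specs)
  expect_identical(fv$provenance[["spo2_min"]], "carried_forward")
  expect_equal(fv$values[["spo2_min"]], 94)
  expect_identical(fv$provenance[["sbp_recent"]], "measured")
  expect_equal(fv$values[["sbp_recent"]], 83)
  expect_equal(fv$values[["rr_expw"]], exp_weighted(c(18, 20)))
  expect_equal(fv$values[["elapsed_time"]], 2)
  # lab never measured: population median with provenance
  expect_identical(fv$provenance[["wbc_recent"]], "population_median")
  sub <- specs[specs$name %in% c("sbp_recent", "wbc_recent"), ]
  fv2 <- assemble(e, 2, sub, medians = c(wbc_recent = 11))
  expect_equal(fv2$values[["wbc_recent"]], 11)
  # medians missing a needed feature: error names it
  expect_error(assemble(e, 2, sub, medians = c(lactate_initial = 2)), "wbc_recent")
})

test_that("the feature table freezes training medians for later data", {
  cohort <- small_cohort_fixture()[1:40]
  info <- classify_cohort(cohort)
  tab <- build_feature_table(cohort, info$tf_h)
  expect_identical(nrow(tab$features), sum(!is.na(info$tf_h)))
  expect_false(anyNA(tab$features))
  # frozen medians reproduce identical imputations on the same rows
  tab2 <- build_feature_table(cohort, info$tf_h, medians = tab$medians)
  expect_equal(tab$features, tab2$features)
})

test_that("z-scoring uses the population-SD convention and inverts cleanly", {
  p <- fit_standardizer(data.frame(a = c(1, 3), b = c(2, 2.5)))
  z <- apply_standardizer(p, data.frame(a = c(1, 3), b = c(2, 2.5)))
  expect_equal(z$a, c(-1, 1))
  expect_equal(unname(p$sd["a"]), 1)  # population (n-denominator) SD

  expect_error(fit_standardizer(data.frame(a = 1)), "2 rows")
  expect_warning(pc <- fit_standardizer(data.frame(a = c(1, 3), c = c(5, 5))),
                 "zero-variance")
  zc <- apply_standardizer(pc, data.frame(a = c(2, 9), c = c(5, 7)))
  expect_true(all(zc$c == 0))

  # applying train parameters to a row at the train mean gives zero
  expect_equal(as.numeric(apply_standardizer(p, data.frame(a = 2, b = 2.25))),
               c(0, 0))

  # standardize-then-invert round trip
  x <- data.frame(a = rnorm(20, 5, 3), b = runif(20, -2, 9))
  pz <- fit_standardizer(x)
  z2 <- apply_standardizer(pz, x)
  back <- sweep(sweep(as.matrix(z2), 2, pz$sd, "*"), 2, pz$mean, "+")
  expect_equal(unname(back), unname(as.matrix(x)), tolerance = 1e-9)
})

test_that("assembled policy features agree with an independent recomputation", {
  cohort <- small_cohort_fixture()[1:60]
  info <- classify_cohort(cohort)
  specs <- build_feature_specs()
  specs <- specs[specs$name %in% POLICY_FEATURES, ]
  for (i in which(info$class %in% c("VP_GT24", "NON_VP"))[1:30]) {
    e <- cohort[[i]]
    tf <- info$tf_h[i]
    fv <- assemble(e, tf, specs)$values
    obs <- e$observations
    upto <- obs$time_h <= tf + 1e-12
    sb <- obs$sbp[upto & !is.na(obs$sbp)]
    ref <- c(
      rr_expw = exp_weighted(obs$rr[upto & !is.na(obs$rr)]),
      fluids_hypo = fluids_while_hypotensive(e, tf),
      elapsed_time = tf,
      gcs_min = suppressWarnings(min(obs$gcs[upto], na.rm = TRUE)),
      spo2_min = suppressWarnings(min(obs$spo2[upto], na.rm = TRUE)),
      sbp_recent = sb[length(sb)]
    )
    expect_equal(fv[names(ref)], ref, tolerance = 1e-9)
  }
})
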