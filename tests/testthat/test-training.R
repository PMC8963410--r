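test_that("the cohort split is stratified, deterministic, and encounter-level", {
  mk <- function(id, treated) {
    make_encounter(id,
      observations = make_obs(c(0, 1, 2), sbp = c(85, 84, 83)),
      vasopressors = if (treated) vp_episode(2.5, 40) else NULL)
  }
  cohort <- c(lapply(1:10, function(i) mk(paste0("vp", i), TRUE)),
              lapply(1:10, function(i) mk(paste0("nv", i), FALSE)))
  sp <- split_cohort(cohort, 0.9, seed = 4)
  cls <- classify_cohort(sp$train)$class
  expect_identical(sum(cls == "VP_GT24"), 9L)
  expect_identical(sum(cls == "NON_VP"), 9L)
  expect_length(sp$test, 2L)
  ids_train <- vapply(sp$train, function(e) e$id, character(1))
  ids_test <- vapply(sp$test, function(e) e$id, character(1))
  expect_length(intersect(ids_train, ids_test), 0L)

  sp2 <- split_cohort(cohort, 0.9, seed = 4)
  expect_identical(vapply(sp2$train, function(e) e$id, character(1)), ids_train)

  expect_warning(split_cohort(cohort, 1.0, seed = 1), "empty test")
  expect_error(split_cohort(cohort[c(1, 11, 12)], 0.9, seed = 1), "fewer than 2")
})

test_that("the L1 screen keeps a planted signal and tolerates pure noise", {
  set.seed(31)
  n <- 400
  x <- as.data.frame(matrix(rnorm(n * 9), n, 9))
  names(x) <- paste0("f", 1:9)
  y <- rbinom(n, 1, plogis(2.5 * x$f1))
  out <- l1_screen(x, y, seed = 2)
  expect_true("f1" %in% out$features)
  expect_true(out$lambda > 0)

  # all-noise candidates: an empty survivor set is an acceptable outcome
  y0 <- rbinom(n, 1, 0.5)
  out0 <- l1_screen(x, y0, seed = 2)
  expect_true(is.character(out0$features))

  # degenerate one-point grid skips cross-validation
  out1 <- l1_screen(x, y, lambda = 0.05, seed = 2)
  expect_equal(out1$lambda, 0.05)
  expect_true(is.na(out1$cv_auc))

  expect_error(l1_screen(x, rep(1, n), seed = 1), "single class")
})

test_that("stepwise selection keeps the informative covariate and drops noise", {
  set.seed(77)
  n <- 500
  x <- data.frame(signal = rnorm(n), noise = rnorm(n))
  y <- rbinom(n, 1, plogis(1.8 * x$signal))
  expect_identical(forward_select(c("signal", "noise"), x, y), "signal")
  expect_identical(forward_select(character(0), x, y), character(0))
})

test_that("stepwise equals the exhaustive-subset oracle on small candidate sets", {
  set.seed(5150)
  for (rep in 1:12) {
    n <- 150
    k <- sample(2:5, 1)
    R <- matrix(rnorm(k * k, sd = 0.4), k, k); diag(R) <- 1
    x <- as.data.frame(matrix(rnorm(n * k), n, k) %*% R)
    names(x) <- paste0("v", seq_len(k))
    beta <- sample(c(0, 0, 0.8, 1.5), k, replace = TRUE)
    y <- rbinom(n, 1, plogis(as.matrix(x) %*% beta - mean(as.matrix(x) %*% beta)))
    got <- forward_select(names(x), x, y, alpha = 0.05)
    fam <- exhaustive_stable_family(names(x), x, y, alpha = 0.05)
    key <- paste(sort(got), collapse = "|")
    fam_keys <- vapply(fam, function(s) paste(sort(s), collapse = "|"), character(1))
    expect_true(key %in% fam_keys, label = sprintf("replicate %d (k=%d) admissible", rep, k))
    if (length(fam) == 1L) {
      expect_identical(sort(got), sort(fam[[1]]),
                       label = sprintf("replicate %d (k=%d)", rep, k))
    }
  }
})

test_that("final fit rescales odds ratios to natural increments", {
  set.seed(9)
  n <- 600
  sd_nat <- 5
  x_nat <- data.frame(f = rnorm(n, 50, sd_nat))
  y <- rbinom(n, 1, plogis(0.3 * (x_nat$f - 50)))
  std <- fit_standardizer(x_nat)
  z <- apply_standardizer(std, x_nat)
  specs <- data.frame(name = "f", signal = "f", transform = "static", increment = 5)
  m <- fit_final(z, y, "f", std, specs = specs)
  # beta_std * increment / SD reproduces the natural-unit log-odds ratio
  expect_equal(m$odds_ratios$odds_ratio,
               exp(m$coefficients[["f"]] * 5 / std$sd[["f"]]), tolerance = 1e-12)
  expect_equal(log(m$odds_ratios$odds_ratio) / 5, 0.3, tolerance = 0.1)
  expect_false(m$penalized)
  expect_error(fit_final(z, y, character(0), std), "empty feature")
})

test_that("perfect separation falls back to a penalized fit", {
  x <- data.frame(f = c(rnorm(30, -3), rnorm(30, 3)))
  y <- rep(c(0L, 1L), each = 30)
  std <- fit_standardizer(x)
  z <- apply_standardizer(std, x)
  specs <- data.frame(name = "f", signal = "f", transform = "static", increment = 1)
  m <- suppressWarnings(fit_final(z, y, "f", std, specs = specs))
  expect_true(m$penalized)
  expect_true(all(is.finite(unlist(m$odds_ratios[, c("odds_ratio", "ci_lo", "ci_hi")]))))
})

test_that("scoring is a logistic of the standardized linear predictor", {
  m <- toy_sbp_model()
  # linear predictor zero at the training mean
  expect_equal(score(m, c(sbp_recent = 85)), 0.5)
  expect_equal(score(m, c(sbp_recent = 80)), plogis(1))
  expect_error(score(m, c(other = 1)), "sbp_recent")

  # monotonicity: with a negative SBP weight, lowering SBP never lowers the score
  fx <- default_model_fixture()
  mod <- fx$model
  expect_true("sbp_recent" %in% mod$features)
  expect_lt(mod$coefficients[["sbp_recent"]], 0)
  set.seed(12)
  for (i in 1:20) {
    base <- sapply(mod$features, function(f) {
      rnorm(1, mod$standardizer$mean[[f]], mod$standardizer$sd[[f]])
    })
    lower <- base
    lower["sbp_recent"] <- lower[["sbp_recent"]] - runif(1, 0.5, 10)
    expect_gte(score(mod, lower), score(mod, base))
  }
})

test_that("scores are invariant to affine rescaling of an input feature", {
  set.seed(21)
  n <- 300
  x <- data.frame(a = rnorm(n, 10, 2), b = rnorm(n, -4, 7))
  y <- rbinom(n, 1, plogis(0.8 * scale(x$a) - 0.5 * scale(x$b)))
  specs <- data.frame(name = c("a", "b"), signal = c("a", "b"),
                      transform = "static", increment = 1)
  fit_and_score <- function(xx) {
    std <- fit_standardizer(xx)
    z <- apply_standardizer(std, xx)
    m <- fit_final(z, y, c("a", "b"), std, specs = specs)
    dynpract:::score_rows(m, xx)
  }
  s1 <- fit_and_score(x)
  x2 <- x; x2$a <- 1000 + 37 * x$a
  s2 <- fit_and_score(x2)
  expect_equal(s1, s2, tolerance = 1e-6)
})

test_that("the full pipeline recovers the direction of every policy effect", {
  fx <- default_model_fixture()
  or <- fx$model$odds_ratios
  up <- intersect(or$feature, c("rr_expw", "fluids_hypo"))
  down <- intersect(or$feature, c("elapsed_time", "gcs_min", "spo2_min", "sbp_recent"))
  expect_gte(length(c(up, down)), 4L)
  expect_true(all(or$odds_ratio[or$feature %in% up] > 1))
  expect_true(all(or$odds_ratio[or$feature %in% down] < 1))
  expect_true(all(or$p_value[or$feature %in% c(up, down)] < 0.05))
})
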