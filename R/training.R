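#' Split the development cohort into training and test sets
#'
#' Only the two model-development classes enter the split: encounters started
#' on ED vasopressors with course duration > 24 h (`VP_GT24`, the positive
#' class) and encounters never given vasopressors within the horizon
#' (`NON_VP`). The split is stratified by class at the encounter level and is
#' deterministic given the seed. Encounters without a valid decision time are
#' dropped beforehand.
#'
#' @param cohort list of encounters.
#' @param train_fraction fraction of each stratum assigned to training
#'   (default 0.9).
#' @param seed integer seed.
#' @return list with `train` and `test` (lists of encounters) and the
#'   matching `train_info` / `test_info` classification tables.
#' @export
split_cohort <- function(cohort, train_fraction = 0.9, seed = 1L) {
  info <- classify_cohort(cohort)
  keep <- info$class %in% c("VP_GT24", "NON_VP") & !is.na(info$tf_h)
  idx <- which(keep)
  train_idx <- integer(0)
  with_seed(child_seed(seed, "split"), {
    for (cl in c("VP_GT24", "NON_VP")) {
      stratum <- idx[info$class[idx] == cl]
      if (length(stratum) < 2L) {
        stop(sprintf("split_cohort: stratum %s has fewer than 2 encounters", cl))
      }
      n_tr <- round(train_fraction * length(stratum))
      train_idx <- c(train_idx, sample(stratum, n_tr))
    }
  })
  test_idx <- setdiff(idx, train_idx)
  if (!length(test_idx)) warning("split_cohort: empty test set (train_fraction too high)")
  list(
    train = cohort[sort(train_idx)], test = cohort[sort(test_idx)],
    train_info = info[sort(train_idx), , drop = FALSE],
    test_info = info[sort(test_idx), , drop = FALSE]
  )
}

#' Build the modeling table for a set of encounters at a timepoint index
#'
#' Assembles features at the k-th timepoint before each encounter's final
#' decision time (`k = 0` is the decision time itself); rows whose timepoint
#' does not resolve (insufficient history, or SBP at or above 90 mmHg there)
#' are excluded. Labels are 1 for `VP_GT24`, 0 for `NON_VP`.
#'
#' @param encounters list of encounters (development classes).
#' @param k timepoint index (0 = final decision time).
#' @param specs feature specifications.
#' @param medians frozen population medians (NULL to compute from these rows).
#' @return list with `x` (natural-unit feature data.frame), `y`, `ids`,
#'   `anchors`, `medians`, `provenance`.
#' @export
build_model_table <- function(encounters, k = 0, specs = build_feature_specs(),
                              medians = NULL) {
  info <- classify_cohort(encounters)
  anchors <- vapply(seq_along(encounters), function(i) {
    timepoint(encounters[[i]], info$tf_h[i], k)
  }, numeric(1))
  tab <- build_feature_table(encounters, anchors, specs, medians)
  keep_ids <- tab$ids
  y <- as.integer(info$class[match(keep_ids, info$id)] == "VP_GT24")
  list(x = tab$features, y = y, ids = keep_ids, anchors = tab$anchors,
       medians = tab$medians, provenance = tab$provenance)
}

#' L1-regularized screening of candidate covariates
#'
#' Fits an L1-penalized logistic model over a grid of regularization
#' strengths, picks the strength by 5-fold cross-validated ROC AUC (ties
#' resolved toward stronger regularization, i.e. sparser models), refits on
#' all rows at the chosen strength, and returns the covariates with non-zero
#' coefficients.
#'
#' @param x standardized feature matrix or data.frame.
#' @param y binary labels (1 = positive class).
#' @param lambda optional regularization grid; by default a 20-point
#'   log-spaced grid derived from the data.
#' @param nfolds number of cross-validation folds.
#' @param seed integer seed controlling fold assignment.
#' @return list with `features` (character, possibly empty), `lambda`
#'   (chosen strength), `cv_auc`.
#' @export
l1_screen <- function(x, y, lambda = NULL, nfolds = 5, seed = 1L) {
  x <- as.matrix(x)
  if (length(unique(y)) < 2L) stop("l1_screen: labels contain a single class")
  if (is.null(lambda)) {
    path <- glmnet::glmnet(x, y, family = "binomial", nlambda = 20,
                           standardize = FALSE)
    lambda <- path$lambda
  }
  if (length(lambda) == 1L) {
    chosen <- lambda
    cv_auc <- NA_real_
  } else {
    foldid <- with_seed(child_seed(seed, "l1folds"), {
      sample(rep_len(seq_len(nfolds), length(y)))
    })
    cv <- glmnet::cv.glmnet(x, y, family = "binomial", lambda = sort(lambda, decreasing = TRUE),
                            foldid = foldid, type.measure = "auc",
                            standardize = FALSE)
    best <- max(cv$cvm)
    chosen <- max(cv$lambda[cv$cvm >= best - 1e-12])
    cv_auc <- best
  }
  fit <- glmnet::glmnet(x, y, family = "binomial", lambda = chosen,
                        standardize = FALSE)
  beta <- as.matrix(stats::coef(fit))[-1, 1]
  list(features = names(beta)[beta != 0], lambda = chosen, cv_auc = cv_auc)
}

# Wald p-values of a fitted glm, excluding the intercept.
#' @keywords internal
wald_p <- function(fit) {
  sm <- summary(fit)$coefficients
  p <- sm[, 4]
  p[setdiff(rownames(sm), "(Intercept)")]
}

#' @keywords internal
fit_logit <- function(x, y, features) {
  df <- as.data.frame(x[, features, drop = FALSE])
  df$.y <- y
  suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
}

#' Stepwise forward selection with backward pruning
#'
#' Iteratively adds the candidate with the smallest Wald p-value when added
#' to the current model, while that p-value is below `alpha`; after forward
#' steps stall, any included covariate whose p-value in the joint model is at
#' or above `alpha` is removed, and the add/prune cycle repeats until stable.
#' Every covariate of the returned set is therefore significant in the final
#' joint fit.
#'
#' @param candidates character vector of candidate covariate names.
#' @param x standardized feature table containing the candidates.
#' @param y binary labels.
#' @param alpha significance level (default 0.05).
#' @return character vector of selected covariates (possibly empty).
#' @export
forward_select <- function(candidates, x, y, alpha = 0.05) {
  if (!length(candidates)) return(character(0))
  x <- as.data.frame(x)
  current <- character(0)
  seen <- character(0)
  for (iter in seq_len(10L * length(candidates) + 10L)) {
    changed <- FALSE
    # forward phase
    repeat {
      pool <- setdiff(candidates, current)
      if (!length(pool)) break
      p_add <- vapply(pool, function(f) {
        fit <- fit_logit(x, y, c(current, f))
        unname(wald_p(fit)[make.names(f)])
      }, numeric(1))
      if (all(is.na(p_add)) || min(p_add, na.rm = TRUE) >= alpha) break
      best <- pool[which.min(p_add)]
      current <- c(current, best)
      changed <- TRUE
    }
    # backward pruning phase
    repeat {
      if (!length(current)) break
      fit <- fit_logit(x, y, current)
      p_cur <- wald_p(fit)[make.names(current)]
      if (all(p_cur < alpha, na.rm = TRUE) && !anyNA(p_cur)) break
      worst <- current[which.max(ifelse(is.na(p_cur), Inf, p_cur))]
      current <- setdiff(current, worst)
      changed <- TRUE
    }
    key <- paste(sort(current), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  current
}

#' Fit the final usual-care logistic model
#'
#' Maximum-likelihood logistic fit on the standardized selected covariates.
#' Odds ratios are rescaled to each covariate's natural-unit increment:
#' `OR = exp(beta_std * increment / SD)`, with Wald 95% confidence intervals
#' rescaled identically. Under (quasi-)separation the fit falls back to a
#' tiny quadratic (ridge) penalty and the model is flagged `penalized`.
#'
#' @param x standardized training feature table.
#' @param y binary labels (1 = `VP_GT24`).
#' @param features selected covariate names (non-empty).
#' @param standardizer standardization parameters from [fit_standardizer()].
#' @param specs feature specifications (for natural-unit increments).
#' @param medians population medians used for imputation (stored for
#'   application to new data).
#' @param metadata list of training metadata to store (seed, split sizes,
#'   chosen regularization strength).
#' @return an object of class `ucv_model`.
#' @export
fit_final <- function(x, y, features, standardizer, specs = build_feature_specs(),
                      medians = NULL, metadata = list()) {
  if (!length(features)) stop("fit_final: empty feature set (no-model result)")
  x <- as.data.frame(x)
  fit <- fit_logit(x, y, features)
  cf <- stats::coef(fit)
  se <- summary(fit)$coefficients[, 2]
  penalized <- FALSE
  if (!fit$converged || any(abs(cf) > 15) || any(se > 10)) {
    ridge <- ridge_logit(as.matrix(x[, features, drop = FALSE]), y, penalty = 1e-4)
    cf <- ridge$coef
    se <- ridge$se
    names(cf) <- names(se) <- c("(Intercept)", make.names(features))
    penalized <- TRUE
  }
  beta <- cf[make.names(features)]
  sdev <- se[make.names(features)]
  names(beta) <- names(sdev) <- features
  inc <- specs$increment[match(features, specs$name)]
  sd_nat <- standardizer$sd[features]
  scale_f <- inc / ifelse(sd_nat > 0, sd_nat, 1)
  or <- data.frame(
    feature = features,
    increment = inc,
    odds_ratio = exp(beta * scale_f),
    ci_lo = exp((beta - 1.96 * sdev) * scale_f),
    ci_hi = exp((beta + 1.96 * sdev) * scale_f),
    beta_std = unname(beta),
    se_std = unname(sdev),
    p_value = 2 * stats::pnorm(-abs(beta / sdev)),
    row.names = NULL
  )
  structure(list(
    features = features,
    intercept = unname(cf[["(Intercept)"]]),
    coefficients = beta,
    standardizer = standardizer,
    specs = specs,
    odds_ratios = or,
    medians = medians,
    penalized = penalized,
    metadata = metadata
  ), class = "ucv_model")
}

# Logistic regression with a small quadratic penalty on the slopes
# (intercept unpenalized); Newton iterations on the penalized log-likelihood.
#' @keywords internal
ridge_logit <- function(X, y, penalty = 1e-4, max_iter = 100) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  pen <- diag(c(0, rep(penalty, p - 1L)))
  b <- rep(0, p)
  for (i in seq_len(max_iter)) {
    eta <- drop(X1 %*% b)
    mu <- logistic(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * w, X1) + pen
    g <- crossprod(X1, y - mu) - pen %*% b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  cov <- solve(H)
  list(coef = b, se = sqrt(diag(cov)))
}

#' @export
print.ucv_model <- function(x, ...) {
  cat(sprintf("<ucv_model> %d covariate(s)%s\n", length(x$features),
              if (x$penalized) " [penalized fit]" else ""))
  print(x$odds_ratios[, c("feature", "increment", "odds_ratio", "ci_lo", "ci_hi", "p_value")],
        digits = 3)
  invisible(x)
}

#' Score a feature vector with a usual-care model
#'
#' Standardizes the model covariates with the training parameters and returns
#' the logistic of the linear predictor: the estimated probability that the
#' observation is from a patient subsequently needing sustained (> 24 h)
#' vasopressors.
#'
#' @param model a `ucv_model`.
#' @param fv an assembled feature vector (from [assemble()]) or a named
#'   numeric vector in natural units.
#' @return probability in (0, 1).
#' @export
score <- function(model, fv) {
  if (is.list(fv) && !is.null(fv$values)) fv <- fv$values
  missing <- setdiff(model$features, names(fv))
  if (length(missing)) {
    stop(sprintf("score: missing feature(s): %s", paste(missing, collapse = ", ")))
  }
  z <- (fv[model$features] - model$standardizer$mean[model$features]) /
    ifelse(model$standardizer$sd[model$features] > 0,
           model$standardizer$sd[model$features], 1)
  unname(logistic(model$intercept + sum(model$coefficients * z)))
}

# Vectorized scoring of a natural-unit feature table.
#' @keywords internal
score_rows <- function(model, x) {
  x <- as.matrix(as.data.frame(x)[, model$features, drop = FALSE])
  z <- sweep(x, 2, model$standardizer$mean[model$features])
  z <- sweep(z, 2, ifelse(model$standardizer$sd[model$features] > 0,
                          model$standardizer$sd[model$features], 1), "/")
  drop(logistic(model$intercept + z %*% model$coefficients))
}

#' Train a usual-care model with the two-stage selection pipeline
#'
#' Runs the full development procedure on a set of training encounters:
#' feature assembly at the final decision time (with carry-forward and
#' population-median imputation), z-score standardization, L1-regularized
#' screening with cross-validated AUC, stepwise forward selection with
#' backward pruning, and the final maximum-likelihood logistic fit.
#'
#' @param train list of training encounters (development classes).
#' @param specs feature specifications.
#' @param alpha stepwise significance level.
#' @param nfolds folds for the L1 screen.
#' @param seed integer seed (fold assignment; recorded in metadata).
#' @param k timepoint index to train at (0 = final decision time).
#' @return a `ucv_model`, or `NULL` (with a warning) when no covariate
#'   survives selection.
#' @export
train_ucv <- function(train, specs = build_feature_specs(), alpha = 0.05,
                      nfolds = 5, seed = 1L, k = 0) {
  tab <- build_model_table(train, k = k, specs = specs)
  std <- fit_standardizer(tab$x)
  xz <- apply_standardizer(std, tab$x)
  screened <- l1_screen(xz, tab$y, nfolds = nfolds, seed = seed)
  selected <- forward_select(screened$features, xz, tab$y, alpha = alpha)
  if (!length(selected)) {
    warning("train_ucv: no covariate survived selection (no-model result)")
    return(NULL)
  }
  fit_final(
    xz, tab$y, selected, std, specs = specs, medians = tab$medians,
    metadata = list(
      seed = seed, n_train = length(tab$y), n_pos = sum(tab$y),
      lambda = screened$lambda, cv_auc = screened$cv_auc,
      alpha = alpha, k = k
    )
  )
}
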