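#' ROC curve summary with DeLong confidence interval
#'
#' AUC computed as the Mann-Whitney statistic (ties counted one half), with a
#' 95% confidence interval by DeLong's variance estimator.
#'
#' @param scores numeric scores (higher = more positive-like).
#' @param labels binary labels (1 = positive).
#' @return object of class `ucv_roc`: `scores`, `labels`, `auc`, `ci95`,
#'   `n_pos`, `n_neg`.
#' @export
roc_result <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("roc_result: both classes must be present")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0, 1), direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  structure(list(
    scores = as.numeric(scores), labels = labels,
    auc = as.numeric(pROC::auc(r)),
    ci95 = c(lower = min(ci[1], ci[2]), upper = max(ci[3], ci[2])),
    n_pos = sum(labels == 1L), n_neg = sum(labels == 0L),
    roc = r
  ), class = "ucv_roc")
}

#' @export
print.ucv_roc <- function(x, ...) {
  cat(sprintf("<ucv_roc> AUC %.3f (95%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, x$ci95[1], x$ci95[2], x$n_pos, x$n_neg))
  invisible(x)
}

#' Paired DeLong comparison of two ROC curves
#'
#' Two-tailed p-value for the AUC difference of two score vectors evaluated
#' on the same observations (same labels, paired scores).
#'
#' @param roc_a,roc_b `ucv_roc` objects from [roc_result()] on the same
#'   observations.
#' @return list with `auc_a`, `auc_b`, `difference`, `p_value`.
#' @export
delong_compare <- function(roc_a, roc_b) {
  if (length(roc_a$labels) != length(roc_b$labels) ||
      !all(roc_a$labels == roc_b$labels)) {
    stop("delong_compare: inputs must be paired (same observations and labels)")
  }
  if (isTRUE(all.equal(roc_a$scores, roc_b$scores, tolerance = 0))) {
    p <- 1
  } else {
    tst <- suppressWarnings(
      pROC::roc.test(roc_a$roc, roc_b$roc, method = "delong", paired = TRUE)
    )
    p <- tst$p.value
    if (!is.finite(p)) p <- 1
  }
  list(auc_a = roc_a$auc, auc_b = roc_b$auc,
       difference = roc_a$auc - roc_b$auc, p_value = p)
}

#' Leave-one-out cross-validated scores
#'
#' Scores every row with a logistic model using a frozen covariate set whose
#' coefficients are refit on all other rows; the pooled held-out scores yield
#' a single out-of-sample ROC. Deterministic (no randomness in LOOCV).
#'
#' @param x feature table (standardized or natural units; the covariate set
#'   is used as-is).
#' @param y binary labels with at least 3 per class.
#' @param features covariate names to use.
#' @return numeric vector of out-of-sample scores, one per row.
#' @export
loocv_scores <- function(x, y, features) {
  x <- as.matrix(as.data.frame(x)[, features, drop = FALSE])
  y <- as.integer(y)
  if (min(sum(y == 1L), sum(y == 0L)) < 3L) {
    stop("loocv_scores: need at least 3 observations per class")
  }
  X1 <- cbind(`(Intercept)` = 1, x)
  full <- suppressWarnings(stats::glm.fit(X1, y, family = stats::binomial()))
  start <- full$coefficients
  start[is.na(start)] <- 0
  n <- length(y)
  out <- numeric(n)
  for (i in seq_len(n)) {
    fit <- suppressWarnings(
      stats::glm.fit(X1[-i, , drop = FALSE], y[-i],
                     family = stats::binomial(), start = start)
    )
    b <- fit$coefficients
    b[is.na(b)] <- 0
    out[i] <- logistic(drop(X1[i, ] %*% b))
  }
  out
}

#' Temporal validation experiment
#'
#' For each timepoint index k before the final decision time, rebuilds the
#' modeling rows at that timepoint (rows whose timepoint does not resolve, or
#' has SBP at or above 90 mmHg, are excluded), trains an alternative model
#' with the full two-stage pipeline on those rows, and compares it with the
#' usual-care model on the same rows: the fixed model applied as-is, the
#' fixed covariate set refit under leave-one-out cross-validation, and the
#' alternative model's LOOCV AUC, with a paired DeLong test between the two
#' LOOCV score vectors.
#'
#' @param train list of development-class training encounters.
#' @param model the trained `ucv_model`.
#' @param k_values timepoint indices to evaluate (0 = decision time).
#' @param specs feature specifications.
#' @param alpha stepwise significance level for alternative models.
#' @param seed integer seed (fold assignment in alternative-model screens).
#' @param min_rows_per_class smallest class count for which a timepoint is
#'   evaluated; smaller timepoints are reported unavailable.
#' @return data.frame with one row per k: `k`, `n`, `auc_ucv_applied`,
#'   `auc_ucv_loocv`, `auc_alt_loocv`, `p_delong`, `available`.
#' @export
temporal_experiment <- function(train, model, k_values = 0:4,
                                specs = build_feature_specs(), alpha = 0.05,
                                seed = 1L, min_rows_per_class = 10L) {
  rows <- lapply(k_values, function(k) {
    tab <- tryCatch(build_model_table(train, k = k, specs = specs),
                    error = function(e) NULL)
    if (is.null(tab) || min(sum(tab$y == 1L), sum(tab$y == 0L)) < min_rows_per_class) {
      return(data.frame(k = k, n = if (is.null(tab)) 0L else length(tab$y),
                        auc_ucv_applied = NA_real_, auc_ucv_loocv = NA_real_,
                        auc_alt_loocv = NA_real_, p_delong = NA_real_,
                        available = FALSE))
    }
    std_k <- fit_standardizer(tab$x)
    xz <- suppressWarnings(apply_standardizer(std_k, tab$x))
    ucv_applied <- score_rows(model, tab$x)
    ucv_loocv <- loocv_scores(xz, tab$y, model$features)
    alt <- tryCatch(
      train_ucv(train, specs = specs, alpha = alpha, seed = seed, k = k),
      warning = function(w) NULL, error = function(e) NULL
    )
    if (is.null(alt)) {
      return(data.frame(k = k, n = length(tab$y),
                        auc_ucv_applied = fast_auc(ucv_applied, tab$y),
                        auc_ucv_loocv = fast_auc(ucv_loocv, tab$y),
                        auc_alt_loocv = NA_real_, p_delong = NA_real_,
                        available = TRUE))
    }
    alt_loocv <- loocv_scores(xz, tab$y, alt$features)
    cmp <- delong_compare(roc_result(ucv_loocv, tab$y), roc_result(alt_loocv, tab$y))
    data.frame(k = k, n = length(tab$y),
               auc_ucv_applied = fast_auc(ucv_applied, tab$y),
               auc_ucv_loocv = fast_auc(ucv_loocv, tab$y),
               auc_alt_loocv = fast_auc(alt_loocv, tab$y),
               p_delong = cmp$p_value, available = TRUE)
  })
  do.call(rbind, rows)
}
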