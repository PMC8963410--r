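#' Score one outcome group at the final decision time
#'
#' Computes the usual-care model score at each encounter's final decision
#' time for every encounter of the requested outcome class. Encounters
#' lacking a valid decision time are omitted (their count is reported via a
#' message).
#'
#' @param model a `ucv_model`.
#' @param cohort list of encounters.
#' @param group one of the five outcome classes.
#' @return object of class `ucv_scored_group`: `group`, `ids`, `scores`.
#' @export
score_group <- function(model, cohort, group) {
  stopifnot(group %in% OUTCOME_CLASSES)
  info <- classify_cohort(cohort)
  in_group <- info$class == group
  if (!any(in_group)) stop(sprintf("score_group: no encounter in group %s", group))
  # EXCLUDED_NO_TF encounters have already left the partition; within the
  # group a missing tf cannot occur, but guard for robustness.
  valid <- in_group & !is.na(info$tf_h)
  n_dropped <- sum(in_group) - sum(valid)
  if (n_dropped > 0) {
    message(sprintf("score_group: omitting %d encounter(s) without a valid decision time", n_dropped))
  }
  if (!any(valid)) stop(sprintf("score_group: no scorable encounter in group %s", group))
  specs <- model$specs[model$specs$name %in% model$features, , drop = FALSE]
  tab <- build_feature_table(cohort[valid], info$tf_h[valid], specs,
                             medians = model$medians)
  structure(list(
    group = group, ids = tab$ids, scores = score_rows(model, tab$features)
  ), class = "ucv_scored_group")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D is the maximum gap between the two empirical distribution functions;
#' the p-value is two-tailed.
#'
#' @param a,b numeric score samples (both non-empty).
#' @return list with `D` and `p_value`.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stop("ks_two_sample: empty sample")
  tst <- suppressWarnings(stats::ks.test(a, b))
  list(D = unname(tst$statistic), p_value = tst$p.value)
}

#' Gaussian kernel density estimate of a score distribution
#'
#' Used for visual comparison of score distributions; bandwidth by Scott's
#' rule unless given. The curve is evaluated on a support padded by three
#' bandwidths and integrates to 1 (within numerical quadrature error).
#'
#' @param scores numeric vector with at least 2 distinct values.
#' @param bw bandwidth, or `NULL` for Scott's rule.
#' @param n number of evaluation points.
#' @return data.frame with columns `x` and `density`.
#' @export
kde_density <- function(scores, bw = NULL, n = 512) {
  if (length(scores) < 2L) stop("kde_density: need at least 2 scores")
  if (is.null(bw)) bw <- stats::bw.nrd(scores)
  d <- stats::density(scores, bw = bw, n = n,
                      from = min(scores) - 3 * bw, to = max(scores) + 3 * bw)
  data.frame(x = d$x, density = d$y)
}

#' Compare score distributions between two outcome groups
#'
#' Scores both groups at the final decision time, runs the two-sample KS
#' test, and reports summary quantiles for each group (statistical
#' difference and clinical importance are judged separately).
#'
#' @param model a `ucv_model`.
#' @param cohort list of encounters.
#' @param group_a,group_b outcome classes to compare.
#' @return list with the two scored groups, `ks` (D and p-value), and
#'   `quantiles` (2.5/25/50/75/97.5 percent per group).
#' @export
compare_groups <- function(model, cohort, group_a, group_b) {
  ga <- score_group(model, cohort, group_a)
  gb <- score_group(model, cohort, group_b)
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  list(
    group_a = ga, group_b = gb,
    ks = ks_two_sample(ga$scores, gb$scores),
    quantiles = rbind(
      stats::setNames(stats::quantile(ga$scores, qs), paste0("q", qs * 100)),
      stats::setNames(stats::quantile(gb$scores, qs), paste0("q", qs * 100))
    )
  )
}
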