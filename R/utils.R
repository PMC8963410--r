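#' @keywords internal
logistic <- function(x) 1 / (1 + exp(-x))

#' Evaluate code under a temporary RNG state
#'
#' Runs `expr` with the global RNG seeded to `seed`, restoring the caller's
#' RNG state afterwards so package functions do not perturb user scripts.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a stream-specific child seed from a master seed; keeps independent
# stages (generation, splitting, folds) decoupled while fully seed-determined.
#' @keywords internal
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629L)
}

# Fast midrank AUC (Mann-Whitney with ties counted 1/2). Internal kernel used
# by cross-validation loops and threshold scans; the user-facing ROC surface
# with confidence intervals is roc_result().
#' @keywords internal
fast_auc <- function(scores, labels) {
  pos <- labels == 1L
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("fast_auc: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# data.frame constructor without the checking overhead of data.frame();
# columns must already be equal-length atomic vectors.
#' @keywords internal
fast_df <- function(...) {
  cols <- list(...)
  n <- if (length(cols)) length(cols[[1L]]) else 0L
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}
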