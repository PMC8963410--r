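# Independent oracles used by unit and acceptance tests. These deliberately
# avoid the package's computational paths.

# AUC by exhaustive pair counting (ties count one half).
brute_force_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# Paired permutation reference for the AUC difference of two score vectors:
# under exchangeability the model assignment of each observation's pair of
# scores can be swapped independently.
permutation_delong_oracle <- function(sa, sb, labels, n_shuffle = 10000, seed = 1) {
  obs <- abs(brute_force_auc(sa, labels) - brute_force_auc(sb, labels))
  n <- length(labels)
  hits <- 0
  set.seed(seed)
  for (i in seq_len(n_shuffle)) {
    swap <- runif(n) < 0.5
    a <- ifelse(swap, sb, sa)
    b <- ifelse(swap, sa, sb)
    d <- abs(fast_auc_oracle(a, labels) - fast_auc_oracle(b, labels))
    if (d >= obs - 1e-12) hits <- hits + 1
  }
  (hits + 1) / (n_shuffle + 1)
}

# midrank AUC for the permutation loop (rank arithmetic, not the package path)
fast_auc_oracle <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Exhaustive stepwise oracle: enumerate all subsets; a subset is stable when
# every member keeps Wald p < alpha in the joint fit and no non-member would
# enter with p < alpha. Correlated designs can admit several stable sets, in
# which case the add/prune rule does not determine a unique answer; the
# oracle therefore returns the whole stable family.
exhaustive_stable_family <- function(candidates, x, y, alpha = 0.05) {
  x <- as.data.frame(x)
  k <- length(candidates)
  wald <- function(features) {
    df <- x[, features, drop = FALSE]
    df$.y <- y
    fit <- suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    sm <- summary(fit)$coefficients
    p <- sm[setdiff(rownames(sm), "(Intercept)"), 4]
    names(p) <- setdiff(rownames(sm), "(Intercept)")
    list(p = p, ll = as.numeric(stats::logLik(fit)))
  }
  family <- list()
  for (mask in 0:(2^k - 1)) {
    members <- candidates[bitwAnd(mask, 2^(seq_len(k) - 1)) > 0]
    if (length(members)) {
      w <- wald(members)
      if (anyNA(w$p[make.names(members)]) || any(w$p[make.names(members)] >= alpha)) next
    }
    outside <- setdiff(candidates, members)
    enterable <- FALSE
    for (f in outside) {
      w2 <- wald(c(members, f))
      pf <- w2$p[make.names(f)]
      if (!is.na(pf) && pf < alpha) { enterable <- TRUE; break }
    }
    if (enterable) next
    family[[length(family) + 1L]] <- members
  }
  family
}

# Exhaustive operating-point scan: smallest candidate threshold achieving the
# required specificity on the negative scores.
threshold_scan_oracle <- function(neg_scores, target) {
  cand <- sort(unique(c(neg_scores, max(neg_scores) + 1e-9)))
  for (t in cand) {
    if (mean(neg_scores < t) >= target) return(t)
  }
  NA_real_
}
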