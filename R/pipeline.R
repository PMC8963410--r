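# FNV-1a hash of a string; embedded in every output so downstream artifacts
# can be traced to one configuration snapshot.
#' @keywords internal
config_digest <- function(x) {
  s <- if (is.character(x) && length(x) == 1L) x else yaml::as.yaml(x)
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Default pipeline run configuration
#'
#' @param out_dir output directory for run artifacts.
#' @param seed master seed for the whole run.
#' @param n_encounters cohort size when simulating.
#' @param cohort_path optional path to an existing JSON Lines cohort
#'   (otherwise a synthetic cohort is generated).
#' @param train_fraction training fraction of the development split.
#' @param specificity_target operating-point specificity.
#' @param horizon_h outcome-classification horizon in hours.
#' @param alpha stepwise significance level.
#' @param temporal logical; run the temporal validation experiment.
#' @return a named list (RunConfig).
#' @export
default_run_config <- function(out_dir = "ucv_run", seed = 1L,
                               n_encounters = 2000, cohort_path = NULL,
                               train_fraction = 0.9, specificity_target = 0.90,
                               horizon_h = 48, alpha = 0.05, temporal = FALSE) {
  list(out_dir = out_dir, seed = as.integer(seed),
       n_encounters = as.integer(n_encounters), cohort_path = cohort_path,
       train_fraction = train_fraction, specificity_target = specificity_target,
       horizon_h = horizon_h, alpha = alpha, temporal = temporal)
}

#' Run the full usual-care modeling pipeline
#'
#' Orchestrates simulate (or load), split, train, evaluate, compare, and
#' timing as one reproducible run. Every artifact embeds the configuration
#' digest; a rerun with the same configuration is identical for all
#' deterministic stages. Stage-level counts (rows built, exclusions by
#' reason) are logged via `message()`.
#'
#' @param cfg run configuration from [default_run_config()].
#' @return invisibly, a list with the cohort, split, model, evaluation,
#'   comparisons, timing report, and output paths.
#' @export
run_pipeline <- function(cfg = default_run_config()) {
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  # digest covers the scientific configuration, not filesystem paths
  digest <- config_digest(cfg[setdiff(names(cfg), c("out_dir", "cohort_path"))])
  stage <- function(name, expr) {
    tryCatch(expr, error = function(err) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(err)))
    })
  }

  cohort <- stage("simulate", {
    if (!is.null(cfg$cohort_path)) {
      read_cohort_jsonl(cfg$cohort_path)
    } else {
      gen <- default_generator_config(n_encounters = cfg$n_encounters, seed = cfg$seed)
      co <- generate_cohort(gen)
      write_cohort_jsonl(co, file.path(cfg$out_dir, "cohort.jsonl"))
      yaml::write_yaml(list(config_digest = digest, generator = unclass(gen)),
                       file.path(cfg$out_dir, "generator_config.yaml"))
      co
    }
  })
  info <- classify_cohort(cohort, horizon_h = cfg$horizon_h)
  message(sprintf("pipeline: %d encounters; class counts: %s",
                  length(cohort),
                  paste(sprintf("%s=%d", names(table(info$class)), table(info$class)),
                        collapse = ", ")))

  split <- stage("split", split_cohort(cohort, cfg$train_fraction, seed = cfg$seed))
  model <- stage("train", train_ucv(split$train, alpha = cfg$alpha, seed = cfg$seed))
  if (is.null(model)) stop("pipeline stage 'train' failed: no-model result")
  model$metadata$config_digest <- digest
  write_ucv_model(model, file.path(cfg$out_dir, "model.json"))

  evaluation <- stage("evaluate", {
    tab_tr <- build_model_table(split$train, k = 0)
    std <- model$standardizer
    xz <- apply_standardizer(std, tab_tr$x)
    loo <- loocv_scores(xz, tab_tr$y, model$features)
    roc_tr <- roc_result(loo, tab_tr$y)
    res <- list(config_digest = digest,
                train_loocv = list(auc = roc_tr$auc, ci95 = unname(roc_tr$ci95),
                                   n = length(tab_tr$y)))
    if (length(split$test)) {
      tab_te <- build_model_table(split$test, k = 0, medians = model$medians)
      if (length(unique(tab_te$y)) == 2L) {
        roc_te <- roc_result(score_rows(model, tab_te$x), tab_te$y)
        res$test <- list(auc = roc_te$auc, ci95 = unname(roc_te$ci95),
                         n = length(tab_te$y))
      }
    } else {
      warning("pipeline: empty test set; held-out AUC skipped")
    }
    if (isTRUE(cfg$temporal)) {
      res$temporal <- temporal_experiment(split$train, model, seed = cfg$seed)
    }
    res
  })
  jsonlite::write_json(evaluation, file.path(cfg$out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  comparisons <- stage("compare", {
    cmp <- list(config_digest = digest)
    for (pair in list(c("VP_GT24", "VP_LT8"), c("VP_GT24", "VP_8_24"),
                      c("NON_VP", "VP_ICU"))) {
      key <- paste(pair, collapse = "_vs_")
      res <- tryCatch(compare_groups(model, cohort, pair[1], pair[2]),
                      error = function(e) NULL)
      if (!is.null(res)) {
        cmp[[key]] <- list(D = res$ks$D, p_value = res$ks$p_value,
                           quantiles = res$quantiles,
                           n = c(length(res$group_a$scores), length(res$group_b$scores)))
      }
    }
    cmp
  })
  jsonlite::write_json(comparisons, file.path(cfg$out_dir, "compare.json"),
                       auto_unbox = TRUE, digits = NA, na = "null")

  timing <- stage("timing", {
    op <- select_threshold(model, cohort, cfg$specificity_target)
    rep <- timing_report(model, cohort, op$threshold, horizon_h = cfg$horizon_h)
    rep$operating_point <- op
    rep$config_digest <- digest
    rep
  })
  utils::write.csv(timing$per_encounter,
                   file.path(cfg$out_dir, "timing_per_encounter.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    timing[c("config_digest", "threshold", "sensitivity", "ppv", "ppv_development")],
    file.path(cfg$out_dir, "timing.json"), auto_unbox = TRUE, digits = NA, na = "null")

  invisible(list(cohort = cohort, split = split, model = model,
                 evaluation = evaluation, comparisons = comparisons,
                 timing = timing, out_dir = cfg$out_dir,
                 config_digest = digest))
}
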