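#' Serialize and restore a usual-care model as JSON
#'
#' Writes the selected covariates, intercept, standardized coefficients,
#' standardizer, natural-unit odds-ratio table, population medians, and
#' training metadata to a single JSON document; `read_ucv_model()` restores
#' a scoring-equivalent model object.
#'
#' @param model a `ucv_model`.
#' @param path file path.
#' @return `write_ucv_model()` returns `path` invisibly; `read_ucv_model()`
#'   returns a `ucv_model`.
#' @export
write_ucv_model <- function(model, path) {
  doc <- list(
    features = model$features,
    intercept = model$intercept,
    coefficients = as.list(model$coefficients),
    standardizer = list(
      mean = as.list(model$standardizer$mean),
      sd = as.list(model$standardizer$sd),
      degenerate = as.list(model$standardizer$degenerate)
    ),
    specs = model$specs,
    odds_ratios = model$odds_ratios,
    medians = as.list(model$medians),
    penalized = model$penalized,
    metadata = model$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_ucv_model
#' @export
read_ucv_model <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  structure(list(
    features = doc$features,
    intercept = doc$intercept,
    coefficients = unlist(doc$coefficients),
    standardizer = list(
      mean = unlist(doc$standardizer$mean),
      sd = unlist(doc$standardizer$sd),
      degenerate = unlist(doc$standardizer$degenerate)
    ),
    specs = as.data.frame(doc$specs),
    odds_ratios = as.data.frame(doc$odds_ratios),
    medians = unlist(doc$medians),
    penalized = isTRUE(doc$penalized),
    metadata = doc$metadata
  ), class = "ucv_model")
}
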