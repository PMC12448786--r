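#' Validated run configuration
#'
#' Central knobs of the pipeline with their defaults: chunking (500-character
#' chunks, 100-character overlap), retrieval depth (top 10 per strategy,
#' keyword cap 50), fusion weights (5, 3, 1), generation (5 relevant chunks
#' sought, examination budget 30), mock embedding dimension and the run seed.
#'
#' @param chunk_size,overlap Chunking parameters (characters).
#' @param k_per_strategy Retrieval depth per embedding strategy.
#' @param keyword_cap Maximum keyword-strategy hits.
#' @param weights An [aggregator_weights()] list.
#' @param target Relevant chunks sought by the relevance check.
#' @param max_examined Relevance-check examination budget.
#' @param dimension Mock embedding dimension.
#' @param backend Backend selection tag (`"mock"`).
#' @param seed Integer seed recorded with every run.
#' @return A validated `run_config` list.
#' @export
run_config <- function(chunk_size = 500, overlap = 100, k_per_strategy = 10,
                       keyword_cap = 50, weights = aggregator_weights(),
                       target = 5, max_examined = 30, dimension = 256,
                       backend = "mock", seed = 1L) {
  if (!(overlap >= 0 && overlap < chunk_size)) {
    stop("run_config: need 0 <= overlap < chunk_size")
  }
  stopifnot(k_per_strategy >= 1, keyword_cap >= 1, target >= 1,
            max_examined >= target, dimension >= 1)
  structure(
    list(chunk_size = chunk_size, overlap = overlap,
         k_per_strategy = k_per_strategy, keyword_cap = keyword_cap,
         weights = weights, target = target, max_examined = max_examined,
         dimension = dimension, backend = backend, seed = as.integer(seed)),
    class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys must be [run_config()] arguments (weights given as a
#' mapping `w_S`/`w_M`/`w_R`); unknown keys are rejected.
#'
#' @param path YAML file.
#' @param overrides Named list applied over the file values
#'   (flags > file > defaults).
#' @export
read_run_config <- function(path = NULL, overrides = list()) {
  vals <- if (!is.null(path)) yaml::read_yaml(path) else list()
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (!is.null(vals$weights)) {
    vals$weights <- do.call(aggregator_weights, as.list(vals$weights))
  }
  do.call(run_config, vals)
}

#' Write the resolved configuration snapshot of a run
#'
#' @param config A [run_config()].
#' @param path Output YAML file.
#' @export
write_run_config <- function(config, path) {
  vals <- unclass(config)
  yaml::write_yaml(vals, path)
  invisible(path)
}
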