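cohort_schema <- c("gender", "race", "age_y", "height_cm", "weight_kg",
                   "fvc_L", "fev1_L", "pef_Ls", "fef25_Ls", "fef50_Ls",
                   "fef75_Ls")

#' Read and write cohort tables
#'
#' Cohort CSVs carry one spirometry test per row with unit-suffixed column
#' names fixed at the schema level (years, cm, kg, L, L/s); files with
#' missing or unit-mismatched columns are rejected with the offending names
#' rather than silently converted. `fev_pef_L`, `aex` and `cohort` columns
#' are optional.
#'
#' @param path CSV file path.
#' @return `read_cohort()`: a tibble. `write_cohort()`: `path`, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort file not found: %s", path))
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  assert_columns(d, cohort_schema, sprintf("cohort file '%s'", path))
  num <- setdiff(cohort_schema, c("gender", "race"))
  for (cn in num) {
    if (!is.numeric(d[[cn]])) {
      abort(sprintf("cohort file '%s': column %s must be numeric", path, cn))
    }
  }
  bad_g <- setdiff(unique(d$gender), c("female", "male"))
  if (length(bad_g)) {
    abort(sprintf("cohort file '%s': unknown gender value '%s'", path, bad_g[1]))
  }
  bad_r <- setdiff(unique(d$race), c("white", "black"))
  if (length(bad_r)) {
    abort(sprintf("cohort file '%s': unknown race value '%s'", path, bad_r[1]))
  }
  tibble::as_tibble(d)
}

#' @rdname read_cohort
#' @param data Cohort table to write.
#' @export
write_cohort <- function(data, path) {
  assert_columns(data, cohort_schema, "cohort table")
  utils::write.csv(data, path, row.names = FALSE)
  invisible(path)
}

#' Read a sampled flow-volume trace
#'
#' Two-column CSV (`volume_L`, `flow_L_s`), header required.
#'
#' @param path CSV file path.
#' @return A tibble of class `aex_fv_curve`.
#' @export
read_flow_volume <- function(path) {
  if (!file.exists(path)) abort(sprintf("trace file not found: %s", path))
  d <- utils::read.csv(path)
  assert_columns(d, c("volume_L", "flow_L_s"), sprintf("trace '%s'", path))
  out <- tibble::as_tibble(d[c("volume_L", "flow_L_s")])
  class(out) <- c("aex_fv_curve", class(out))
  out
}

#' Serialize a fitted ANN model to JSON
#'
#' Stores architecture, input encoders, weights, outcome scaling, stratum
#' stats (for z-score models) and the training seed at full double precision,
#' so a reloaded model reproduces predictions bit-for-bit.
#'
#' @param model An `aex_ann`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (!inherits(model, "aex_ann")) abort("`model` must be an aex_ann")
  payload <- list(
    type = "aex_ann",
    package_version = as.character(utils::packageVersion("aexref")),
    architecture = lapply(model$architecture, as.integer),
    weights = lapply(model$weights, function(m) {
      list(dim = dim(m), data = as.numeric(m))
    }),
    encoder = model$encoder,
    predictors = model$predictors,
    outcome = model$outcome,
    output = model$output,
    stratum_stats = if (!is.null(model$stratum_stats))
      as.data.frame(model$stratum_stats),
    y_center = model$y_center, y_scale = model$y_scale,
    lambda = model$lambda, loss = model$loss, delta = model$delta,
    transform_inputs = model$transform_inputs,
    seed = model$seed, converged = model$converged
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) abort(sprintf("model file not found: %s", path))
  p <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = TRUE)
  if (!identical(p$type, "aex_ann")) abort("not an aex_ann model file")
  arch_layers <- if (is.matrix(p$architecture)) {
    lapply(seq_len(nrow(p$architecture)), function(i) p$architecture[i, ])
  } else {
    lapply(p$architecture, as.integer)
  }
  arch <- do.call(ann_architecture, unname(arch_layers))
  weights <- lapply(p$weights, function(w) matrix(w$data, w$dim[1], w$dim[2]))
  encoder <- lapply(p$encoder, function(e) {
    if (!is.null(e$rank_map)) e$rank_map <- lapply(e$rank_map, as.numeric)
    e
  })
  stats_tab <- if (!is.null(p$stratum_stats)) {
    st <- tibble::as_tibble(p$stratum_stats)
    class(st) <- c("aex_stratum_stats", class(st))
    st
  }
  structure(
    list(architecture = arch, weights = weights,
         shapes = ann_shapes(nrow(weights$W1), arch),
         encoder = encoder, predictors = p$predictors, outcome = p$outcome,
         output = p$output, stratum_stats = stats_tab,
         y_center = p$y_center, y_scale = p$y_scale, lambda = p$lambda,
         loss = p$loss, delta = p$delta %||% NA_real_,
         transform_inputs = isTRUE(p$transform_inputs), seed = p$seed,
         converged = isTRUE(p$converged),
         metrics = tibble::tibble(rase = NA_real_, r2 = NA_real_)),
    class = "aex_ann"
  )
}

#' Write a run manifest
#'
#' Records inputs, seeds, package version and summary metrics of a pipeline
#' run as JSON next to its outputs.
#'
#' @param path Output path.
#' @param inputs Named list or character vector of input descriptions.
#' @param seed The run seed.
#' @param summaries Named list of summary values.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, inputs, seed, summaries = list()) {
  payload <- list(
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    package = "aexref",
    package_version = as.character(utils::packageVersion("aexref")),
    seed = seed, inputs = inputs, summaries = summaries
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}
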