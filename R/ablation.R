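#' Ablation grid over ANN configurations
#'
#' Trains every configuration in `grid` on the same partition and seed and
#' reports the familiar comparison table: one row per configuration with
#' layer counts, node mix, and R^2 / RMSE / RASE / AAE on the train, test
#' and validation slices. A standard least-squares row (stratified linear
#' model) can be included as the baseline.
#'
#' @param data Cohort table.
#' @param partition A factor from [make_partition()] (or a `.set` column
#'   name); must contain a non-empty train slice.
#' @param grid A list of configurations; each element is a list with fields
#'   `label` (optional), `architecture` (an [ann_architecture()] or list of
#'   layer vectors), and optionally `lambda`, `loss`, `transform_inputs`,
#'   `boost` (logical), `n_models`, `learning_rate`, `max_iter`.
#' @param outcome,predictors Passed to the model fitters.
#' @param include_linear Include the stratified OLS baseline row.
#' @param strata Strata for the baseline linear model.
#' @param seed Seed shared by all configurations.
#' @param max_iter Default BFGS cap for configurations that do not set one.
#' @return A tibble with one row per configuration.
#' @export
run_ablation <- function(data, partition, grid, outcome = "aex",
                         predictors = c("gender", "race", "age_y",
                                        "height_cm", "weight_kg"),
                         include_linear = TRUE,
                         strata = c("gender", "race"), seed = 1L,
                         max_iter = 1000) {
  if (!length(grid)) abort("`grid` must contain at least one configuration")
  if (is.character(partition) && length(partition) == 1) {
    partition <- data[[partition]]
  }
  if (length(partition) != nrow(data)) {
    abort("`partition` must label every row of `data`")
  }
  sets <- intersect(c("train", "test", "validation"),
                    unique(as.character(partition)))
  train <- data[partition == "train", , drop = FALSE]
  if (!nrow(train)) abort("partition has an empty train slice")

  slice_metrics <- function(predict_fun, model_df) {
    out <- list()
    for (s in sets) {
      d <- data[partition == s, , drop = FALSE]
      p <- predict_fun(d)
      m <- eval_metrics(observed = d[[outcome]], predicted = p,
                        model_df = min(model_df, nrow(d) - 1))
      out[[paste0("r2_", s)]] <- m$r2
      out[[paste0("rmse_", s)]] <- m$rmse
      out[[paste0("rase_", s)]] <- m$rase
      out[[paste0("aae_", s)]] <- m$aae
    }
    tibble::as_tibble(out)
  }

  rows <- list()
  if (include_linear) {
    fit0 <- fit_stratified_linear(train, outcome = outcome,
                                  predictors = intersect(
                                    predictors,
                                    names(dplyr::select_if(train, is.numeric))),
                                  strata = strata)
    df0 <- sum(vapply(fit0$fits,
                      function(f) length(coef(f$fit)), numeric(1)))
    rows[["linear"]] <- dplyr::bind_cols(
      tibble::tibble(model = "linear regression", layers = 0L,
                     nodes = NA_character_, boosted = FALSE,
                     time_s = NA_real_),
      slice_metrics(function(d) predict(fit0, d), df0)
    )
  }

  for (i in seq_along(grid)) {
    cfg <- grid[[i]]
    arch <- cfg$architecture
    if (!inherits(arch, "aex_ann_arch")) arch <- do.call(ann_architecture, arch)
    label <- cfg$label %||%
      paste(vapply(arch, function(l) sprintf("%ds%dl%dg", l[1], l[2], l[3]),
                   ""), collapse = "-")
    t0 <- proc.time()[["elapsed"]]
    if (isTRUE(cfg$boost)) {
      fit <- train_boosted(train, outcome = outcome, predictors = predictors,
                           architecture = arch,
                           n_models = cfg$n_models %||% 100,
                           learning_rate = cfg$learning_rate %||% 0.1,
                           lambda = cfg$lambda %||% 1e-3, seed = seed,
                           max_iter = cfg$max_iter %||% 200)
      model_df <- length(fit$components) *
        sum(vapply(fit$components[[1]]$shapes, prod, numeric(1)))
    } else {
      fit <- train_ann(train, outcome = outcome, predictors = predictors,
                       architecture = arch, lambda = cfg$lambda %||% 1e-3,
                       loss = cfg$loss %||% "squared",
                       transform_inputs = isTRUE(cfg$transform_inputs),
                       seed = seed, max_iter = cfg$max_iter %||% max_iter)
      model_df <- sum(vapply(fit$shapes, prod, numeric(1)))
    }
    elapsed <- proc.time()[["elapsed"]] - t0
    rows[[label]] <- dplyr::bind_cols(
      tibble::tibble(model = paste("ANN", label), layers = length(arch),
                     nodes = label, boosted = isTRUE(cfg$boost),
                     time_s = elapsed),
      slice_metrics(function(d) predict(fit, d), model_df)
    )
  }
  dplyr::bind_rows(rows)
}
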