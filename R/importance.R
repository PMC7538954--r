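#' Variance-based total-effect input importance with dependent inputs
#'
#' Estimates each input's total-effect share of the model-output variance on
#' a paired resampling design that respects input dependence: for a resampled
#' subject, the probed factor's value is replaced by the value observed in
#' one of the k nearest neighbours of the subject's *complementary* factor
#' vector among the observed rows (k = 5 by default), so substitutes are
#' drawn approximately from the conditional distribution given the other,
#' possibly correlated, factors. The total effect of factor i is the Jansen
#' estimator `E[(y - y_i')^2] / 2` of `E[Var(y | x_{-i})]`; shares are
#' normalized to sum to 100.
#'
#' Distances are Euclidean on standardized continuous factors; a categorical
#' mismatch adds a fixed penalty (`cat_penalty`, default 1.0 standardized
#' unit) per factor.
#'
#' @param model A fitted model with a `predict(model, newdata)` method (e.g.
#'   [train_ann()] output), or a function `f(newdata) -> numeric`.
#' @param data Cohort table of observed input combinations (>= 50 rows).
#' @param predictors Input columns; defaults to the model's predictors.
#' @param k Number of nearest neighbours (default 5).
#' @param n_resamples Paired resamples per factor (default 1000).
#' @param cat_penalty Distance added per mismatching categorical factor.
#' @param seed Integer seed.
#' @return A tibble of class `aex_importance`: `factor`, `total_effect`
#'   (share, %), with attributes `k`, `n_resamples`, `seed`.
#' @export
total_effects <- function(model, data, predictors = NULL, k = 5,
                          n_resamples = 1000, cat_penalty = 1.0, seed = 1L) {
  if (is.null(predictors)) {
    predictors <- if (is.function(model)) {
      abort("`predictors` must be given when `model` is a bare function")
    } else {
      model$predictors
    }
  }
  assert_columns(data, predictors, "cohort table")
  n <- nrow(data)
  if (n < 50) abort("need at least 50 observed rows")
  if (k < 1 || k > n) abort("`k` must be between 1 and nrow(data)")
  f <- if (is.function(model)) model else function(d) predict(model, d)
  data <- tibble::as_tibble(data)

  # standardized columns for the distance
  std <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      (v - mean(v)) / if (s > 0) s else 1
    } else {
      as.character(v)
    }
  })
  names(std) <- predictors
  is_num <- vapply(std, is.numeric, logical(1))

  with_seed(seed, {
    rows <- sample.int(n, n_resamples, replace = TRUE)
    base <- data[rows, , drop = FALSE]
    y0 <- f(base)
    raw <- numeric(length(predictors))
    for (ii in seq_along(predictors)) {
      others <- predictors[-ii]
      d2 <- matrix(0, n_resamples, n)
      for (p in others) {
        if (is_num[[p]]) {
          d2 <- d2 + outer(std[[p]][rows], std[[p]], `-`)^2
        } else {
          d2 <- d2 + cat_penalty^2 *
            outer(std[[p]][rows], std[[p]], `!=`)
        }
      }
      # draw uniformly among the k nearest observed complementary vectors
      sub_rows <- integer(n_resamples)
      pick <- sample.int(k, n_resamples, replace = TRUE)
      for (j in seq_len(n_resamples)) {
        nb <- order(d2[j, ])[seq_len(k)]
        sub_rows[j] <- nb[pick[j]]
      }
      probe <- base
      probe[[predictors[ii]]] <- data[[predictors[ii]]][sub_rows]
      y1 <- f(probe)
      raw[ii] <- mean((y0 - y1)^2) / 2
    }
    total <- sum(raw)
    if (total <= 0) abort("model output is constant over the resampling design")
    out <- tibble::tibble(factor = predictors,
                          total_effect = 100 * raw / total)
    attr(out, "k") <- k
    attr(out, "n_resamples") <- n_resamples
    attr(out, "seed") <- seed
    class(out) <- c("aex_importance", class(out))
    out
  })
}
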