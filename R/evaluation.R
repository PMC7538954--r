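#' Root average squared error and average absolute error
#'
#' `rase()` is the square root of the sum of squared residuals divided by n
#' (no degrees-of-freedom correction); `aae()` is the mean absolute residual.
#' The power-mean inequality guarantees `aae(r) <= rase(r) <= max(abs(r))`.
#'
#' @param residuals Numeric vector of residuals (predicted - observed).
#' @return A single non-negative number.
#' @examples
#' rase(c(3, -4))  # sqrt(12.5)
#' @export
rase <- function(residuals) {
  if (length(residuals) < 1) abort("`residuals` must be non-empty")
  if (any(!is.finite(residuals))) abort("`residuals` must be finite")
  sqrt(mean(residuals^2))
}

#' @rdname rase
#' @export
aae <- function(residuals) {
  if (length(residuals) < 1) abort("`residuals` must be non-empty")
  if (any(!is.finite(residuals))) abort("`residuals` must be finite")
  mean(abs(residuals))
}

#' Model-comparison metrics for paired observed/predicted values
#'
#' Computes the residual summary used to compare reference models: mean
#' difference (predicted - observed) with a 95% CI, RMSE (root of the sum of
#' squared residuals over `n - model_df`), RASE (over `n`), AAE, R^2, and
#' optionally the small-sample-corrected AICc under a gaussian likelihood.
#' Because prediction residuals are often non-normal, the CI can instead be
#' obtained by a seeded nonparametric bootstrap of the residual mean.
#'
#' @param data Optional data frame holding the two columns; if supplied,
#'   `observed`/`predicted` are interpreted as its column names.
#' @param observed,predicted Numeric vectors (or column names).
#' @param model_df Fitted-parameter count used in the RMSE denominator and
#'   AICc; 0 makes RMSE equal RASE.
#' @param aicc If `TRUE`, include gaussian AICc.
#' @param ci `"t"` (Student-t interval) or `"bootstrap"`.
#' @param n_boot,seed Bootstrap resamples and seed (used when
#'   `ci = "bootstrap"`).
#' @return A one-row tibble: `n`, `mean_diff`, `ci_low`, `ci_high`, `rmse`,
#'   `rase`, `aae`, `r2`, `aicc`.
#' @examples
#' eval_metrics(observed = c(1, 2, 3), predicted = c(2, 2, 2))
#' @export
eval_metrics <- function(data = NULL, observed, predicted, model_df = 0,
                         aicc = FALSE, ci = c("t", "bootstrap"),
                         n_boot = 2000, seed = 1L) {
  ci <- match.arg(ci)
  if (!is.null(data)) {
    observed <- data[[observed]]
    predicted <- data[[predicted]]
  }
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length")
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    abort("observed/predicted values must be finite")
  }
  n <- length(observed)
  if (n < 2) abort("need at least 2 pairs")
  assert_number(model_df, "model_df", lower = 0)
  if (model_df >= n) abort("`model_df` must be smaller than n")
  r <- predicted - observed
  md <- mean(r)
  if (ci == "t") {
    se <- stats::sd(r) / sqrt(n)
    tq <- stats::qt(0.975, n - 1)
    lo <- md - tq * se
    hi <- md + tq * se
  } else {
    means <- with_seed(seed, {
      vapply(seq_len(n_boot),
             function(i) mean(r[sample.int(n, replace = TRUE)]), numeric(1))
    })
    qs <- stats::quantile(means, c(0.025, 0.975), names = FALSE)
    lo <- qs[1]; hi <- qs[2]
  }
  ss <- sum(r^2)
  sst <- sum((observed - mean(observed))^2)
  aicc_val <- if (aicc) {
    k <- model_df + 1  # + residual variance
    n * log(ss / n) + 2 * k + 2 * k * (k + 1) / max(n - k - 1, 1)
  } else {
    NA_real_
  }
  tibble::tibble(
    n = n, mean_diff = md, ci_low = lo, ci_high = hi,
    rmse = sqrt(ss / (n - model_df)), rase = sqrt(ss / n), aae = mean(abs(r)),
    r2 = 1 - ss / sst, aicc = aicc_val
  )
}

#' Heteroscedasticity check on prediction residuals
#'
#' Flags residual spread that grows with the predicted value: a one-sided
#' Spearman rank correlation between |residual| and the prediction,
#' heteroscedastic when the correlation is positive with p < 0.05. This is
#' the residuals-not-progressively-larger-at-higher-values criterion used
#' when validating reference models.
#'
#' @param observed,predicted Numeric vectors (n >= 20).
#' @param alpha Significance level (default 0.05).
#' @return A one-row tibble: `statistic` (Spearman rho), `p_value`,
#'   `heteroscedastic` flag, and a `note`.
#' @export
homoscedasticity_check <- function(observed, predicted, alpha = 0.05) {
  if (length(observed) != length(predicted)) {
    abort("`observed` and `predicted` must have equal length")
  }
  if (length(observed) < 20) abort("need at least 20 pairs")
  r <- abs(predicted - observed)
  if (stats::sd(predicted) == 0 || stats::sd(r) == 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          heteroscedastic = FALSE,
                          note = "constant predictions or residuals"))
  }
  ct <- suppressWarnings(
    stats::cor.test(r, predicted, method = "spearman",
                    alternative = "greater", exact = FALSE)
  )
  tibble::tibble(
    statistic = unname(ct$estimate),
    p_value = ct$p.value,
    heteroscedastic = unname(ct$estimate) > 0 && ct$p.value < alpha,
    note = NA_character_
  )
}
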