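#' Per-stratum reference moments for z-scores
#'
#' Computes the sample mean and SD (n - 1 denominator) of a measurement
#' within each gender-by-race stratum. These moments define the stratified
#' z-score `(x - mean) / sd` and hence the lower limit of normal.
#'
#' @param data Cohort table.
#' @param value Name of the measurement column (default `"aex"`).
#' @param strata Character vector of stratifying columns.
#' @return A tibble of class `aex_stratum_stats` with the strata columns plus
#'   `mean`, `sd`, `n`.
#' @examples
#' d <- data.frame(gender = "female", race = "white", aex = c(2, 4))
#' fit_stratum_stats(d)  # mean 3, sd sqrt(2)
#' @export
fit_stratum_stats <- function(data, value = "aex",
                              strata = c("gender", "race")) {
  assert_columns(data, c(value, strata), "cohort table")
  out <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      n = dplyr::n(),
      .groups = "drop"
    )
  small <- out$n < 2
  if (any(small)) {
    lab <- apply(out[small, strata, drop = FALSE], 1, paste, collapse = "/")
    abort(sprintf("stratum with fewer than 2 subjects: %s",
                  paste(lab, collapse = "; ")))
  }
  class(out) <- c("aex_stratum_stats", class(out))
  out
}

#' Stratified z-score
#'
#' `z_score()` standardizes a measurement against one stratum's reference
#' moments: `(x - mean) / sd`. `add_z_scores()` joins an
#' [fit_stratum_stats()] table onto a cohort and appends a `z` column (and an
#' LLN flag).
#'
#' @param x Numeric measurement(s) (L^2/s for AEX).
#' @param stats A one-row `aex_stratum_stats` (or any list with `mean`, `sd`).
#' @return `z_score()`: numeric z. `add_z_scores()`: the cohort with columns
#'   `z` and `below_lln`.
#' @export
z_score <- function(x, stats) {
  m <- stats$mean
  s <- stats$sd
  if (length(m) != 1 || length(s) != 1 || !is.finite(s) || s <= 0) {
    abort("`stats` must supply a single stratum with sd > 0")
  }
  (x - m) / s
}

#' @rdname z_score
#' @param data Cohort table with the strata columns.
#' @param stats A full `aex_stratum_stats` table.
#' @param value Measurement column to standardize.
#' @export
add_z_scores <- function(data, stats, value = "aex") {
  strata <- setdiff(names(stats), c("mean", "sd", "n"))
  assert_columns(data, c(value, strata), "cohort table")
  joined <- dplyr::left_join(tibble::as_tibble(data), stats, by = strata)
  if (anyNA(joined$mean)) {
    abort("some rows fall in strata absent from `stats`")
  }
  joined |>
    dplyr::mutate(z = (.data[[value]] - .data$mean) / .data$sd,
                  below_lln = is_below_lln(.data$z)) |>
    dplyr::select(-dplyr::all_of(c("mean", "sd", "n")))
}

#' Lower limit of normal flag
#'
#' A measurement is below the LLN when its stratified z-score is strictly
#' below -1.645, the 5th percentile of the standard normal (to 3 decimals).
#'
#' @param z Numeric z-score(s).
#' @param threshold LLN boundary; default -1.645.
#' @return Logical vector, `TRUE` where `z < threshold`.
#' @export
is_below_lln <- function(z, threshold = -1.645) {
  if (!is.numeric(z) || any(!is.finite(z))) abort("`z` must be finite numeric")
  z < threshold
}

lm_formula <- function(outcome, predictors) {
  stats::as.formula(paste(outcome, "~", paste(predictors, collapse = " + ")),
                    env = baseenv())
}

check_full_rank <- function(model) {
  cf <- coef(model)
  if (anyNA(cf)) {
    abort(sprintf("rank-deficient design; collinear column(s): %s",
                  paste(names(cf)[is.na(cf)], collapse = ", ")))
  }
  qrm <- model$qr
  if (!is.null(qrm) && qrm$rank < ncol(qrm$qr)) {
    abort("rank-deficient design")
  }
  invisible(model)
}

#' Stratified least-squares reference equations
#'
#' Fits one ordinary least-squares model per gender-by-race stratum,
#' regressing the outcome (AEX by default) on anthropometric predictors.
#' Optional backward elimination drops the least significant predictor while
#' any exceeds `alpha` (intercept always kept).
#'
#' @param data Cohort table.
#' @param outcome Outcome column name (default `"aex"`).
#' @param predictors Predictor column names.
#' @param strata Stratifying columns (default gender and race).
#' @param backward If `TRUE`, backward-eliminate predictors at level `alpha`.
#' @param alpha Significance level for elimination (default 0.05).
#' @return An object of class `aex_lm_strata` with `tidy()`, `glance()` and
#'   `predict()` methods.
#' @export
fit_stratified_linear <- function(data, outcome = "aex",
                                  predictors = c("age_y", "height_cm",
                                                 "weight_kg"),
                                  strata = c("gender", "race"),
                                  backward = FALSE, alpha = 0.05) {
  assert_columns(data, c(outcome, predictors, strata), "cohort table")
  data <- tibble::as_tibble(data)
  groups <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::group_split()
  keys <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(strata))) |>
    dplyr::group_keys()
  fits <- purrr::map(groups, function(g) {
    if (nrow(g) < length(predictors) + 2) {
      abort(sprintf("stratum %s has too few rows (%d) for %d predictors",
                    paste(unlist(g[1, strata]), collapse = "/"), nrow(g),
                    length(predictors)))
    }
    kept <- predictors
    fit <- lm(lm_formula(outcome, kept), data = g)
    check_full_rank(fit)
    if (backward) {
      repeat {
        p <- summary(fit)$coefficients[, 4]
        p <- p[setdiff(names(p), "(Intercept)")]
        if (!length(p) || max(p) <= alpha) break
        drop_var <- kept[which.max(p[kept])]
        kept <- setdiff(kept, drop_var)
        fit <- lm(lm_formula(outcome, if (length(kept)) kept else "1"),
                  data = g)
      }
    }
    list(fit = fit, predictors = kept)
  })
  structure(
    list(keys = keys, fits = fits, strata = strata, outcome = outcome,
         predictors = predictors, backward = backward),
    class = "aex_lm_strata"
  )
}

#' @export
print.aex_lm_strata <- function(x, ...) {
  cat(sprintf("<aex_lm_strata> %s ~ %s in %d strata (%s)\n", x$outcome,
              paste(x$predictors, collapse = " + "), nrow(x$keys),
              paste(x$strata, collapse = " x ")))
  print(glance(x))
  invisible(x)
}

#' @export
predict.aex_lm_strata <- function(object, newdata, ...) {
  assert_columns(newdata, c(object$strata, object$predictors), "newdata")
  key_id <- function(d) {
    do.call(paste, c(d[object$strata], sep = "\r"))
  }
  ids <- key_id(newdata)
  fit_ids <- key_id(object$keys)
  unknown <- setdiff(unique(ids), fit_ids)
  if (length(unknown)) {
    abort(sprintf("no fitted model for stratum: %s",
                  gsub("\r", "/", unknown[1])))
  }
  out <- numeric(nrow(newdata))
  for (i in seq_along(object$fits)) {
    idx <- ids == fit_ids[i]
    if (any(idx)) {
      out[idx] <- predict(object$fits[[i]]$fit,
                          newdata = newdata[idx, , drop = FALSE])
    }
  }
  out
}

#' Penalized / transformed regression reference equation
#'
#' Fits the outcome on the predictors with an optional outcome transform
#' (`log`, or a `gamma` GLM with log link) and an optional shrinkage penalty:
#' `ridge`, `lasso`, `elastic-net` (glmnet), or `double-lasso` (a lasso
#' selection stage followed by a lasso re-fit on the selected columns).
#' Predictions are always reported on the original outcome scale. The penalty
#' strength is chosen by tenfold cross-validation or by fixed-rate (33%)
#' holdback unless `lambda` is given explicitly.
#'
#' @param data Cohort table.
#' @param outcome,predictors Column names.
#' @param transform `"none"`, `"log"` or `"gamma"`.
#' @param penalty `"none"`, `"ridge"`, `"lasso"`, `"double-lasso"` or
#'   `"elastic-net"`.
#' @param lambda Penalty strength; `NULL` selects it by `validation`. `0`
#'   reproduces the unpenalized fit.
#' @param alpha Elastic-net mixing (used only for `penalty = "elastic-net"`).
#' @param validation `"tenfold-cv"` or `"holdback"`.
#' @param seed Seed for fold / holdback assignment.
#' @return An object of class `aex_reglm` with `tidy()`/`glance()` methods
#'   and a `predict()` method; `glance()` reports the validation RASE and AAE.
#' @export
fit_regularized <- function(data, outcome = "aex",
                            predictors = c("age_y", "height_cm", "weight_kg"),
                            transform = c("none", "log", "gamma"),
                            penalty = c("none", "ridge", "lasso",
                                        "double-lasso", "elastic-net"),
                            lambda = NULL, alpha = 0.5,
                            validation = c("tenfold-cv", "holdback"),
                            seed = 1L) {
  transform <- match.arg(transform)
  penalty <- match.arg(penalty)
  validation <- match.arg(validation)
  assert_columns(data, c(outcome, predictors), "cohort table")
  if (!is.null(lambda)) assert_number(lambda, "lambda", lower = 0)
  y <- data[[outcome]]
  if (transform %in% c("log", "gamma") && any(y <= 0)) {
    abort(sprintf("transform '%s' requires a strictly positive outcome",
                  transform))
  }
  x <- stats::model.matrix(lm_formula(outcome, predictors),
                           data = data)[, -1, drop = FALSE]
  yt <- if (transform == "log") log(y) else y
  ga <- switch(penalty, ridge = 0, lasso = 1, `double-lasso` = 1,
               `elastic-net` = alpha, none = NA_real_)
  family <- if (transform == "gamma") stats::Gamma(link = "log") else "gaussian"

  fit_one <- function(xm, lam) {
    if (penalty == "none" || (!is.null(lam) && lam == 0)) {
      df <- data.frame(.y = yt, xm, check.names = FALSE)
      rhs <- if (ncol(xm)) sprintf("`%s`", colnames(xm)) else "1"
      if (transform == "gamma") {
        glm(lm_formula(".y", rhs), data = df, family = family)
      } else {
        lm(lm_formula(".y", rhs), data = df)
      }
    } else {
      glmnet::glmnet(xm, yt, family = family, alpha = ga, lambda = lam)
    }
  }
  # rule = "min" picks the error-minimizing strength; "1se" the largest
  # strength within one standard error of it (used by the double-lasso
  # selection stage, which wants parsimony rather than prediction)
  pick_lambda <- function(xm, rule = "min") {
    if (!is.null(lambda)) return(lambda)
    if (penalty == "none") return(0)
    with_seed(seed, {
      if (validation == "tenfold-cv") {
        cv <- glmnet::cv.glmnet(xm, yt, family = family, alpha = ga,
                                nfolds = 10)
        if (rule == "1se") cv$lambda.1se else cv$lambda.min
      } else {
        hold <- sample.int(nrow(xm)) <= round(0.33 * nrow(xm))
        path <- glmnet::glmnet(xm[!hold, , drop = FALSE], yt[!hold],
                               family = family, alpha = ga)
        pred <- predict(path, xm[hold, , drop = FALSE])
        sqerr <- (pred - yt[hold])^2
        err <- colMeans(sqerr)
        if (rule == "1se") {
          i_min <- which.min(err)
          se <- stats::sd(sqerr[, i_min]) / sqrt(sum(hold))
          max(path$lambda[err <= err[i_min] + se])
        } else {
          path$lambda[which.min(err)]
        }
      }
    })
  }

  selected <- colnames(x)
  lam1 <- pick_lambda(x, rule = if (penalty == "double-lasso") "1se" else "min")
  fit <- fit_one(x, lam1)
  if (penalty == "double-lasso" && lam1 > 0) {
    cf <- as.matrix(coef(fit))[-1, 1]
    selected <- names(cf)[cf != 0]
    if (length(selected) >= 2) {
      x2 <- x[, selected, drop = FALSE]
      lam2 <- pick_lambda(x2)
      fit <- fit_one(x2, lam2)
      lam1 <- lam2
    } else {
      # fewer than two survivors: re-fit unpenalized on the selection
      x2 <- x[, selected, drop = FALSE]
      fit <- fit_one(if (ncol(x2)) x2 else x[, 0, drop = FALSE], 0)
      lam1 <- 0
    }
  }

  obj <- structure(
    list(fit = fit, outcome = outcome, predictors = predictors,
         transform = transform, penalty = penalty, lambda = lam1,
         alpha = if (penalty == "elastic-net") alpha else NULL,
         selected = selected, validation = validation, seed = seed,
         formula_cols = colnames(x)),
    class = "aex_reglm"
  )
  # cross-validated error of the final configuration, on the original scale
  obj$cv_metrics <- with_seed(child_seed(seed, 7), {
    fold <- sample(rep_len(1:10, nrow(x)))
    pred <- numeric(nrow(x))
    for (k in 1:10) {
      te <- fold == k
      xk <- x[!te, obj$selected %||% colnames(x), drop = FALSE]
      fk <- if (inherits(fit, "glmnet")) {
        glmnet::glmnet(xk, yt[!te], family = family, alpha = ga, lambda = lam1)
      } else {
        refit_df <- data.frame(.y = yt[!te], xk, check.names = FALSE)
        rhs <- if (ncol(xk)) sprintf("`%s`", colnames(xk)) else "1"
        if (transform == "gamma") {
          glm(lm_formula(".y", rhs), data = refit_df, family = family)
        } else {
          lm(lm_formula(".y", rhs), data = refit_df)
        }
      }
      xte <- x[te, obj$selected %||% colnames(x), drop = FALSE]
      pk <- if (inherits(fk, "glmnet")) {
        eta <- as.numeric(predict(fk, xte))
        if (transform %in% c("log", "gamma")) exp(eta) else eta
      } else {
        nd <- data.frame(xte, check.names = FALSE)
        p0 <- as.numeric(predict(fk, newdata = nd,
                                 type = if (transform == "gamma")
                                   "response" else "response"))
        if (transform == "log") exp(p0) else p0
      }
      pred[te] <- pk
    }
    tibble::tibble(rase = rase(pred - y), aae = aae(pred - y))
  })
  obj
}

#' @export
predict.aex_reglm <- function(object, newdata, ...) {
  x <- stats::model.matrix(
    stats::as.formula(paste("~", paste(object$predictors, collapse = " + ")),
                      env = baseenv()),
    data = newdata
  )[, -1, drop = FALSE]
  cols <- object$selected
  fit <- object$fit
  if (inherits(fit, "glmnet")) {
    p <- as.numeric(predict(fit, x[, cols, drop = FALSE]))
    if (object$transform %in% c("log", "gamma")) p <- exp(p)
  } else if (length(cols) == 0) {
    mu <- unname(coef(fit)[1])
    p <- rep(if (object$transform == "log") exp(mu) else
      if (object$transform == "gamma") exp(mu) else mu, nrow(x))
  } else {
    nd <- data.frame(x[, cols, drop = FALSE], check.names = FALSE)
    p <- as.numeric(predict(fit, newdata = nd, type = "response"))
    if (object$transform == "log") p <- exp(p)
  }
  p
}

#' @export
print.aex_reglm <- function(x, ...) {
  cat(sprintf("<aex_reglm> %s ~ %s | transform=%s penalty=%s lambda=%.4g\n",
              x$outcome, paste(x$predictors, collapse = " + "), x$transform,
              x$penalty, x$lambda))
  print(x$cv_metrics)
  invisible(x)
}
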