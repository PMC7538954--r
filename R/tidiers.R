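#' Tidy methods for fitted reference models
#'
#' `tidy()` returns per-term (or per-weight) information; `glance()` returns
#' one-row model summaries, in the broom convention.
#'
#' @param x A fitted object.
#' @param ... Unused.
#' @return A tibble.
#' @name aexref-tidiers
NULL

#' @rdname aexref-tidiers
#' @export
tidy.aex_lm_strata <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$fits), x$fits, function(i, f) {
    cf <- summary(f$fit)$coefficients
    dplyr::bind_cols(
      x$keys[rep(i, nrow(cf)), , drop = FALSE],
      tibble::tibble(term = rownames(cf), estimate = unname(cf[, 1]),
                     std_error = unname(cf[, 2]),
                     statistic = unname(cf[, 3]),
                     p_value = unname(cf[, 4]))
    )
  })
}

#' @rdname aexref-tidiers
#' @export
glance.aex_lm_strata <- function(x, ...) {
  purrr::map2_dfr(seq_along(x$fits), x$fits, function(i, f) {
    s <- summary(f$fit)
    dplyr::bind_cols(
      x$keys[i, , drop = FALSE],
      tibble::tibble(r2 = s$r.squared, sigma = s$sigma,
                     n = length(s$residuals),
                     predictors = paste(f$predictors, collapse = "+"))
    )
  })
}

#' @rdname aexref-tidiers
#' @export
tidy.aex_reglm <- function(x, ...) {
  cf <- if (inherits(x$fit, "glmnet")) {
    m <- as.matrix(coef(x$fit))
    tibble::tibble(term = rownames(m), estimate = m[, 1])
  } else {
    m <- coef(x$fit)
    tibble::tibble(term = names(m), estimate = unname(m))
  }
  cf$penalty <- x$penalty
  cf$lambda <- x$lambda
  cf
}

#' @rdname aexref-tidiers
#' @export
glance.aex_reglm <- function(x, ...) {
  tibble::tibble(transform = x$transform, penalty = x$penalty,
                 lambda = x$lambda, validation = x$validation,
                 cv_rase = x$cv_metrics$rase, cv_aae = x$cv_metrics$aae,
                 n_selected = length(x$selected))
}

#' @rdname aexref-tidiers
#' @export
tidy.aex_ann <- function(x, ...) {
  purrr::imap_dfr(x$weights, function(m, nm) {
    layer <- as.integer(sub("^[Wb]", "", nm))
    kind <- if (startsWith(nm, "W")) "weight" else "bias"
    idx <- which(!is.na(m), arr.ind = TRUE)
    tibble::tibble(layer = layer, kind = kind,
                   from = idx[, 1], to = idx[, 2],
                   value = m[idx])
  })
}

#' @rdname aexref-tidiers
#' @export
glance.aex_ann <- function(x, ...) {
  tibble::tibble(
    layers = length(x$architecture),
    n_weights = sum(vapply(x$shapes, prod, numeric(1))),
    lambda = x$lambda, loss = x$loss, output = x$output,
    converged = x$converged, seed = x$seed,
    train_rase = x$metrics$rase, train_r2 = x$metrics$r2
  )
}

#' @rdname aexref-tidiers
#' @export
glance.aex_ann_boost <- function(x, ...) {
  tibble::tibble(
    n_models = length(x$components),
    learning_rate = x$learning_rate,
    train_rase = x$rase_path[length(x$rase_path)],
    train_r2 = x$metrics$r2
  )
}
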