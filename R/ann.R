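#' Mixed-activation network architecture
#'
#' Each hidden layer mixes three node families: sigmoidal (`tanh`), linear
#' (identity) and gaussian (`exp(-u^2)` of the affine input). The default,
#' two hidden layers of (3 sigmoidal, 3 linear, 3 gaussian) nodes each, is
#' the architecture that balances bias, variance and speed for
#' anthropometry-to-AEX surfaces; see [run_ablation()] to explore the grid.
#'
#' @param ... One integer vector `c(n_sigmoidal, n_linear, n_gaussian)` per
#'   hidden layer.
#' @return An object of class `aex_ann_arch`.
#' @examples
#' ann_architecture(c(3, 3, 3), c(3, 3, 3))  # the default
#' ann_architecture(c(0, 3, 0))              # one linear-only layer
#' @export
ann_architecture <- function(...) {
  layers <- list(...)
  if (!length(layers)) abort("need at least one hidden layer")
  layers <- lapply(layers, function(l) {
    l <- as.integer(l)
    if (length(l) != 3 || any(l < 0) || sum(l) < 1) {
      abort("each layer must be c(n_sigmoidal, n_linear, n_gaussian) with >= 1 node")
    }
    stats::setNames(l, c("sigmoidal", "linear", "gaussian"))
  })
  structure(layers, class = "aex_ann_arch")
}

#' @export
print.aex_ann_arch <- function(x, ...) {
  lab <- vapply(x, function(l) sprintf("%ds%dl%dg", l[1], l[2], l[3]), "")
  cat("<aex_ann_arch>", paste(lab, collapse = " -> "), "\n")
  invisible(x)
}

arch_sizes <- function(arch) vapply(arch, sum, integer(1))

# activation type codes per node of a layer: 1 tanh, 2 identity, 3 gaussian
arch_codes <- function(layer) {
  rep(1:3, times = layer[c("sigmoidal", "linear", "gaussian")])
}

activate <- function(a, codes) {
  z <- a
  s <- codes == 1; g <- codes == 3
  if (any(s)) z[, s] <- tanh(a[, s, drop = FALSE])
  if (any(g)) z[, g] <- exp(-a[, g, drop = FALSE]^2)
  z
}

activate_grad <- function(a, z, codes) {
  d <- matrix(1, nrow(a), ncol(a))
  s <- codes == 1; g <- codes == 3
  if (any(s)) d[, s] <- 1 - z[, s, drop = FALSE]^2
  if (any(g)) d[, g] <- -2 * a[, g, drop = FALSE] * z[, g, drop = FALSE]
  d
}

# --- input encoding -----------------------------------------------------

build_encoder <- function(data, predictors) {
  enc <- lapply(predictors, function(p) {
    v <- data[[p]]
    if (is.numeric(v)) {
      s <- stats::sd(v)
      list(type = "numeric", center = mean(v), scale = if (s > 0) s else 1)
    } else {
      lev <- sort(unique(as.character(v)))
      if (length(lev) < 2) {
        list(type = "constant", level = lev)
      } else {
        list(type = "categorical", levels = lev)
      }
    }
  })
  stats::setNames(enc, predictors)
}

encode_inputs <- function(encoder, data) {
  cols <- list()
  for (p in names(encoder)) {
    e <- encoder[[p]]
    v <- data[[p]]
    if (is.null(v)) abort(sprintf("newdata is missing predictor '%s'", p))
    if (e$type == "numeric") {
      cols[[p]] <- (as.numeric(v) - e$center) / e$scale
    } else if (e$type == "constant") {
      if (any(as.character(v) != e$level)) {
        abort(sprintf("unseen level in '%s' (trained on constant '%s')",
                      p, e$level))
      }
    } else {
      v <- as.character(v)
      unseen <- setdiff(unique(v), e$levels)
      if (length(unseen)) {
        abort(sprintf("unseen level '%s' in predictor '%s'", unseen[1], p))
      }
      for (lev in e$levels[-1]) {
        cols[[paste0(p, "_", lev)]] <- as.numeric(v == lev)
      }
    }
  }
  do.call(cbind, cols)
}

# rank-based normalizing transform of continuous inputs (optional)
rank_normalize <- function(x) {
  stats::qnorm((rank(x) - 0.5) / length(x))
}

# --- parameter bookkeeping ----------------------------------------------

ann_shapes <- function(p_in, arch) {
  sizes <- c(p_in, arch_sizes(arch), 1L)
  shapes <- list()
  for (l in seq_len(length(sizes) - 1)) {
    shapes[[paste0("W", l)]] <- c(sizes[l], sizes[l + 1])
    shapes[[paste0("b", l)]] <- c(1L, sizes[l + 1])
  }
  shapes
}

unflatten <- function(par, shapes) {
  out <- list()
  pos <- 0L
  for (nm in names(shapes)) {
    sh <- shapes[[nm]]
    len <- prod(sh)
    out[[nm]] <- matrix(par[pos + seq_len(len)], sh[1], sh[2])
    pos <- pos + len
  }
  out
}

ann_forward <- function(w, X, arch) {
  n_layers <- length(arch)
  A <- Z <- vector("list", n_layers)
  zin <- X
  for (l in seq_len(n_layers)) {
    A[[l]] <- sweep(zin %*% w[[paste0("W", l)]], 2,
                    w[[paste0("b", l)]][1, ], "+")
    Z[[l]] <- activate(A[[l]], arch_codes(arch[[l]]))
    zin <- Z[[l]]
  }
  L <- n_layers + 1L
  yhat <- drop(zin %*% w[[paste0("W", L)]]) + w[[paste0("b", L)]][1, 1]
  list(A = A, Z = Z, yhat = yhat)
}

# objective Sum(loss(resid)) + lambda * Sum(weights^2) and its gradient;
# biases are not penalized
ann_obj_grad <- function(par, X, y, arch, shapes, lambda, loss, delta) {
  w <- unflatten(par, shapes)
  fw <- ann_forward(w, X, arch)
  r <- fw$yhat - y
  if (loss == "squared") {
    val <- sum(r^2)
    dr <- 2 * r
  } else {
    big <- abs(r) > delta
    val <- sum(ifelse(big, 2 * delta * abs(r) - delta^2, r^2))
    dr <- ifelse(big, 2 * delta * sign(r), 2 * r)
  }
  n_layers <- length(arch)
  L <- n_layers + 1L
  grads <- vector("list", length(shapes))
  names(grads) <- names(shapes)
  zprev <- if (n_layers >= 1) fw$Z[[n_layers]] else X
  grads[[paste0("W", L)]] <- crossprod(zprev, dr) +
    2 * lambda * w[[paste0("W", L)]]
  grads[[paste0("b", L)]] <- matrix(sum(dr), 1, 1)
  upstream <- outer(dr, w[[paste0("W", L)]][, 1])  # n x h_last
  for (l in rev(seq_len(n_layers))) {
    dact <- activate_grad(fw$A[[l]], fw$Z[[l]], arch_codes(arch[[l]]))
    dA <- upstream * dact
    zin <- if (l == 1) X else fw$Z[[l - 1]]
    grads[[paste0("W", l)]] <- crossprod(zin, dA) +
      2 * lambda * w[[paste0("W", l)]]
    grads[[paste0("b", l)]] <- matrix(colSums(dA), 1)
    if (l > 1) upstream <- dA %*% t(w[[paste0("W", l)]])
  }
  pen <- lambda * sum(vapply(grep("^W", names(shapes), value = TRUE),
                             function(nm) sum(w[[nm]]^2), numeric(1)))
  list(value = val + pen,
       grad = unlist(lapply(names(shapes), function(nm) grads[[nm]]),
                     use.names = FALSE))
}

#' Train a mixed-activation neural-network reference model
#'
#' Fits a small multilayer perceptron with sigmoidal (`tanh`), linear and
#' gaussian (`exp(-u^2)`) hidden nodes predicting AEX (or its stratified
#' z-score) from anthropometric inputs. Continuous inputs are standardized
#' and categoricals one-hot encoded; the outcome is standardized internally
#' and restored on prediction. Training minimizes `sum(loss(residual)) +
#' lambda * sum(weights^2)` by BFGS from small seeded uniform(-0.1, 0.1)
#' initial weights, so results are deterministic given the seed.
#'
#' @param data Training table.
#' @param outcome Outcome column (default `"aex"`).
#' @param predictors Input columns (continuous or categorical).
#' @param architecture An [ann_architecture()]; default two layers of
#'   (3, 3, 3).
#' @param output `"aex"` trains on the raw outcome; `"zscore"` standardizes
#'   it per stratum first (using `stratum_stats`, computed from the training
#'   data when omitted) and lets [predict.aex_ann()] reconstruct the raw
#'   scale as `mean + z * sd`.
#' @param stratum_stats Optional [fit_stratum_stats()] table for
#'   `output = "zscore"`.
#' @param lambda Non-negative squared penalty on the weights, on the
#'   summed standardized-outcome scale (default 5).
#' @param loss `"squared"` or `"robust"` (Huber, delta = 1.345 x a
#'   preliminary residual scale).
#' @param transform_inputs If `TRUE`, apply a rank-based normalizing
#'   transform to continuous inputs before standardizing (off by default).
#' @param seed Integer seed for the weight initialization.
#' @param max_iter,tol BFGS iteration cap and relative-objective tolerance.
#' @return An object of class `aex_ann`; non-convergence within `max_iter`
#'   returns the model with a warning and `converged = FALSE`.
#' @export
train_ann <- function(data, outcome = "aex",
                      predictors = c("gender", "race", "age_y", "height_cm",
                                     "weight_kg"),
                      architecture = ann_architecture(c(3, 3, 3), c(3, 3, 3)),
                      output = c("aex", "zscore"), stratum_stats = NULL,
                      lambda = 5, loss = c("squared", "robust"),
                      transform_inputs = FALSE,
                      seed = 1L, max_iter = 5000, tol = 1e-8) {
  output <- match.arg(output)
  loss <- match.arg(loss)
  assert_columns(data, c(outcome, predictors), "training table")
  assert_number(lambda, "lambda", lower = 0)
  if (!inherits(architecture, "aex_ann_arch")) {
    architecture <- do.call(ann_architecture, architecture)
  }
  if (nrow(data) < 10) abort("need at least 10 training rows")

  y_raw <- data[[outcome]]
  if (output == "zscore") {
    if (is.null(stratum_stats)) {
      stratum_stats <- fit_stratum_stats(data, value = outcome)
    }
    strata <- setdiff(names(stratum_stats), c("mean", "sd", "n"))
    zd <- add_z_scores(data, stratum_stats, value = outcome)
    y_raw <- zd$z
  }
  if (stats::sd(y_raw) == 0) abort("outcome is constant; nothing to fit")

  encoder <- build_encoder(data, predictors)
  if (transform_inputs) {
    for (p in names(encoder)) {
      if (encoder[[p]]$type == "numeric") {
        # replace the raw column by its normal scores before standardizing
        rn <- rank_normalize(data[[p]])
        encoder[[p]]$rank_map <- list(x = sort(data[[p]]),
                                      q = sort(rn))
        data[[p]] <- rn
        encoder[[p]]$center <- mean(rn)
        encoder[[p]]$scale <- max(stats::sd(rn), 1e-12)
      }
    }
  }
  X <- encode_inputs(encoder, data)
  y_center <- mean(y_raw)
  y_scale <- stats::sd(y_raw)
  y <- (y_raw - y_center) / y_scale

  delta <- if (loss == "robust") {
    r0 <- stats::lm.fit(cbind(1, X), y)$residuals
    max(1.345 * stats::mad(r0), 1e-6)
  } else {
    NA_real_
  }

  shapes <- ann_shapes(ncol(X), architecture)
  n_par <- sum(vapply(shapes, prod, numeric(1)))
  init <- with_seed(seed, stats::runif(n_par, -0.1, 0.1))
  cache <- new.env(parent = emptyenv())
  evaluate <- function(par) {
    if (!is.null(cache$par) && identical(par, cache$par)) return(cache$res)
    res <- ann_obj_grad(par, X, y, architecture, shapes, lambda, loss, delta)
    cache$par <- par
    cache$res <- res
    res
  }
  opt <- stats::optim(init, fn = function(p) evaluate(p)$value,
                      gr = function(p) evaluate(p)$grad, method = "BFGS",
                      control = list(maxit = max_iter, reltol = tol))
  if (opt$convergence != 0) {
    warn(sprintf("ANN training did not converge within %d iterations (code %d)",
                 max_iter, opt$convergence))
  }
  w <- unflatten(opt$par, shapes)
  fw <- ann_forward(w, X, architecture)
  pred_raw <- fw$yhat * y_scale + y_center
  res <- pred_raw - y_raw
  model <- structure(
    list(architecture = architecture, weights = w, shapes = shapes,
         encoder = encoder, predictors = predictors, outcome = outcome,
         output = output, stratum_stats = stratum_stats,
         y_center = y_center, y_scale = y_scale, lambda = lambda,
         loss = loss, delta = delta, transform_inputs = transform_inputs,
         seed = seed, converged = opt$convergence == 0,
         objective = opt$value,
         metrics = tibble::tibble(
           rase = rase(res), r2 = 1 - sum(res^2) / sum((y_raw - y_center)^2)
         )),
    class = "aex_ann"
  )
  model
}

#' @export
print.aex_ann <- function(x, ...) {
  lab <- vapply(x$architecture,
                function(l) sprintf("%ds%dl%dg", l[1], l[2], l[3]), "")
  cat(sprintf("<aex_ann> %s ~ %s | layers %s | lambda %.3g | %s loss\n",
              x$outcome, paste(x$predictors, collapse = " + "),
              paste(lab, collapse = " -> "), x$lambda, x$loss))
  cat(sprintf("  output: %s | train RASE %.4g, R^2 %.3f%s\n", x$output,
              x$metrics$rase, x$metrics$r2,
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

encode_for_predict <- function(object, newdata) {
  if (isTRUE(object$transform_inputs)) {
    for (p in names(object$encoder)) {
      e <- object$encoder[[p]]
      if (!is.null(e$rank_map)) {
        newdata[[p]] <- stats::approx(e$rank_map$x, e$rank_map$q,
                                      xout = newdata[[p]], rule = 2)$y
      }
    }
  }
  encode_inputs(object$encoder, newdata)
}

#' Predict from a fitted ANN reference model
#'
#' @param object An `aex_ann` from [train_ann()].
#' @param newdata Subject table with the model's predictor columns.
#' @param type For z-score models, `"response"` (default) reconstructs the
#'   raw outcome as `mean + z * sd` from the stratum stats; `"zscore"`
#'   returns the standardized prediction. For raw-outcome models only
#'   `"response"` is available.
#' @param stratum_stats Optional replacement stats table for the
#'   reconstruction.
#' @param ... Unused.
#' @return Numeric predictions, one per row of `newdata`.
#' @export
predict.aex_ann <- function(object, newdata, type = c("response", "zscore"),
                            stratum_stats = NULL, ...) {
  type <- match.arg(type)
  X <- encode_for_predict(object, newdata)
  fw <- ann_forward(object$weights, X, object$architecture)
  out <- fw$yhat * object$y_scale + object$y_center
  if (object$output == "zscore") {
    if (type == "zscore") return(out)
    stats_tab <- stratum_stats %||% object$stratum_stats
    if (is.null(stats_tab)) {
      abort("z-score model has no stratum stats; supply `stratum_stats`")
    }
    strata <- setdiff(names(stats_tab), c("mean", "sd", "n"))
    joined <- dplyr::left_join(tibble::as_tibble(newdata), stats_tab,
                               by = strata)
    if (anyNA(joined$mean)) abort("rows fall in strata absent from the stats")
    return(joined$mean + out * joined$sd)
  }
  if (type == "zscore") abort("model was trained on the raw outcome")
  out
}

#' Boosted additive ensemble of small ANNs
#'
#' Sequential residual fitting: an additive sequence of `n_models` small
#' networks, each trained on the current residuals and added with shrinkage
#' `learning_rate`. With `n_models = 1` and `learning_rate = 1`, the
#' ensemble reduces to a single [train_ann()] fit.
#'
#' @inheritParams train_ann
#' @param architecture Base learner architecture; default one layer of
#'   (2, 2, 2).
#' @param n_models Number of boosting stages (default 100).
#' @param learning_rate Shrinkage applied to each stage (default 0.1).
#' @param max_iter BFGS cap per stage (default 200; stages are many and
#'   small).
#' @param tol Relative-objective convergence tolerance per stage.
#' @return An object of class `aex_ann_boost` with a `predict()` method and
#'   a `rase_path` giving the training RASE after each stage.
#' @export
train_boosted <- function(data, outcome = "aex",
                          predictors = c("gender", "race", "age_y",
                                         "height_cm", "weight_kg"),
                          architecture = ann_architecture(c(2, 2, 2)),
                          n_models = 100, learning_rate = 0.1,
                          lambda = 1e-3, seed = 1L, max_iter = 200,
                          tol = 1e-8) {
  assert_columns(data, c(outcome, predictors), "training table")
  if (learning_rate <= 0 || learning_rate > 1) {
    abort("`learning_rate` must be in (0, 1]")
  }
  y <- data[[outcome]]
  base_mean <- mean(y)
  current <- rep(base_mean, length(y))
  work <- tibble::as_tibble(data)
  components <- vector("list", n_models)
  rase_path <- numeric(n_models)
  for (m in seq_len(n_models)) {
    work$.resid <- y - current
    fit <- train_ann(work, outcome = ".resid", predictors = predictors,
                     architecture = architecture, lambda = lambda,
                     seed = if (m == 1) seed else child_seed(seed, m - 1),
                     max_iter = max_iter, tol = tol)
    components[[m]] <- fit
    current <- current + learning_rate * predict(fit, work)
    rase_path[m] <- rase(current - y)
  }
  structure(
    list(base_mean = base_mean, components = components,
         learning_rate = learning_rate, outcome = outcome,
         predictors = predictors, seed = seed, rase_path = rase_path,
         metrics = tibble::tibble(rase = rase_path[n_models],
                                  r2 = 1 - rase_path[n_models]^2 / var(y) /
                                    ((length(y) - 1) / length(y)))),
    class = "aex_ann_boost"
  )
}

#' @export
predict.aex_ann_boost <- function(object, newdata, ...) {
  out <- rep(object$base_mean, nrow(newdata))
  for (fit in object$components) {
    out <- out + object$learning_rate * predict(fit, newdata)
  }
  out
}

#' @export
print.aex_ann_boost <- function(x, ...) {
  cat(sprintf("<aex_ann_boost> %d stages, learning rate %.2g, train RASE %.4g\n",
              length(x$components), x$learning_rate,
              x$rase_path[length(x$rase_path)]))
  invisible(x)
}
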