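#' Read a published equation set from JSON
#'
#' An equation set holds per-stratum affine-or-log-affine prediction formulas
#' for spirometric targets (FVC, PEF, FEF25/50/75, FEV1, FEV_PEF, AEX) in
#' age / height / weight, with validity ranges. The package ships an empty
#' template (`system.file("extdata", "equation_set_template.json", package =
#' "aexref")`) whose coefficients users fill in from the source publications;
#' no published coefficients are bundled.
#'
#' @param path Path to a JSON equation-set file.
#' @return An object of class `aex_equation_set`: a list with `name` and a
#'   tibble `strata` (columns `gender`, `race`, `target`, `intercept`,
#'   `terms` list-column, `scale`, `valid_age`, `valid_height` list-columns).
#' @export
read_equation_set <- function(path) {
  if (!file.exists(path)) abort(sprintf("equation set file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  equation_set(raw)
}

#' @rdname read_equation_set
#' @param x A named list with fields `name` and `strata` (see the template).
#' @export
equation_set <- function(x) {
  if (is.null(x$name) || is.null(x$strata)) {
    abort("equation set needs `name` and `strata`")
  }
  rows <- purrr::map(x$strata, function(s) {
    for (f in c("gender", "race", "target", "intercept")) {
      if (is.null(s[[f]])) abort(sprintf("equation stratum missing `%s`", f))
    }
    tibble::tibble(
      gender = s$gender, race = s$race, target = toupper(s$target),
      intercept = as.numeric(s$intercept),
      terms = list(s$terms %||% list()),
      scale = s$scale %||% "none",
      valid_age = list(as.numeric(s$valid_age %||% c(-Inf, Inf))),
      valid_height = list(as.numeric(s$valid_height %||% c(-Inf, Inf)))
    )
  })
  structure(list(name = x$name, strata = dplyr::bind_rows(rows)),
            class = "aex_equation_set")
}

#' @export
print.aex_equation_set <- function(x, ...) {
  cat(sprintf("<aex_equation_set> %s: %d stratum-target formulas\n",
              x$name, nrow(x$strata)))
  invisible(x)
}

eval_equation_row <- function(row, subject) {
  vars <- list(age = subject$age_y, height = subject$height_cm,
               weight = subject$weight_kg)
  val <- row$intercept
  for (term in row$terms[[1]]) {
    v <- vars[[term$var]]
    if (is.null(v)) abort(sprintf("equation term references unknown var '%s'",
                                  term$var))
    if (is.null(term$coef)) abort("equation term missing coefficient")
    val <- val + as.numeric(term$coef) * v^(term$power %||% 1)
  }
  if (identical(row$scale, "log")) exp(val) else val
}

#' Predict spirometric targets from a published equation set
#'
#' Evaluates the stored formula of `eq` for each subject. For composite
#' targets `"AEX1"` ... `"AEX4"`, the component predictions (FVC, PEF, the
#' needed FEFs, and FEV_PEF -- estimated from predicted FEV1 via
#' [estimate_fev_pef()] if the set has no FEV_PEF formula) are evaluated
#' first and the polygonal area is delegated to [aex_approx()]. Subjects
#' outside a formula's validity range are predicted anyway but flagged as
#' extrapolations, with a warning.
#'
#' @param data Subject table with `gender`, `race`, `age_y`, `height_cm`,
#'   `weight_kg`.
#' @param eq An `aex_equation_set`.
#' @param target Target name, e.g. `"AEX"`, `"FVC"`, `"AEX1"`.
#' @return A tibble with columns `value` and `extrapolated`.
#' @export
apply_equation_set <- function(data, eq, target = "AEX") {
  if (!inherits(eq, "aex_equation_set")) abort("`eq` must be an aex_equation_set")
  assert_columns(data, c("gender", "race", "age_y", "height_cm", "weight_kg"),
                 "subject table")
  target <- toupper(target)
  if (grepl("^AEX[1-4]$", target)) {
    k <- as.integer(substr(target, 4, 4))
    comps <- c("FVC", "PEF",
               toupper(sub("_Ls$", "", aex_order_flows[[as.character(k)]])))
    # components warn individually; emit a single warning for the composite
    preds <- suppressWarnings(purrr::map(comps,
                                         ~ apply_equation_set(data, eq, .x)))
    names(preds) <- comps
    fev_pef <- suppressWarnings(
      if ("FEV_PEF" %in% eq$strata$target) {
        apply_equation_set(data, eq, "FEV_PEF")$value
      } else if ("FEV1" %in% eq$strata$target) {
        estimate_fev_pef(apply_equation_set(data, eq, "FEV1")$value)
      } else {
        abort("equation set has neither FEV_PEF nor FEV1; cannot place the peak")
      }
    )
    lmtab <- tibble::tibble(
      fvc_L = preds$FVC$value, pef_Ls = preds$PEF$value, fev_pef_L = fev_pef
    )
    for (cn in aex_order_flows[[as.character(k)]]) {
      key <- toupper(sub("_Ls$", "", cn))
      lmtab[[cn]] <- preds[[key]]$value
    }
    res <- aex_approx(lmtab, order = k)
    extrap <- Reduce(`|`, purrr::map(preds, "extrapolated"))
    if (any(extrap)) {
      warn(sprintf(
        "%d subject(s) outside the validity range of '%s' for %s components",
        sum(extrap), eq$name, target))
    }
    return(tibble::tibble(value = res$value, extrapolated = extrap))
  }

  n <- nrow(data)
  value <- rep(NA_real_, n)
  extrap <- rep(FALSE, n)
  for (i in seq_len(n)) {
    row <- eq$strata[eq$strata$gender == data$gender[i] &
                       eq$strata$race == data$race[i] &
                       eq$strata$target == target, ]
    if (nrow(row) == 0) {
      abort(sprintf("equation set '%s' has no %s formula for stratum %s/%s",
                    eq$name, target, data$gender[i], data$race[i]))
    }
    row <- row[1, ]
    ar <- row$valid_age[[1]]; hr <- row$valid_height[[1]]
    extrap[i] <- data$age_y[i] < ar[1] || data$age_y[i] > ar[2] ||
      data$height_cm[i] < hr[1] || data$height_cm[i] > hr[2]
    value[i] <- eval_equation_row(row, data[i, ])
  }
  if (any(extrap)) {
    warn(sprintf("%d subject(s) outside the validity range of '%s'; %s",
                 sum(extrap), eq$name, "predictions flagged as extrapolated"))
  }
  tibble::tibble(value = value, extrapolated = extrap)
}
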