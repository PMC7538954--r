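#' Integrate flow over exhaled volume (measured AEX)
#'
#' Computes the area under a sampled maximal expiratory flow-volume curve by
#' the trapezoidal rule: \eqn{AEX = \int_0^{FVC} \dot{V}\, dV} in L\eqn{^2}/s.
#' The trapezoidal rule is exact on the piecewise-linear polygons used for the
#' landmark approximations [aex_approx()], so the two routes agree on
#' polyline data.
#'
#' @param curve Data frame with columns `volume_L` and `flow_L_s` (the names
#'   `volume`/`flow` are also accepted): exhaled volume (L, strictly
#'   increasing) and instantaneous expiratory flow (L/s, non-negative).
#' @return A single non-negative number, the area in L\eqn{^2}/s.
#' @examples
#' tri <- data.frame(volume_L = c(0, 0.5, 4), flow_L_s = c(0, 6, 0))
#' integrate_flow_volume(tri)  # 0.5*0.5*6 + 0.5*3.5*6 = 12
#' @export
integrate_flow_volume <- function(curve) {
  curve <- normalize_curve(curve)
  v <- curve$volume_L
  f <- curve$flow_L_s
  n <- length(v)
  if (n < 2) abort("flow-volume curve needs at least 2 sampled points")
  dv <- diff(v)
  bad <- which(dv <= 0)
  if (length(bad)) {
    abort(sprintf("volumes must be strictly increasing; violation at index %d",
                  bad[1] + 1L))
  }
  neg <- which(f < 0)
  if (length(neg)) {
    abort(sprintf("flows must be non-negative; negative flow at index %d",
                  neg[1]))
  }
  sum(dv * (f[-1] + f[-n]) / 2)
}

normalize_curve <- function(curve) {
  if (!is.data.frame(curve)) abort("`curve` must be a data frame")
  nm <- names(curve)
  if (all(c("volume_L", "flow_L_s") %in% nm)) {
    curve[c("volume_L", "flow_L_s")]
  } else if (all(c("volume", "flow") %in% nm)) {
    stats::setNames(curve[c("volume", "flow")], c("volume_L", "flow_L_s"))
  } else {
    abort("`curve` must have columns volume_L and flow_L_s")
  }
}

#' Estimate the exhaled volume at peak flow from FEV1
#'
#' When the volume at which peak expiratory flow occurs (FEV_PEF) is not
#' exported by the spirometer, it can be estimated from FEV1 by the linear
#' model `0.157174 + 0.176439 * FEV1`, derived on a large adult
#' normal-spirometry cohort. AEX approximations computed from this estimate
#' are conventionally starred (AEX2*, AEX3*, AEX4*).
#'
#' @param fev1 Numeric vector of FEV1 values (L), all non-negative.
#' @return Estimated FEV_PEF (L), same length as `fev1`.
#' @examples
#' estimate_fev_pef(2.8)  # ~0.65 L
#' @export
estimate_fev_pef <- function(fev1) {
  if (!is.numeric(fev1)) abort("`fev1` must be numeric")
  bad <- which(fev1 < 0)
  if (length(bad)) {
    abort(sprintf("`fev1` must be non-negative; negative value at index %d",
                  bad[1]))
  }
  0.157174 + 0.176439 * fev1
}

# canonical landmark column names used across the package
landmark_columns <- c("fvc_L", "fev1_L", "pef_Ls", "fev_pef_L",
                      "fef25_Ls", "fef50_Ls", "fef75_Ls")

# Accept a one-row data frame or named list/vector with canonical or bare
# names; return a named list with canonical names (missing fields NA).
normalize_landmarks <- function(landmarks) {
  if (is.data.frame(landmarks) && nrow(landmarks) != 1) {
    abort("`landmarks` must describe a single test (one row)")
  }
  x <- as.list(landmarks)
  bare <- c(fvc = "fvc_L", fev1 = "fev1_L", pef = "pef_Ls",
            fev_pef = "fev_pef_L", fef25 = "fef25_Ls", fef50 = "fef50_Ls",
            fef75 = "fef75_Ls")
  for (b in names(bare)) {
    if (!is.null(x[[b]]) && is.null(x[[bare[[b]]]])) x[[bare[[b]]]] <- x[[b]]
  }
  out <- lapply(landmark_columns, function(cn) {
    v <- x[[cn]]
    if (is.null(v)) NA_real_ else as.numeric(v)
  })
  stats::setNames(out, landmark_columns)
}

# flows required for each approximation order, beyond FVC/PEF/FEV_PEF
aex_order_flows <- list(
  `1` = character(0),
  `2` = "fef50_Ls",
  `3` = c("fef25_Ls", "fef75_Ls"),
  `4` = c("fef25_Ls", "fef50_Ls", "fef75_Ls")
)

# interior quartile volume fractions for each order
aex_order_fracs <- list(`1` = numeric(0), `2` = 0.5,
                        `3` = c(0.25, 0.75), `4` = c(0.25, 0.5, 0.75))

#' Node set of an AEX landmark approximation
#'
#' The AEX approximations replace the measured expiratory curve with a
#' piecewise-linear curve through spirometric landmarks: the origin (0, 0),
#' the peak (FEV_PEF, PEF), the quartile flows placed at the exhaled volumes
#' where they are defined (FEF25 at 0.25 FVC, FEF50 at 0.5 FVC, FEF75 at
#' 0.75 FVC), and the terminal point (FVC, 0). Order 1 uses FVC and PEF only;
#' order 2 adds FEF50; order 3 adds FEF25 and FEF75; order 4 uses all three.
#'
#' @param landmarks A one-row data frame (or named list) with landmark columns
#'   `fvc_L`, `pef_Ls`, `fev_pef_L` and whichever of `fef25_Ls`, `fef50_Ls`,
#'   `fef75_Ls` the order needs. Bare names (`fvc`, `pef`, ...) also work.
#' @param order Approximation order, 1-4.
#' @return A tibble with columns `volume` (L) and `flow` (L/s), one row per
#'   node in order of exhaled volume.
#' @examples
#' aex_nodes(list(fvc = 4, pef = 6, fev_pef = 0.5, fef50 = 3), order = 2)
#' @export
aex_nodes <- function(landmarks, order = 4) {
  lm <- normalize_landmarks(landmarks)
  order <- check_order(order)
  need <- c("fvc_L", "pef_Ls", "fev_pef_L", aex_order_flows[[as.character(order)]])
  miss <- need[vapply(need, function(cn) is.na(lm[[cn]]), logical(1))]
  if (length(miss)) {
    abort(sprintf("landmark(s) required for AEX_%d missing or NA: %s%s",
                  order, paste(miss, collapse = ", "),
                  if ("fev_pef_L" %in% miss)
                    " (see estimate_fev_pef() for the starred estimate)" else ""))
  }
  fvc <- lm$fvc_L; pef <- lm$pef_Ls; fev_pef <- lm$fev_pef_L
  if (fvc <= 0) abort("fvc_L must be > 0")
  if (pef < 0) abort("pef_Ls must be >= 0")
  if (fev_pef <= 0 || fev_pef >= fvc) {
    abort("fev_pef_L must lie strictly between 0 and fvc_L")
  }
  fracs <- aex_order_fracs[[as.character(order)]]
  iv <- fvc * fracs
  flows <- unlist(lm[aex_order_flows[[as.character(order)]]], use.names = FALSE)
  if (any(flows < 0)) abort("instantaneous flows must be non-negative")
  if (length(iv) && fev_pef >= min(iv)) {
    abort(sprintf(paste0("degenerate geometry: fev_pef_L (%.3g) is not below ",
                         "the first quartile node volume (%.3g) for AEX_%d"),
                  fev_pef, min(iv), order))
  }
  tibble::tibble(
    volume = c(0, fev_pef, iv, fvc),
    flow   = c(0, pef, flows, 0)
  )
}

check_order <- function(order) {
  if (length(order) != 1 || !order %in% 1:4) {
    abort("`order` must be one of 1, 2, 3, 4")
  }
  as.integer(order)
}

#' Landmark-based AEX approximations (AEX1-AEX4)
#'
#' Computes the area of the polygon under the piecewise-linear flow-volume
#' curve through the landmark nodes (see [aex_nodes()]): the ascending
#' triangle to (FEV_PEF, PEF), the interior trapezoids, and the terminal
#' triangle down to (FVC, 0). Equals [integrate_flow_volume()] applied to any
#' dense sampling of the node polyline.
#'
#' @param data Data frame of spirometry tests with landmark columns `fvc_L`,
#'   `pef_Ls`, `fev_pef_L` and the `fefXX_Ls` flows the order needs.
#' @param order Approximation order, 1-4.
#' @param use_estimated_fev_pef If `TRUE`, rows with missing `fev_pef_L` use
#'   [estimate_fev_pef()] on `fev1_L` (the starred AEX of reports). Default
#'   `FALSE`: missing FEV_PEF is an error, so the estimate is always an
#'   explicit opt-in.
#' @return A tibble with one row per input row: `value` (L\eqn{^2}/s), `kind`
#'   (e.g. `"approx2"`), and `used_estimated_fev_pef`.
#' @examples
#' aex_approx(data.frame(fvc_L = 4, pef_Ls = 6, fev_pef_L = 0.5), order = 1)
#' @export
aex_approx <- function(data, order = 4, use_estimated_fev_pef = FALSE) {
  order <- check_order(order)
  if (!is.data.frame(data)) data <- tibble::as_tibble(as.list(data))
  need <- c("fvc_L", "pef_Ls", aex_order_flows[[as.character(order)]])
  assert_columns(data, need, "landmark table")
  fev_pef <- if ("fev_pef_L" %in% names(data)) data$fev_pef_L else
    rep(NA_real_, nrow(data))
  estimated <- is.na(fev_pef)
  if (any(estimated)) {
    if (!isTRUE(use_estimated_fev_pef)) {
      abort(paste0("fev_pef_L is missing for ", sum(estimated), " row(s); ",
                   "set use_estimated_fev_pef = TRUE to use the FEV1-based ",
                   "estimate (starred AEX)"))
    }
    assert_columns(data, "fev1_L", "landmark table (for estimated FEV_PEF)")
    fev_pef[estimated] <- estimate_fev_pef(data$fev1_L[estimated])
  }
  fvc <- data$fvc_L
  pef <- data$pef_Ls
  bad_row <- function(cond, msg) {
    i <- which(cond)
    if (length(i)) abort(sprintf("%s (row %d)", msg, i[1]))
  }
  bad_row(!is.finite(fvc) | fvc <= 0, "fvc_L must be positive")
  bad_row(!is.finite(pef) | pef < 0, "pef_Ls must be non-negative")
  bad_row(!is.finite(fev_pef) | fev_pef <= 0 | fev_pef >= fvc,
          "fev_pef_L must lie strictly in (0, fvc_L)")
  fracs <- aex_order_fracs[[as.character(order)]]
  if (length(fracs)) {
    bad_row(fev_pef >= fvc * min(fracs),
            sprintf("degenerate geometry: fev_pef_L >= %.2g*fvc_L for AEX_%d",
                    min(fracs), order))
  }
  vol <- cbind(0, fev_pef, fvc %o% fracs, fvc)
  flo <- cbind(0, pef,
               as.matrix(data[aex_order_flows[[as.character(order)]]]),
               0)
  bad_row(rowSums(flo < 0) > 0, "instantaneous flows must be non-negative")
  m <- ncol(vol)
  area <- rowSums((vol[, -1, drop = FALSE] - vol[, -m, drop = FALSE]) *
                    (flo[, -1, drop = FALSE] + flo[, -m, drop = FALSE]) / 2)
  tibble::tibble(
    value = unname(area),
    kind = paste0("approx", order),
    used_estimated_fev_pef = unname(estimated)
  )
}

#' Add AEX approximation columns to a cohort table
#'
#' Convenience wrapper around [aex_approx()] for pipelines: appends columns
#' `aex1` ... `aex4` (and `aex_fev_pef_estimated`) to the input.
#'
#' @inheritParams aex_approx
#' @param orders Which approximation orders to compute (subset of 1:4).
#' @return The input data with one `aex<k>` column per requested order.
#' @export
add_aex <- function(data, orders = 1:4, use_estimated_fev_pef = FALSE) {
  stopifnot(all(orders %in% 1:4))
  out <- tibble::as_tibble(data)
  est <- NULL
  for (k in sort(unique(orders))) {
    res <- aex_approx(data, order = k,
                      use_estimated_fev_pef = use_estimated_fev_pef)
    out[[paste0("aex", k)]] <- res$value
    est <- res$used_estimated_fev_pef
  }
  out$aex_fev_pef_estimated <- est
  out
}
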