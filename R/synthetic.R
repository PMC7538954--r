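#' Cohort specification for the synthetic spirometry generator
#'
#' A cohort spec bundles the demographic marginals (gender/race mix, age,
#' height, weight distributions), the structural log-linear surface linking
#' anthropometry to FVC and PEF, the flow-ratio chains that produce FEV1 and
#' FEF25/50/75, lognormal noise scales, and the convexity of the scooped
#' expiratory curve. Two presets emulating large adult normal-spirometry
#' populations ship with the package (see [cleveland_like_spec()] and
#' [madrid_like_spec()]); their structural coefficients are synthetic,
#' documented defaults, not estimates from any real cohort.
#'
#' @param x A named list with the fields shown in
#'   `system.file("extdata", "cleveland_like.yaml", package = "aexref")`.
#' @return An object of class `aex_cohort_spec`.
#' @export
cohort_spec <- function(x) {
  req <- c("name", "n", "fraction_female", "fraction_black", "age", "height",
           "weight", "reference", "surface", "ratios", "fev_pef", "noise",
           "shape")
  miss <- setdiff(req, names(x))
  if (length(miss)) {
    abort(sprintf("cohort spec is missing field(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (x$n < 1) abort("cohort spec: n must be >= 1")
  for (p in c("fraction_female", "fraction_black")) {
    if (x[[p]] < 0 || x[[p]] > 1) abort(sprintf("%s must be in [0, 1]", p))
  }
  for (d in list(x$age, x$height$female, x$height$male)) {
    if (is.null(d$mean) || is.null(d$sd) || d$sd <= 0) {
      abort("age/height distributions need mean and sd > 0")
    }
  }
  for (r in x$ratios) {
    if (r$min >= r$max || r$sd < 0) abort("ratio bounds must satisfy min < max, sd >= 0")
  }
  structure(x, class = "aex_cohort_spec")
}

#' @export
print.aex_cohort_spec <- function(x, ...) {
  cat(sprintf("<aex_cohort_spec> %s: n = %d, %.0f%% female, %.0f%% black\n",
              x$name, x$n, 100 * x$fraction_female, 100 * x$fraction_black))
  cat(sprintf("  age %.0f +/- %.0f y; height F %.0f / M %.0f cm; shape %.2g\n",
              x$age$mean, x$age$sd, x$height$female$mean, x$height$male$mean,
              x$shape))
  invisible(x)
}

#' Read a cohort spec from a YAML file
#' @param path Path to a YAML cohort spec.
#' @return An `aex_cohort_spec`.
#' @export
read_cohort_spec <- function(path) {
  if (!file.exists(path)) abort(sprintf("cohort spec file not found: %s", path))
  cohort_spec(yaml::read_yaml(path))
}

load_preset <- function(name, n = NULL) {
  path <- system.file("extdata", paste0(name, ".yaml"), package = "aexref")
  spec <- read_cohort_spec(path)
  if (!is.null(n)) spec$n <- as.integer(n)
  spec
}

#' Packaged synthetic cohort presets
#'
#' `cleveland_like_spec()` emulates a large, mixed-race US clinical cohort
#' (n = 3111, ~66% women, 87% White / 13% Black, age 53 +/- 15 y, height
#' 166 +/- 10 cm, weight 82 +/- 20 kg); `madrid_like_spec()` emulates a small
#' elderly all-White European volunteer cohort (n = 457, 61% women, age
#' 73 +/- 5 y, height 158 +/- 9 cm, weight 70 +/- 12 kg).
#'
#' @param n Optional override of the preset cohort size.
#' @return An `aex_cohort_spec`.
#' @export
cleveland_like_spec <- function(n = NULL) load_preset("cleveland_like", n)

#' @rdname cleveland_like_spec
#' @export
madrid_like_spec <- function(n = NULL) load_preset("madrid_like", n)

#' Strip all stochastic components from a cohort spec
#'
#' Sets every noise scale and ratio SD to zero, so generated landmarks are an
#' exact deterministic function of the drawn anthropometry. Used to verify
#' that regression on a generated cohort recovers the structural coefficients.
#'
#' @param spec An `aex_cohort_spec`.
#' @return The spec with all noise terms zeroed.
#' @export
noiseless_spec <- function(spec) {
  spec$noise <- lapply(spec$noise, function(z) 0)
  spec$ratios <- lapply(spec$ratios, function(r) { r$sd <- 0; r })
  spec$fev_pef$sd <- 0
  spec
}

# exact inverse-cdf sampler for a truncated normal; errors if the retained
# mass is under 50% (an infeasible spec rather than a sampling problem)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi - plo < 0.5) {
    abort(sprintf(paste0("infeasible cohort spec: truncation [%.3g, %.3g] ",
                         "keeps only %.0f%% of N(%.3g, %.3g)"),
                  lo, hi, 100 * (phi - plo), mean, sd))
  }
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

#' Structural design matrix of the synthetic surface
#'
#' Returns the covariate transforms the generator's log-linear surface is
#' built on: height and age centered at the spec's reference values and
#' scaled to 10-cm / 10-year units, a quadratic age term, gender and race
#' indicators, a gender-by-height interaction, and weight in 10-kg units.
#' Regressing `log(fvc_L)` (or `log(pef_Ls)`) on these columns recovers the
#' spec's surface coefficients exactly when the spec is noiseless.
#'
#' @param data A cohort table with `gender`, `race`, `age_y`, `height_cm`,
#'   `weight_kg`.
#' @param spec The `aex_cohort_spec` whose reference values to use.
#' @return A tibble with columns `height`, `age`, `age2`, `male`, `black`,
#'   `male_height`, `weight`.
#' @export
surface_design <- function(data, spec) {
  assert_columns(data, c("gender", "race", "age_y", "height_cm", "weight_kg"),
                 "cohort table")
  h <- (data$height_cm - spec$reference$height) / 10
  a <- (data$age_y - spec$reference$age) / 10
  male <- as.numeric(data$gender == "male")
  tibble::tibble(
    height = h, age = a, age2 = a^2, male = male,
    black = as.numeric(data$race == "black"),
    male_height = male * h,
    weight = (data$weight_kg - spec$reference$weight) / 10
  )
}

surface_eta <- function(design, coefs) {
  coefs$intercept +
    coefs$height * design$height + coefs$age * design$age +
    coefs$age2 * design$age2 + coefs$male * design$male +
    coefs$black * design$black + coefs$male_height * design$male_height +
    coefs$weight * design$weight
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# mean value of the scooped interpolant g(t) on [0,1]; convex (below the
# identity) on ascending segments, concave (above it) on descending ones, so
# the curve lies below every chord. s -> 0 recovers the straight chord.
scoop_mean_factor <- function(s, ascending) {
  if (s < 1e-8) return(0.5)
  if (ascending) 1 / s - 1 / (expm1(s)) else 1 / (1 - exp(-s)) - 1 / s
}

scoop_g <- function(t, s, ascending) {
  if (s < 1e-8) return(t)
  if (ascending) expm1(s * t) / expm1(s) else (1 - exp(-s * t)) / (1 - exp(-s))
}

# areas under the scooped curve through the six landmark nodes, vectorized
scooped_area <- function(vol, flo, shape) {
  m <- ncol(vol)
  asc_fac <- scoop_mean_factor(shape, ascending = TRUE)
  des_fac <- scoop_mean_factor(shape, ascending = FALSE)
  area <- 0
  for (j in seq_len(m - 1)) {
    f1 <- flo[, j]; f2 <- flo[, j + 1]
    fac <- ifelse(f2 >= f1, asc_fac, des_fac)
    area <- area + (vol[, j + 1] - vol[, j]) * (f1 + (f2 - f1) * fac)
  }
  area
}

#' Generate a synthetic spirometry cohort
#'
#' Draws anthropometry from truncated normals (+/- 4 SD, positive), builds
#' the spirometric landmarks from the spec's structural log-linear surface
#' with multiplicative lognormal noise, enforces per-row physiologic
#' consistency (FEV1/FVC in \[0.70, 0.95\], FEF25 >= FEF50 >= FEF75,
#' 0 < FEV_PEF < 0.25 FVC), and computes a measured AEX as the exact area of
#' a scooped (convex, below-chord) curve through all six landmark nodes, with
#' small multiplicative noise.
#'
#' @param spec An `aex_cohort_spec` (see [cleveland_like_spec()]).
#' @param seed Integer seed; the whole cohort is deterministic given it.
#' @param n Optional override of `spec$n`.
#' @return A tibble with columns `cohort`, `gender`, `race`, `age_y`,
#'   `height_cm`, `weight_kg`, the landmark columns `fvc_L`, `fev1_L`,
#'   `pef_Ls`, `fev_pef_L`, `fef25_Ls`, `fef50_Ls`, `fef75_Ls`, and the
#'   measured `aex` (L\eqn{^2}/s).
#' @examples
#' cohort <- generate_cohort(cleveland_like_spec(n = 100), seed = 1)
#' @export
generate_cohort <- function(spec, seed, n = NULL) {
  if (!inherits(spec, "aex_cohort_spec")) spec <- cohort_spec(spec)
  n <- as.integer(n %||% spec$n)
  with_seed(seed, {
    gender <- ifelse(stats::runif(n) < spec$fraction_female, "female", "male")
    race <- ifelse(stats::runif(n) < spec$fraction_black, "black", "white")
    age_lo <- max(spec$age$min %||% 0, spec$age$mean - 4 * spec$age$sd)
    age <- rtruncnorm(n, spec$age$mean, spec$age$sd,
                      lo = age_lo, hi = spec$age$mean + 4 * spec$age$sd)
    height <- numeric(n)
    for (g in c("female", "male")) {
      hd <- spec$height[[g]]
      idx <- gender == g
      height[idx] <- rtruncnorm(sum(idx), hd$mean, hd$sd,
                                lo = max(0, hd$mean - 4 * hd$sd),
                                hi = hd$mean + 4 * hd$sd)
    }
    h_overall <- spec$fraction_female * spec$height$female$mean +
      (1 - spec$fraction_female) * spec$height$male$mean
    wres <- rtruncnorm(n, 0, spec$weight$sd_resid,
                       lo = -4 * spec$weight$sd_resid,
                       hi = 4 * spec$weight$sd_resid)
    weight <- pmax(spec$weight$mean +
                     spec$weight$beta_height * (height - h_overall) + wres, 30)

    cohort <- tibble::tibble(
      cohort = spec$name, gender = gender, race = race,
      age_y = age, height_cm = height, weight_kg = weight
    )
    des <- surface_design(cohort, spec)
    fvc <- exp(surface_eta(des, spec$surface$fvc) +
                 stats::rnorm(n, 0, spec$noise$fvc))
    pef <- exp(surface_eta(des, spec$surface$pef) +
                 stats::rnorm(n, 0, spec$noise$pef))
    ratio <- function(r) {
      clamp(r$base + r$age_slope * des$age + stats::rnorm(n, 0, r$sd),
            r$min, r$max)
    }
    fev1 <- fvc * ratio(spec$ratios$fev1_fvc)
    fef25 <- pef * ratio(spec$ratios$fef25_pef)
    fef50 <- fef25 * ratio(spec$ratios$fef50_fef25)
    fef75 <- fef50 * ratio(spec$ratios$fef75_fef50)
    fp <- spec$fev_pef
    fev_pef <- clamp(fp$intercept + fp$slope * fev1 + stats::rnorm(n, 0, fp$sd),
                     fp$min_L, fp$max_frac * fvc)

    vol <- cbind(0, fev_pef, 0.25 * fvc, 0.5 * fvc, 0.75 * fvc, fvc)
    flo <- cbind(0, pef, fef25, fef50, fef75, 0)
    aex <- scooped_area(vol, flo, spec$shape) *
      exp(stats::rnorm(n, 0, spec$noise$aex))

    cohort$fvc_L <- fvc
    cohort$fev1_L <- fev1
    cohort$pef_Ls <- pef
    cohort$fev_pef_L <- fev_pef
    cohort$fef25_Ls <- fef25
    cohort$fef50_Ls <- fef50
    cohort$fef75_Ls <- fef75
    cohort$aex <- aex
    cohort
  })
}

#' Sample a scooped flow-volume trace through landmark nodes
#'
#' Builds a dense flow-volume curve through the six landmark nodes
#' ((0,0), (FEV_PEF, PEF), the three quartile flows, (FVC, 0)) using
#' exponential-in-volume segments: for `shape > 0` the curve lies strictly
#' below every chord between consecutive nodes (the scooped expiratory
#' pattern); `shape = 0` reproduces the straight polyline of [aex_approx()]
#' with `order = 4`.
#'
#' @param landmarks One test's landmarks (one-row data frame or named list).
#' @param shape Non-negative convexity parameter (exponential decay rate).
#' @param n_points Number of sampled points (>= 50); node volumes are always
#'   included so the trace passes through the landmarks exactly.
#' @param seed Optional seed for the volume-grid jitter; `NULL` (default)
#'   gives an unjittered uniform grid.
#' @return A tibble of class `aex_fv_curve` with columns `volume_L`,
#'   `flow_L_s`.
#' @export
make_flow_volume_trace <- function(landmarks, shape = 2, n_points = 200,
                                   seed = NULL) {
  assert_number(shape, "shape", lower = 0)
  if (n_points < 50) abort("`n_points` must be >= 50")
  nodes <- aex_nodes(landmarks, order = 4)
  nv <- nodes$volume
  nf <- nodes$flow
  fvc <- nv[length(nv)]
  v <- with_seed(seed, {
    grid <- seq(0, fvc, length.out = n_points)
    if (!is.null(seed)) {
      step <- fvc / (n_points - 1)
      grid[-c(1, n_points)] <- grid[-c(1, n_points)] +
        stats::runif(n_points - 2, -0.3, 0.3) * step
    }
    sort(unique(c(grid, nv)))
  })
  seg <- findInterval(v, nv, rightmost.closed = TRUE)
  t <- (v - nv[seg]) / (nv[seg + 1] - nv[seg])
  f <- numeric(length(v))
  for (j in seq_len(length(nv) - 1)) {
    idx <- seg == j
    if (!any(idx)) next
    asc <- nf[j + 1] >= nf[j]
    f[idx] <- nf[j] + (nf[j + 1] - nf[j]) * scoop_g(t[idx], shape, asc)
  }
  f[1] <- 0
  f[length(f)] <- 0
  out <- tibble::tibble(volume_L = v, flow_L_s = pmax(f, 0))
  class(out) <- c("aex_fv_curve", class(out))
  out
}
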