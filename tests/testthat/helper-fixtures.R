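# Random but physiologically ordered landmark sets: peak early, quartile
# flows decreasing, so every AEX order is computable.
random_landmarks <- function(n) {
  fvc <- runif(n, 2, 6)
  pef <- runif(n, 4, 10)
  fef25 <- pef * runif(n, 0.7, 0.95)
  fef50 <- fef25 * runif(n, 0.5, 0.8)
  fef75 <- fef50 * runif(n, 0.2, 0.6)
  tibble::tibble(
    fvc_L = fvc, fev1_L = 0.8 * fvc, pef_Ls = pef,
    fev_pef_L = runif(n, 0.05, 0.2) * fvc,
    fef25_Ls = fef25, fef50_Ls = fef50, fef75_Ls = fef75
  )
}

# dense piecewise-linear sampling of a node polyline, for the trapezoid oracle
sample_polyline <- function(nodes, n_points = 2000) {
  v <- sort(unique(c(seq(min(nodes$volume), max(nodes$volume),
                         length.out = n_points), nodes$volume)))
  tibble::tibble(
    volume_L = v,
    flow_L_s = approx(nodes$volume, nodes$flow, xout = v)$y
  )
}

# small cached cohorts shared across test files (generation is seeded, so
# caching only saves time, not determinism)
.fixture_env <- new.env(parent = emptyenv())
fixture_cohort <- function(n = 600, seed = 42, preset = cleveland_like_spec) {
  key <- paste0(deparse(substitute(preset))[1], "_", n, "_", seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(preset(n = n), seed = seed)
  }
  .fixture_env[[key]]
}
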