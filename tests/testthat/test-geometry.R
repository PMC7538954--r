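test_that("trapezoidal integration matches closed-form areas", {
  tri <- data.frame(volume_L = c(0, 0.5, 4), flow_L_s = c(0, 6, 0))
  expect_equal(integrate_flow_volume(tri), 12)

  flat <- data.frame(volume_L = 0:5, flow_L_s = rep(0, 6))
  expect_equal(integrate_flow_volume(flat), 0)

  v <- seq(0, 4, length.out = 10000)
  parab <- data.frame(volume_L = v, flow_L_s = v * (4 - v))
  expect_equal(integrate_flow_volume(parab), 32 / 3, tolerance = 1e-3 / (32 / 3))
})

test_that("integration validates its inputs and names the offending index", {
  bad_vol <- data.frame(volume_L = c(0, 2, 1), flow_L_s = c(0, 3, 0))
  expect_error(integrate_flow_volume(bad_vol), "index 3")
  neg <- data.frame(volume_L = c(0, 1, 2), flow_L_s = c(0, -1, 0))
  expect_error(integrate_flow_volume(neg), "negative flow at index 2")
  expect_error(integrate_flow_volume(data.frame(a = 1, b = 2)), "volume_L")
})

test_that("node sets follow the landmark definitions of each order", {
  lmk <- list(fvc = 4, pef = 6, fev_pef = 0.5, fef25 = 4, fef50 = 3,
              fef75 = 1.5)
  n1 <- aex_nodes(lmk, order = 1)
  expect_equal(n1$volume, c(0, 0.5, 4))
  expect_equal(n1$flow, c(0, 6, 0))
  n2 <- aex_nodes(lmk, order = 2)
  expect_equal(n2$volume, c(0, 0.5, 2, 4))
  expect_equal(n2$flow, c(0, 6, 3, 0))
  n4 <- aex_nodes(lmk, order = 4)
  expect_equal(n4$volume, c(0, 0.5, 1, 2, 3, 4))

  # a peak volume at or past the first quartile node is invalid data
  expect_error(aex_nodes(list(fvc = 4, pef = 6, fev_pef = 1.2, fef25 = 4,
                              fef50 = 3, fef75 = 1.5), order = 3),
               "degenerate")
})

test_that("polygon areas match the hand-computed decompositions", {
  expect_equal(
    aex_approx(data.frame(fvc_L = 4, pef_Ls = 6, fev_pef_L = 0.5), 1)$value,
    12
  )
  # a collinear interior node leaves the area unchanged
  expect_equal(
    aex_approx(data.frame(fvc_L = 4, pef_Ls = 6, fev_pef_L = 0.5,
                          fef50_Ls = 6 * (4 - 2) / (4 - 0.5)), 2)$value,
    12
  )
  expect_equal(
    aex_approx(data.frame(fvc_L = 4, pef_Ls = 6, fev_pef_L = 0.5,
                          fef25_Ls = 4, fef50_Ls = 3, fef75_Ls = 1.5),
               4)$value,
    10.5
  )
})

test_that("aex_approx equals trapezoidal integration of its node polyline", {
  set.seed(101)
  lms <- random_landmarks(50)
  for (k in 1:4) {
    res <- aex_approx(lms, order = k)
    for (i in c(1, 17, 50)) {
      oracle <- integrate_flow_volume(
        sample_polyline(aex_nodes(lms[i, ], order = k))
      )
      expect_equal(res$value[i], oracle, tolerance = 1e-9)
    }
  }
})

test_that("area responds to node insertion, scaling and zero flow as geometry dictates", {
  set.seed(7)
  lms <- random_landmarks(60)
  a1 <- aex_approx(lms, order = 1)$value
  # chord flow at mid-volume of the order-1 polyline
  chord <- lms$pef_Ls * (lms$fvc_L - 0.5 * lms$fvc_L) /
    (lms$fvc_L - lms$fev_pef_L)
  below <- lms
  below$fef50_Ls <- 0.8 * chord
  above <- lms
  above$fef50_Ls <- pmin(1.2 * chord, lms$pef_Ls)
  expect_true(all(aex_approx(below, 2)$value < a1))
  expect_true(all(aex_approx(above, 2)$value > a1))

  # scale equivariance in flows and in volumes
  scaled_f <- dplyr::mutate(lms, dplyr::across(dplyr::ends_with("_Ls"), ~ 3 * .x))
  expect_equal(aex_approx(scaled_f, 4)$value, 3 * aex_approx(lms, 4)$value)
  scaled_v <- dplyr::mutate(lms, dplyr::across(dplyr::ends_with("_L"), ~ 2 * .x))
  expect_equal(aex_approx(scaled_v, 4)$value, 2 * aex_approx(lms, 4)$value)

  zero <- dplyr::mutate(lms, dplyr::across(dplyr::ends_with("_Ls"), ~ 0 * .x))
  expect_true(all(aex_approx(zero, 4)$value == 0))
})

test_that("the FEV1-based FEV_PEF estimate reproduces printed group means", {
  expect_equal(estimate_fev_pef(2.2), 0.157174 + 0.176439 * 2.2)
  expect_equal(round(estimate_fev_pef(2.2), 1), 0.5)  # elderly cohort mean
  expect_equal(round(estimate_fev_pef(2.8), 1), 0.7)  # clinical cohort mean
  expect_equal(estimate_fev_pef(0), 0.157174)
  expect_error(estimate_fev_pef(-1), "non-negative")
})

test_that("estimated FEV_PEF is an explicit opt-in recorded per row", {
  d <- data.frame(fvc_L = c(4, 4), fev1_L = c(2.8, 2.8), pef_Ls = c(6, 6),
                  fev_pef_L = c(0.5, NA), fef50_Ls = c(3, 3))
  expect_error(aex_approx(d, 2), "use_estimated_fev_pef")
  res <- aex_approx(d, 2, use_estimated_fev_pef = TRUE)
  expect_equal(res$used_estimated_fev_pef, c(FALSE, TRUE))
  expect_true(all(res$value > 0))
})
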