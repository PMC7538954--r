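test_that("stratum moments use the sample definition and guard small strata", {
  d <- data.frame(gender = "female", race = "white", aex = c(2, 4))
  st <- fit_stratum_stats(d)
  expect_equal(st$mean, 3)
  expect_equal(st$sd, sqrt(2))
  expect_equal(st$n, 2L)

  single <- data.frame(gender = c("female", "male"), race = "white",
                       aex = c(2, 3))
  expect_error(fit_stratum_stats(single), "fewer than 2")
})

test_that("stratum moments recover generating parameters at scale", {
  set.seed(17)
  d <- data.frame(gender = "female", race = "white",
                  aex = rnorm(1e4, 11.9, 6.8))
  st <- fit_stratum_stats(d)
  expect_lt(abs(st$mean - 11.9), 0.2)
  expect_lt(abs(st$sd - 6.8), 0.15)
})

test_that("z-scores, their inverse and the LLN threshold are consistent", {
  st <- list(mean = 11.9, sd = 6.8)
  expect_equal(z_score(11.9, st), 0)
  expect_equal(z_score(11.9 - 1.645 * 6.8, st), -1.645)
  expect_equal(z_score(5.1, st), -1, tolerance = 0.01)
  # inverse round-trip
  x <- c(2.2, 9.7, 25.1)
  expect_equal(st$mean + z_score(x, st) * st$sd, x, tolerance = 1e-12)

  expect_false(is_below_lln(-1.645))   # strict inequality at the boundary
  expect_true(is_below_lln(-1.70))
  expect_equal(round(qnorm(0.05), 3), -1.645)

  co <- fixture_cohort(n = 600, seed = 5)
  st2 <- fit_stratum_stats(co)
  zd <- add_z_scores(co, st2)
  by_stratum <- dplyr::summarise(dplyr::group_by(zd, gender, race),
                                 m = mean(z), s = sd(z))
  expect_equal(by_stratum$m, rep(0, nrow(by_stratum)), tolerance = 1e-10)
  expect_equal(by_stratum$s, rep(1, nrow(by_stratum)), tolerance = 1e-10)
})

test_that("stratified OLS is exact on noiseless data and rejects rank deficiency", {
  set.seed(23)
  d <- data.frame(gender = rep(c("female", "male"), each = 30),
                  race = "white", age_y = runif(60, 20, 80))
  d$height_cm <- 160
  d$aex <- 2 + 3 * d$age_y
  fit <- fit_stratified_linear(d, predictors = "age_y")
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "(Intercept)"], c(2, 2))
  expect_equal(td$estimate[td$term == "age_y"], c(3, 3))
  expect_equal(glance(fit)$r2, c(1, 1))

  expect_error(
    fit_stratified_linear(d, predictors = c("age_y", "height_cm")),
    "height_cm"
  )
})

test_that("stratified fits are permutation-invariant and route predictions by stratum", {
  co <- fixture_cohort(n = 600, seed = 5)
  fit1 <- fit_stratified_linear(co)
  fit2 <- fit_stratified_linear(co[sample(nrow(co)), ])
  expect_equal(tidy(fit1)$estimate, tidy(fit2)$estimate)
  expect_equal(predict(fit1, co[1:10, ]), predict(fit2, co[1:10, ]))

  odd <- co[1, ]
  odd$race <- "martian"
  expect_error(predict(fit1, odd), "martian")
})

test_that("backward elimination drops null predictors and keeps real ones", {
  set.seed(31)
  d <- data.frame(gender = "female", race = "white",
                  age_y = rnorm(300, 50, 10), height_cm = rnorm(300, 165, 7),
                  weight_kg = rnorm(300, 80, 15))
  d$aex <- 5 + 0.4 * d$height_cm - 0.1 * d$age_y + rnorm(300, 0, 1)
  fit <- fit_stratified_linear(d, backward = TRUE)
  expect_setequal(fit$fits[[1]]$predictors, c("age_y", "height_cm"))
})

test_that("penalty-free and penalty-dominated limits behave as OLS and the mean", {
  co <- fixture_cohort(n = 400, seed = 19)
  ridge0 <- fit_regularized(co, penalty = "ridge", lambda = 0)
  ols <- lm(aex ~ age_y + height_cm + weight_kg, data = co)
  expect_equal(predict(ridge0, co), unname(predict(ols, co)),
               tolerance = 1e-8)

  lasso_inf <- fit_regularized(co, penalty = "lasso", lambda = 1e6)
  expect_equal(predict(lasso_inf, co), rep(mean(co$aex), nrow(co)),
               tolerance = 1e-6)
})

test_that("outcome transforms fit on their scale and predict on the original one", {
  co <- fixture_cohort(n = 400, seed = 19)
  for (tr in c("log", "gamma")) {
    f <- fit_regularized(co, transform = tr, penalty = "none")
    p <- predict(f, co)
    expect_true(all(p > 0))
    expect_lt(eval_metrics(observed = co$aex, predicted = p)$rase,
              sd(co$aex))  # beats the trivial mean predictor
  }
  neg <- co
  neg$aex[1] <- -1
  expect_error(fit_regularized(neg, transform = "log"), "positive")
})

test_that("double lasso screens out null predictors", {
  wins <- 0
  for (s in 1:60) {
    set.seed(s)
    n <- 1000
    d <- data.frame(matrix(rnorm(n * 6), n))
    names(d) <- paste0("x", 1:6)
    d$y <- 1 + 2 * d$x1 - 1.5 * d$x2 + rnorm(n)
    f <- fit_regularized(d, outcome = "y", predictors = paste0("x", 1:6),
                         penalty = "double-lasso", validation = "holdback",
                         seed = s)
    wins <- wins + all(!paste0("x", 3:6) %in% f$selected)
  }
  expect_gte(wins / 60, 0.9)
})

test_that("equation sets evaluate formulas, delegate composite targets and flag extrapolation", {
  const_eq <- equation_set(list(
    name = "toy_constant",
    strata = list(list(gender = "female", race = "white", target = "AEX",
                       intercept = 10, terms = list()))
  ))
  subj <- data.frame(gender = "female", race = "white", age_y = 50,
                     height_cm = 165, weight_kg = 70)
  expect_equal(apply_equation_set(subj, const_eq, "AEX")$value, 10)

  mk <- function(target, intercept) {
    list(gender = "female", race = "white", target = target,
         intercept = intercept, terms = list(), valid_age = c(18, 90))
  }
  toy <- equation_set(list(name = "toy_aex1", strata = list(
    mk("FVC", 4), mk("PEF", 6), mk("FEV_PEF", 0.5)
  )))
  res <- apply_equation_set(subj, toy, "AEX1")
  expect_equal(res$value, 12)  # the polygonal oracle value
  expect_false(res$extrapolated)

  old <- subj
  old$age_y <- 99
  expect_warning(res2 <- apply_equation_set(old, toy, "AEX1"),
                 "validity range")
  expect_true(res2$extrapolated)

  expect_error(apply_equation_set(subj, toy, "FEF50"), "no FEF50 formula")

  # affine terms and log scale
  aff <- equation_set(list(name = "toy_affine", strata = list(
    list(gender = "female", race = "white", target = "FVC", intercept = 1,
         terms = list(list(var = "height", power = 1, coef = 0.02),
                      list(var = "age", power = 2, coef = -1e-4)),
         scale = "log")
  )))
  expect_equal(apply_equation_set(subj, aff, "FVC")$value,
               exp(1 + 0.02 * 165 - 1e-4 * 2500))
})

test_that("the packaged equation-set template parses", {
  tmpl <- read_equation_set(system.file("extdata",
                                        "equation_set_template.json",
                                        package = "aexref"))
  expect_s3_class(tmpl, "aex_equation_set")
  expect_true(all(c("gender", "race", "target") %in% names(tmpl$strata)))
})
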