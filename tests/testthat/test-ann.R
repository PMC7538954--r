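test_that("partitions hit their scheme proportions and are seed-deterministic", {
  p <- make_partition(100, "holdback33", seed = 4)
  expect_equal(as.integer(table(p)[c("train", "test")]), c(67L, 33L))
  p2 <- make_partition(1000, "pooled-50-25-25", seed = 4)
  expect_equal(as.integer(table(p2)), c(500L, 250L, 250L))
  expect_identical(make_partition(123, "holdback33", seed = 9),
                   make_partition(123, "holdback33", seed = 9))
  expect_false(identical(make_partition(123, "holdback33", seed = 9),
                         make_partition(123, "holdback33", seed = 10)))

  cohort <- rep(c("derivation", "external"), c(90, 30))
  pe <- make_partition(120, "external", seed = 1, cohort = cohort)
  expect_true(all(pe[cohort == "external"] == "validation"))
  expect_equal(sum(pe == "test"), 30)  # 33% of the 90 derivation rows
  expect_error(make_partition(100, "external", seed = 1), "cohort")
  expect_error(make_partition(3, "holdback33"), ">= 4")
})

test_that("analytic gradients match finite differences for both losses", {
  set.seed(1)
  X <- matrix(rnorm(48), 12, 4)
  y <- rnorm(12)
  arch <- ann_architecture(c(2, 1, 2), c(1, 2, 1))
  shapes <- aexref:::ann_shapes(4, arch)
  np <- sum(vapply(shapes, prod, numeric(1)))
  par <- runif(np, -0.5, 0.5)
  for (cfg in list(list(loss = "squared", delta = NA),
                   list(loss = "robust", delta = 0.4))) {
    got <- aexref:::ann_obj_grad(par, X, y, arch, shapes, 0.02, cfg$loss,
                                 cfg$delta)
    fd <- vapply(seq_len(np), function(i) {
      e <- rep(0, np); e[i] <- 1e-6
      (aexref:::ann_obj_grad(par + e, X, y, arch, shapes, 0.02, cfg$loss,
                             cfg$delta)$value -
         aexref:::ann_obj_grad(par - e, X, y, arch, shapes, 0.02, cfg$loss,
                               cfg$delta)$value) / 2e-6
    }, numeric(1))
    expect_equal(got$grad, fd, tolerance = 1e-5)
  }
})

test_that("a linear-only network at zero penalty reproduces the OLS fit", {
  set.seed(6)
  d <- data.frame(gender = "female", race = "white",
                  age_y = runif(120, 20, 80))
  d$aex <- 1 + 2 * d$age_y + rnorm(120, 0, 0.5)
  f <- train_ann(d, predictors = "age_y",
                 architecture = ann_architecture(c(0, 3, 0)), lambda = 0,
                 seed = 2)
  ols <- lm(aex ~ age_y, data = d)
  expect_lt(abs(f$metrics$rase - rase(resid(ols))), 1e-4)
  expect_equal(predict(f, d), unname(fitted(ols)), tolerance = 1e-3)
})

test_that("an overwhelming penalty collapses predictions toward the mean", {
  co <- fixture_cohort(n = 200, seed = 44)
  f <- train_ann(co, lambda = 1e7, seed = 1, max_iter = 500)
  expect_lt(sd(predict(f, co)), 0.05 * sd(co$aex))
})

test_that("training is bit-deterministic given the seed and permutation-equivariant in prediction", {
  co <- fixture_cohort(n = 200, seed = 44)
  f1 <- train_ann(co, seed = 11, max_iter = 300)
  f2 <- train_ann(co, seed = 11, max_iter = 300)
  expect_identical(f1$weights, f2$weights)
  expect_identical(predict(f1, co), predict(f2, co))

  perm <- sample(nrow(co))
  expect_equal(predict(f1, co[perm, ]), predict(f1, co)[perm])

  odd <- co[1, ]
  odd$gender <- "other"
  expect_error(predict(f1, odd), "unseen level")
  expect_error(train_ann(dplyr::mutate(co, aex = 1), seed = 1), "constant")
})

test_that("z-score output models reconstruct AEX through stratum moments", {
  co <- fixture_cohort(n = 400, seed = 19)
  st <- fit_stratum_stats(co)
  f <- train_ann(co, output = "zscore", stratum_stats = st, seed = 3,
                 max_iter = 400)
  z <- predict(f, co, type = "zscore")
  x <- predict(f, co)  # reconstructed
  joined <- dplyr::left_join(co, st, by = c("gender", "race"))
  expect_equal(x, joined$mean + z * joined$sd, tolerance = 1e-12)

  # the hand round-trip: z = -1 in a stratum with mean 11.9, sd 6.8
  expect_equal(11.9 + (-1) * 6.8, 5.1)
})

test_that("boosting degenerates to a single fit and tightens training error over stages", {
  co <- fixture_cohort(n = 150, seed = 21)
  single <- train_ann(co, architecture = ann_architecture(c(2, 2, 2)),
                      lambda = 1e-3, seed = 5, max_iter = 2000)
  boost1 <- train_boosted(co, architecture = ann_architecture(c(2, 2, 2)),
                          n_models = 1, learning_rate = 1, lambda = 1e-3,
                          seed = 5, max_iter = 2000)
  # both routes minimize the identical objective; BFGS lands within its
  # convergence tolerance of the same optimum
  expect_equal(boost1$components[[1]]$objective, single$objective,
               tolerance = 1e-4)
  expect_equal(predict(boost1, co), predict(single, co), tolerance = 1e-3)

  boost <- train_boosted(co, n_models = 30, learning_rate = 0.1,
                         seed = 5, max_iter = 60)
  expect_lte(boost$rase_path[30], boost$rase_path[10])
  expect_lte(boost$rase_path[30], boost$rase_path[1])
})

test_that("model serialization round-trips predictions exactly", {
  co <- fixture_cohort(n = 200, seed = 44)
  f <- train_ann(co, seed = 2, max_iter = 300)
  path <- withr::local_tempfile(fileext = ".json")
  write_model(f, path)
  g <- read_model(path)
  expect_equal(predict(g, co), predict(f, co), tolerance = 1e-12)

  fz <- train_ann(co, output = "zscore", seed = 2, max_iter = 200)
  write_model(fz, path)
  gz <- read_model(path)
  expect_equal(predict(gz, co), predict(fz, co), tolerance = 1e-12)
})

test_that("total-effect shares normalize, localize and split as theory predicts", {
  co <- fixture_cohort(n = 300, seed = 50)
  preds <- c("gender", "race", "age_y", "height_cm", "weight_kg")

  only_height <- function(d) 2 * d$height_cm
  imp <- total_effects(only_height, co, predictors = preds,
                       n_resamples = 400, seed = 1)
  expect_equal(sum(imp$total_effect), 100, tolerance = 0.5)
  expect_gte(imp$total_effect[imp$factor == "height_cm"], 95)

  set.seed(2)
  ind <- data.frame(x1 = rnorm(400), x2 = rnorm(400))
  imp2 <- total_effects(function(d) d$x1 + d$x2, ind,
                        predictors = c("x1", "x2"), n_resamples = 1500,
                        seed = 3)
  expect_equal(imp2$total_effect, c(50, 50), tolerance = 5)

  expect_error(total_effects(only_height, co[1:30, ], predictors = preds),
               "at least 50")
  expect_error(total_effects(only_height, co, predictors = preds, k = 1e5),
               "`k`")
})

test_that("the ablation harness reports one consistent row per configuration", {
  co <- fixture_cohort(n = 300, seed = 50)
  part <- make_partition(nrow(co), "pooled-50-25-25", seed = 1)
  tab <- run_ablation(co, part,
                      grid = list(list(architecture = list(c(3, 3, 3)),
                                       lambda = 0, max_iter = 800)),
                      include_linear = TRUE, seed = 1)
  expect_equal(nrow(tab), 2)  # baseline + 1 config
  expect_true(all(c("r2_train", "rase_test", "aae_validation") %in%
                    names(tab)))
  # a flexible net at lambda = 0 does not trail the linear baseline on train
  expect_gte(tab$r2_train[2], tab$r2_train[1] - 1e-3)
  # df-corrected RMSE never undercuts RASE, and AAE never exceeds it
  expect_true(all(tab$rmse_train >= tab$rase_train - 1e-12))
  expect_true(all(tab$aae_train <= tab$rase_train + 1e-12))
  expect_error(run_ablation(co, part, grid = list()), "at least one")
})
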