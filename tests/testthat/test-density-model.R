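# synthetic regression table with covariate-named columns
synth_table <- function(n, seed, informative = "builtup_frac",
                        noise_sd = 0) {
  set.seed(seed)
  covs <- c("builtup_frac", "building_height", "ntl", "dist_road",
            "poi_density", "elevation", "slope", "water")
  tab <- as.data.frame(setNames(lapply(covs, function(x) runif(n)), covs))
  tab$density_total <- tab[[informative]] * 10 + rnorm(n, sd = noise_sd)
  tab$zone_id <- seq_len(n)
  tab
}

test_that("training-table densities are count over inhabited area", {
  cen <- data.frame(zone_id = 1:3, total = c(500, 0, 70),
                    a0_14 = c(100, 0, 10), a15_59 = c(300, 0, 40),
                    a60_64 = c(40, 0, 10), a65plus = c(60, 0, 10))
  cov <- data.frame(zone_id = 1:3, builtup_frac = c(0.5, 0.1, NA))
  ar <- data.frame(zone_id = 1:3, area_ha = c(25, 10, 7))
  expect_message(tab <- build_training_table(cen, cov, ar), "excluded")
  expect_equal(tab$density_total[tab$zone_id == 1], 20)
  expect_equal(tab$density_total[tab$zone_id == 2], 0)
  expect_false(3 %in% tab$zone_id)          # NA covariate row dropped

  # zero area with population: excluded with a warning
  ar2 <- ar; ar2$area_ha[1] <- 0
  expect_warning(tab2 <- build_training_table(cen, cov, ar2),
                 "zero inhabited area")
  expect_false(1 %in% tab2$zone_id)

  # synthetic landscape: densities equal census count / area per zone
  w <- small_world()
  tw <- build_training_table(w$census, w$covs, w$areas)
  i <- match(tw$zone_id, w$census$zone_id)
  j <- match(tw$zone_id, w$areas$zone_id)
  expect_equal(tw$density_total,
               w$census$total[i] / w$areas$area_ha[j], tolerance = 1e-12)
})

test_that("middle-99% filter drops exactly the distribution tails", {
  t1000 <- data.frame(density_total = sample(seq_len(1000)))
  expect_identical(nrow(filter_middle_99(t1000, "total")), 990L)

  tsame <- data.frame(density_total = rep(3.3, 250))
  expect_identical(nrow(filter_middle_99(tsame, "total")), 250L)

  set.seed(10)
  t400 <- data.frame(density_total = rnorm(400))
  got <- filter_middle_99(t400, "total")
  q <- quantile(t400$density_total, c(0.005, 0.995), type = 7)
  ora <- t400$density_total[t400$density_total > q[1] &
                              t400$density_total < q[2]]
  expect_identical(sort(got$density_total), sort(ora))

  expect_warning(small <- filter_middle_99(t400[1:50, , drop = FALSE],
                                           "total"), "skipped")
  expect_identical(nrow(small), 50L)
})

test_that("train/test split is seeded, disjoint and exhaustive", {
  tab <- synth_table(100, 1)
  sp <- split_train_test(tab, seed = 3)
  expect_identical(c(nrow(sp$train), nrow(sp$test)), c(85L, 15L))
  expect_identical(sort(c(sp$train$zone_id, sp$test$zone_id)),
                   tab$zone_id)
  expect_length(intersect(sp$train$zone_id, sp$test$zone_id), 0)

  sp7 <- split_train_test(synth_table(7, 2), seed = 9)
  expect_identical(c(nrow(sp7$train), nrow(sp7$test)), c(5L, 2L))

  sp2 <- split_train_test(tab, seed = 3)
  expect_identical(sp$train$zone_id, sp2$train$zone_id)
})

test_that("tuner searches the full candidate grid and is rerun-identical", {
  tab <- synth_table(60, 4, noise_sd = 0.5)
  m <- tune_and_fit(tab, "total", seed = 2, trees = c(20, 60),
                    depths = c(5, 10, 15))
  expect_identical(nrow(m$cv_table), 6L)
  expect_true(all(m$cv_table$cv_rmse > 0))
  expect_true(m$n_trees %in% c(20, 60) && m$max_depth %in% c(5, 10, 15))
  expect_equal(m$cv_rmse, min(m$cv_table$cv_rmse))

  m2 <- tune_and_fit(tab, "total", seed = 2, trees = c(20, 60),
                     depths = c(5, 10, 15))
  expect_identical(m$cv_table$cv_rmse, m2$cv_table$cv_rmse)
  expect_identical(m$importance, m2$importance)

  # ties break to fewer trees, then shallower depth
  grid <- expand.grid(n_trees = c(20, 60), max_depth = c(5, 10, 15),
                      KEEP.OUT.ATTRS = FALSE)
  grid$cv_rmse <- 1
  best <- grid[order(grid$cv_rmse, grid$n_trees, grid$max_depth), ][1, ]
  expect_identical(c(best$n_trees, best$max_depth), c(20, 5))
})

test_that("a noise-free single-covariate target is learned nearly exactly", {
  tab <- synth_table(500, 5, informative = "ntl", noise_sd = 0)
  m <- tune_and_fit(tab, "total", seed = 1, trees = c(150, 400),
                    depths = c(20, 40))
  expect_lt(m$cv_rmse, sd(tab$density_total) / 10)
  expect_identical(names(which.max(m$importance)), "ntl")
})

test_that("held-out metrics match their closed forms", {
  tab <- synth_table(200, 6, noise_sd = 0.3)
  sp <- split_train_test(tab, seed = 1)
  m <- tune_and_fit(sp$train, "total", seed = 1, trees = 100, depths = 20)
  ev <- evaluate_on_test(m, sp$test)
  pred <- predict(m$forest, sp$test, num.threads = 1)$predictions
  expect_equal(ev$r2, oracle_r2(sp$test$density_total, pred),
               tolerance = 1e-12)
  expect_equal(ev$rmse, sqrt(mean((pred - sp$test$density_total)^2)),
               tolerance = 1e-12)
  expect_error(evaluate_on_test(m, sp$test[0, ]), "empty")

  # degenerate definitions: perfect predictions give r2 = 1, rmse = 0;
  # predicting the mean gives r2 = 0
  expect_equal(oracle_r2(1:5, 1:5), 1)
  expect_equal(oracle_r2(1:5, rep(3, 5)), 0)
})

test_that("importances normalize and PDPs expose only real effects", {
  tab <- synth_table(300, 7, informative = "poi_density", noise_sd = 0.2)
  m <- tune_and_fit(tab, "total", seed = 3, trees = 200, depths = 20)
  expect_equal(sum(m$importance), 1, tolerance = 1e-9)
  expect_true(all(m$importance >= 0))
  expect_identical(names(which.max(m$importance)), "poi_density")

  ip <- importance_and_pdp(m, tab, n_points = 20)
  pd <- ip$pdp
  expect_identical(nrow(pd[pd$covariate == "poi_density", ]), 20L)
  rng_inf <- diff(range(pd$yhat[pd$covariate == "poi_density"]))
  rng_nul <- diff(range(pd$yhat[pd$covariate == "elevation"]))
  expect_gt(rng_inf, 0.5 * sd(tab$density_total))
  expect_lt(rng_nul, 0.05 * sd(tab$density_total))
})

test_that("per-group models are independent objects with their own tuning", {
  m <- small_models()
  fits <- m$fit$models
  expect_identical(sort(names(fits)), sort(POP_GROUPS))
  for (g in POP_GROUPS) expect_identical(fits[[g]]$group, g)
  # distinct forests, not one shared object
  expect_false(identical(fits$total$forest, fits$a0_14$forest))
})
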