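test_that("metrics follow their closed forms", {
  m <- age_metrics(c(50, 70), c(50, 70))
  expect_equal(m$mse, 0)
  expect_equal(m$mae_mean, 0)
  expect_equal(m$mae_sd, 0)
  # constant predictor at the mean of a symmetric pair {50, 70}
  m2 <- age_metrics(c(60, 60), c(50, 70))
  expect_equal(m2$mse, 100)
  expect_equal(m2$mae_mean, 10)
  expect_equal(m2$mae_sd, 0)
  # permutation invariance
  set.seed(1)
  p <- runif(20, 20, 90); a <- runif(20, 20, 90)
  i <- sample(20)
  expect_equal(age_metrics(p, a)$mse, age_metrics(p[i], a[i])$mse)
  expect_error(age_metrics(1:3, 1:4), "mismatch")
  mp <- mean_predictor_metrics(c(40, 60), c(50, 70))
  expect_equal(mp$mse, mean(c(0, 400)))
})

test_that("the learning-rate trace follows the step-decay schedule", {
  cfg <- train_config()
  expect_equal(lr_at_epoch(cfg, 1), 1e-3)
  expect_equal(lr_at_epoch(cfg, 80), 1e-3)
  expect_equal(lr_at_epoch(cfg, 81), 1e-4)
  expect_equal(lr_at_epoch(cfg, 160), 1e-4)
  expect_equal(lr_at_epoch(cfg, 161), 1e-5)
  expect_error(train_config(lr = 0), "lr")
})

test_that("zero-epoch training returns the initialized network untouched", {
  cache <- fixture_cache(n = 40, seed = 50)
  set.seed(51)
  g <- build_attianet(tiny_attia_config(), 1024)
  cfg <- train_config(epochs = 0, batch_size = 8, seed = 5,
                      init_output_bias = FALSE)
  fit <- train_fold(g, cache, fold = cache$fold[1], cfg)
  for (nm in names(g$layers))
    for (p in ecgage:::param_names(g$layers[[nm]]))
      expect_identical(fit$graph$layers[[nm]][[p]], g$layers[[nm]][[p]])
  expect_true(is.finite(fit$test$mse))
})

test_that("a constant-prediction stub yields the second-moment test MSE", {
  cache <- fixture_cache(n = 40, seed = 52)
  set.seed(53)
  g <- build_attianet(tiny_attia_config(), 1024)
  # zero all weights, set the output bias: the network predicts a constant
  for (nm in names(g$layers))
    for (p in ecgage:::param_names(g$layers[[nm]]))
      if (p != "gamma") g$layers[[nm]][[p]] <- g$layers[[nm]][[p]] * 0
  const <- 58
  g$layers$out$b <- const
  f <- sort(unique(cache$fold))[1]
  cfg <- train_config(epochs = 0, batch_size = 8, seed = 1,
                      init_output_bias = FALSE)
  fit <- train_fold(g, cache, f, cfg)
  idx <- which(cache$fold == f)
  expect_equal(fit$test$mse, mean((cache$age[idx] - const)^2),
               tolerance = 1e-10)
})

test_that("training is deterministic given a seed and learns the age signal", {
  cache <- fixture_cache(n = 80, seed = 54)
  cfg <- train_config(epochs = 3, batch_size = 16, lr = 0.01, seed = 9)
  set.seed(55); g1 <- build_attianet(reduced_attianet_config(), 1024)
  set.seed(55); g2 <- build_attianet(reduced_attianet_config(), 1024)
  f <- sort(unique(cache$fold))[1]
  fit1 <- train_fold(g1, cache, f, cfg)
  fit2 <- train_fold(g2, cache, f, cfg)
  expect_identical(fit1$test, fit2$test)
  expect_identical(fit1$history, fit2$history)
  expect_identical(fit1$graph$layers$fc1$W, fit2$graph$layers$fc1$W)
  # training reduced the loss against the first epoch
  expect_lt(min(fit1$history$val_mse), fit1$history$val_mse[1] + 1e-9)
})

test_that("the restored checkpoint is the minimum of the validation curve", {
  cache <- fixture_cache(n = 60, seed = 56)
  cfg <- train_config(epochs = 4, batch_size = 12, lr = 0.01, seed = 2)
  set.seed(57); g <- build_attianet(reduced_attianet_config(), 1024)
  f <- sort(unique(cache$fold))[1]
  fit <- train_fold(g, cache, f, cfg)
  expect_equal(fit$best_val_mse, min(fit$history$val_mse))
  expect_equal(fit$best_epoch, which.min(fit$history$val_mse))
})

test_that("random-crop training exercises the crop/pad path end to end", {
  co <- generate_cohort(30, rate = 100, duration = 10, seed = 80)
  cache <- cohort_cache(co$records, co$table)
  pol <- augment_policy("random_crop", crop_seconds = 8)
  cfg <- train_config(epochs = 1, batch_size = 8, lr = 0.01, seed = 81)
  set.seed(82)
  g <- build_attianet(tiny_attia_config(), 1024)
  fit <- train_fold(g, cache, fold = cache$fold[1], cfg, policy = pol)
  expect_true(is.finite(fit$test$mse))
  # evaluation used the deterministic first-8-s crop, padded to the grid
  idx <- which(cache$fold == fit$fold)
  b <- cache$signals[idx, , 1:800, drop = FALSE]
  bb <- array(0, dim = c(length(idx), 12, 1024))
  bb[, , 1:800] <- b
  expect_equal(fit$pred, predict(fit$graph, bb))
})

test_that("cross-validation averages the requested folds and is order-independent", {
  cache <- fixture_cache(n = 50, seed = 58)
  cfg <- train_config(epochs = 1, batch_size = 10, lr = 0.01, seed = 3)
  folds <- sort(unique(cache$fold))[1:2]
  builder <- function(len) build_attianet(tiny_attia_config(), len)
  cv <- cross_validate(builder, cache, 1024, cfg, folds = folds)
  expect_length(cv$fits, 2L)
  expect_equal(cv$mean_test_mse,
               mean(vapply(cv$fits, function(f) f$test$mse, numeric(1))))
  expect_error(cross_validate(builder, cache, 1024, cfg, folds = 42),
               "missing folds")
  # shuffling the cache row order leaves seeded results identical
  set.seed(59)
  perm <- sample(length(cache$record_id))
  cache2 <- ecgage:::cache_subset(cache, perm)
  cv2 <- cross_validate(builder, cache2, 1024, cfg, folds = folds)
  expect_equal(cv$mean_test_mse, cv2$mean_test_mse, tolerance = 1e-12)
  s <- summary(cv)
  expect_equal(nrow(s), 2L)
})
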