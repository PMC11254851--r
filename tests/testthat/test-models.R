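test_that("engine convolution matches a direct reference implementation", {
  set.seed(10)
  x <- matrix(rnorm(3 * 40), 3, 40)
  W <- matrix(rnorm(5 * 3 * 7), 5, 21)
  b <- rnorm(5)
  cube <- array(x, dim = c(3, 40, 1))
  got <- ecgage:::cpp_conv1d_fwd(cube, W, b, 7L, 1L, TRUE)[, , 1]
  expect_equal(got, reference_conv1d(x, W, b, 7), tolerance = 1e-12)
  # strided convolution
  got4 <- ecgage:::cpp_conv1d_fwd(cube, W, b, 7L, 4L, TRUE)[, , 1]
  expect_equal(got4, reference_conv1d(x, W, b, 7, stride = 4),
               tolerance = 1e-12)
})

test_that("analytic gradients match numerical differentiation", {
  set.seed(11)
  g <- build_attianet(tiny_attia_config(), 1024)
  x <- array(rnorm(2 * 12 * 1024), dim = c(2, 12, 1024))
  y <- c(40, 70)
  fw <- ecgage:::model_forward(g, x, training = TRUE)
  gr <- ecgage:::model_backward(g, 2 * (fw$pred - y) / 2, fw$caches)
  probe <- list(c("t1_conv", "W", 3), c("t2_conv", "W", 10),
                c("t1_bn", "gamma", 2), c("spatial_conv", "W", 5),
                c("fc1", "W", 17), c("out", "b", 1))
  for (p in probe) {
    i <- as.integer(p[3]); eps <- 1e-6
    gp <- g; gp$layers[[p[1]]][[p[2]]][i] <- gp$layers[[p[1]]][[p[2]]][i] + eps
    gm <- g; gm$layers[[p[1]]][[p[2]]][i] <- gm$layers[[p[1]]][[p[2]]][i] - eps
    lp <- mean((ecgage:::model_forward(gp, x, training = TRUE)$pred - y)^2)
    lm <- mean((ecgage:::model_forward(gm, x, training = TRUE)$pred - y)^2)
    num <- (lp - lm) / (2 * eps)
    ana <- gr[[p[1]]][[p[2]]][i]
    expect_lt(abs(num - ana) / max(1e-6, abs(num)), 1e-4)
  }
  set.seed(12)
  gr2 <- build_resnet1d(tiny_resnet_config(), 1024)
  fw2 <- ecgage:::model_forward(gr2, x, training = TRUE)
  grads2 <- ecgage:::model_backward(gr2, 2 * (fw2$pred - y) / 2, fw2$caches)
  for (p in list(c("res1_conv1", "W", 4), c("res2_conv_skip", "W", 2),
                 c("res4_conv2", "W", 9), c("fc1", "W", 3))) {
    i <- as.integer(p[3]); eps <- 1e-6
    gp <- gr2; gp$layers[[p[1]]][[p[2]]][i] <- gp$layers[[p[1]]][[p[2]]][i] + eps
    gm <- gr2; gm$layers[[p[1]]][[p[2]]][i] <- gm$layers[[p[1]]][[p[2]]][i] - eps
    lp <- mean((ecgage:::model_forward(gp, x, training = TRUE)$pred - y)^2)
    lm <- mean((ecgage:::model_forward(gm, x, training = TRUE)$pred - y)^2)
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - grads2[[p[1]]][[p[2]]][i]) / max(1e-6, abs(num)),
              1e-4)
  }
})

test_that("canonical graphs carry the documented kernel schedule and channels", {
  a <- build_attianet(input_len = 1024, init = FALSE)
  expect_equal(a$layers$t1_conv$k, 7)
  expect_equal(a$layers$t8_conv$k, 3)
  expect_equal(a$config$pools, rep(2L, 8))
  r <- build_resnet1d(input_len = 1024, init = FALSE)
  chans <- vapply(1:4, function(i)
    r$layers[[sprintf("res%d_conv1", i)]]$out_ch, integer(1))
  expect_equal(c(r$layers$res1_conv1$in_ch, chans),
               c(64L, 128L, 192L, 256L, 320L))
  expect_equal(r$layers$res1_conv1$k, 17)
  expect_error(build_attianet(input_len = 1000), "grid")
  cfg <- attianet_config(filters = rep(8, 8), kernels = rep(3, 8),
                         pools = rep(4, 8))
  expect_error(build_attianet(cfg, 1024), "receptive")
})

test_that("every residual block implements the canonical operator sequence", {
  r <- build_resnet1d(input_len = 1024, init = FALSE)
  for (i in 1:4) {
    blk <- sprintf("res%d", i)
    in_block <- Filter(function(l) l$block == blk, r$layers)
    kinds <- vapply(in_block, `[[`, character(1), "kind")
    paths <- vapply(in_block, `[[`, character(1), "path")
    # two dropouts, two main convs, one 1x1 skip conv, merge-before-final-BN
    expect_equal(sum(kinds == "dropout"), 2L)
    expect_equal(sum(kinds == "conv1d" & paths == "main"), 2L)
    skips <- in_block[kinds == "conv1d" & paths == "skip"]
    expect_length(skips, 1L)
    expect_equal(skips[[1]]$k, 1L)
    nm <- names(in_block)
    expect_lt(match(paste0(blk, "_add"), nm), match(paste0(blk, "_bn2"), nm))
    expect_lt(match(paste0(blk, "_bn2"), nm),
              match(paste0(blk, "_relu2"), nm))
  }
})

test_that("forward pass yields one finite scalar per record, equivariantly", {
  set.seed(13)
  g <- build_attianet(tiny_attia_config(), 2048)
  x <- array(rnorm(5 * 12 * 2048), dim = c(5, 12, 2048))
  p <- predict(g, x)
  expect_length(p, 5L)
  expect_true(all(is.finite(p)))
  perm <- c(3, 1, 5, 2, 4)
  expect_equal(predict(g, x[perm, , ]), p[perm])
  expect_error(predict(g, x[, , 1:1024]), "length")
  # zero weights give zero output
  g0 <- g
  for (nm in names(g0$layers))
    for (pn in ecgage:::param_names(g0$layers[[nm]])) {
      v <- g0$layers[[nm]][[pn]]
      if (pn != "gamma") g0$layers[[nm]][[pn]] <- v * 0
    }
  expect_equal(predict(g0, x), rep(0, 5))
})

test_that("random initializations give finite, non-constant outputs", {
  x <- array(rnorm(6 * 12 * 1024), dim = c(6, 12, 1024))
  for (seed in 1:25) {
    set.seed(seed)
    g <- build_attianet(tiny_attia_config(), 1024)
    p <- predict(g, x)
    expect_true(all(is.finite(p)))
    expect_gt(stats::sd(p), 0)
  }
})

test_that("freeze scope marks the documented boundary and survives training", {
  set.seed(14)
  r <- build_resnet1d(tiny_resnet_config(), 1024)
  f <- freeze_scope(r, "through_resblock3")
  frozen <- vapply(f$layers, function(l) isTRUE(l$frozen), logical(1))
  blocks <- vapply(f$layers, `[[`, character(1), "block")
  expect_true(all(frozen[blocks %in% c("stem", "res1", "res2", "res3")]))
  expect_false(any(frozen[blocks %in% c("res4", "head")]))
  all_free <- freeze_scope(f, "none")
  expect_false(any(vapply(all_free$layers, function(l) isTRUE(l$frozen),
                          logical(1))))
  a <- build_attianet(tiny_attia_config(), 1024)
  expect_error(freeze_scope(a, "through_resblock3"), "resnet1d")
  # five optimization steps leave frozen tensors bit-identical
  cache <- fixture_cache(n = 30, rate = 100, duration = 2, seed = 15)
  cfg <- train_config(epochs = 1, batch_size = 6, lr = 0.01, seed = 3)
  fit <- train_fold(f, cache, fold = cache$fold[1], cfg, pretrained = TRUE)
  for (nm in names(f$layers)) {
    if (!isTRUE(f$layers[[nm]]$frozen)) next
    for (pn in ecgage:::param_names(f$layers[[nm]]))
      expect_identical(fit$graph$layers[[nm]][[pn]], f$layers[[nm]][[pn]])
  }
})

test_that("weights round-trip through the 4-byte float serialization", {
  set.seed(16)
  g <- build_attianet(tiny_attia_config(), 1024)
  dir <- withr::local_tempdir()
  prefix <- file.path(dir, "w")
  save_weights(g, prefix)
  n_par <- count_params(g)$total
  expect_equal(file.size(paste0(prefix, ".bin")), 4 * n_par)
  g2 <- build_attianet(tiny_attia_config(), 1024, init = FALSE)
  g2 <- load_weights(g2, prefix)
  expect_equal(g2$layers$fc1$W, g$layers$fc1$W, tolerance = 1e-6)
  wrong <- build_attianet(attianet_config(filters = c(3, 5),
                                          kernels = c(7, 5),
                                          pools = c(2, 2),
                                          spatial_filters = 2,
                                          head = c(5, 3)), 1024,
                          init = FALSE)
  expect_error(load_weights(wrong, prefix), "mismatch")
})
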