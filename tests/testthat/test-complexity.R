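test_that("single-layer parameter arithmetic is exact", {
  g <- build_attianet(attianet_config(filters = c(16, 16),
                                      kernels = c(7, 5), pools = c(2, 2),
                                      spatial_filters = 2, head = c(4, 3)),
                      1024, init = FALSE)
  per <- count_params(g)$per_layer
  # conv 1 -> 16 channels, kernel 7 (per lead, shared weights): 16*7 + 16
  expect_equal(per$params[per$layer == "t1_conv"], 16 * 7 + 16)
  expect_equal(per$params[per$layer == "t2_conv"], 16 * 16 * 5 + 16)
  expect_equal(per$params[per$layer == "t1_bn"], 32)
  expect_equal(per$buffers[per$layer == "t1_bn"], 32)
  # a 12-lead fusing conv with 2 filters over 16 channels
  expect_equal(per$params[per$layer == "spatial_conv"], 2 * 16 * 12 + 2)
})

test_that("canonical parameter totals match the published accounting", {
  expect_equal(count_params(build_attianet(input_len = 1024,
                                           init = FALSE))$total, 593505)
  expect_equal(count_params(build_attianet(input_len = 5120,
                                           init = FALSE))$total, 599649)
  expect_equal(count_params(build_resnet1d(input_len = 1024,
                                           init = FALSE))$total, 6940065)
  expect_equal(count_params(build_resnet1d(input_len = 5120,
                                           init = FALSE))$total, 7021985)
})

test_that("analytic counts agree with introspection of materialized tensors", {
  set.seed(20)
  for (g in list(build_attianet(input_len = 1024),
                 build_resnet1d(tiny_resnet_config(), 1024))) {
    per <- count_params(g)$per_layer
    for (i in seq_len(nrow(per))) {
      ly <- g$layers[[per$layer[i]]]
      got <- sum(vapply(ecgage:::param_names(ly),
                        function(p) length(ly[[p]]), numeric(1)))
      expect_equal(per$params[i], got, info = per$layer[i])
    }
  }
})

test_that("parameter totals are affine in input length with the printed slopes", {
  lens <- c(1024L, 2048L, 3072L, 4096L, 5120L)
  at <- vapply(lens, function(L)
    count_params(build_attianet(input_len = L, init = FALSE))$total,
    numeric(1))
  rs <- vapply(lens, function(L)
    count_params(build_resnet1d(input_len = L, init = FALSE))$total,
    numeric(1))
  expect_equal(unique(diff(at)), 6144 / 4)
  expect_equal(unique(diff(rs)), 81920 / 4)
  # the five per-rate residual-network totals, exactly
  expect_equal(rs, c(6940065, 6960545, 6981025, 7001505, 7021985))
})

test_that("mult-add accounting follows the fused multiply-accumulate rules", {
  g <- build_attianet(attianet_config(filters = c(16, 16),
                                      kernels = c(7, 5), pools = c(2, 2),
                                      spatial_filters = 2, head = c(4, 3)),
                      1024, init = FALSE)
  per <- count_macs(g)$per_layer
  expect_equal(per$macs[per$layer == "t1_conv"], 1024 * 16 * 1 * 7 * 12)
  expect_equal(per$macs[per$layer == "t2_conv"], 512 * 16 * 16 * 5 * 12)
  expect_equal(per$macs[per$layer == "t1_bn"], 0)
  expect_equal(per$macs[per$layer == "fc1"], (256 * 2) * 4)
  # pure-conv cost doubles when the input doubles
  m1 <- count_macs(g, 1024)$per_layer
  m2 <- count_macs(g, 2048)$per_layer
  conv <- m1$kind == "conv1d"
  expect_equal(m2$macs[conv], 2 * m1$macs[conv])
})

test_that("canonical mult-add totals and serialized sizes are reproduced", {
  a5 <- build_attianet(input_len = 5120, init = FALSE)
  expect_equal(count_macs(a5)$macs_g, 1.57)
  r1 <- build_resnet1d(input_len = 1024, init = FALSE)
  r5 <- build_resnet1d(input_len = 5120, init = FALSE)
  # the all-convolution residual body scales exactly linearly: 5x from
  # 1,024 to 5,120 samples up to the constant head
  conv_macs <- function(g) {
    per <- count_macs(g)$per_layer
    sum(per$macs[per$kind == "conv1d"])
  }
  expect_equal(conv_macs(r5) / conv_macs(r1), 5)
  expect_equal(disk_mb(r1), 27.76)
  expect_equal(disk_mb(a5), 2.40)
  empty <- build_attianet(tiny_attia_config(), 1024, init = FALSE)
  expect_equal(disk_mb(empty), round(4 * count_params(empty)$total / 1e6, 2))
})

test_that("complexity_table emits one consistent row per sampling rate", {
  tab <- complexity_table("attianet")
  expect_equal(nrow(tab), 5L)
  expect_equal(tab$parameter_count,
               c(593505, 595041, 596577, 598113, 599649))
  expect_equal(tab$input_len, c(1024L, 2048L, 3072L, 4096L, 5120L))
})
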