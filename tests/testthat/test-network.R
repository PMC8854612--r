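# Architecture realization: parameter accounting, shape trace, skips,
# dilation arithmetic, forward-pass contracts.

test_that("the default architecture has exactly 8269 parameters with the closed-form per-layer counts", {
  net <- build_network(cranionet_spec(), seed = 1)
  counts <- layer_parameter_counts(net)
  cin <- c(1, head(net$spec$channels, -1))
  expect_equal(counts, 27 * cin * net$spec$channels + net$spec$channels)
  expect_identical(count_parameters(net), 8269)
})

test_that("parameter count grows monotonically with channel width", {
  wide <- cranionet_spec(channels = 2 * c(8, 8, 4, 4, 4, 4, 4, 4, 4, 8, 8, 1))
  expect_gt(count_parameters(build_network(wide, seed = 1)), 8269)
})

test_that("invalid skip topologies are construction errors", {
  expect_error(cranionet_spec(skips = cranionet:::default_skips()[1:7]),
               "8 skip")
  bad <- cranionet:::default_skips()
  bad[[1]] <- c("conv1", "conv11")   # full-res 8ch vs half-res 8ch
  expect_error(cranionet_spec(skips = bad), "conv1 -> conv11")
  bad[[1]] <- c("nowhere", "conv11")
  expect_error(cranionet_spec(skips = bad), "unknown tensor")
})

test_that("weight initialization and the forward pass are deterministic", {
  a <- build_network(seed = 7)
  b <- build_network(seed = 7)
  expect_identical(coef(a), coef(b))
  x <- as.array(mini_shell())
  expect_identical(as.array(forward(a, x)), as.array(forward(a, x)))
  expect_false(identical(coef(a), coef(build_network(seed = 8))))
})

test_that("the forward pass preserves shape and stays in [0, 1]", {
  net <- build_network(seed = 2)
  out <- forward(net, mini_shell())
  expect_identical(dim(out), dim(mini_shell()))
  v <- as.array(out)
  expect_true(all(v >= 0 & v <= 1))
  expect_error(forward(net, array(0, c(30, 32, 8))), "divisible")
})

test_that("dilation widens the receptive field without extra weights", {
  expect_identical(effective_receptive_field(3, 2), 5L)
  expect_identical(effective_receptive_field(3, 1), 3L)
  expect_identical(effective_receptive_field(3, 16), 33L)
  expect_error(effective_receptive_field(4, 2), "odd")
  # each dilated kernel still carries 27 weights per channel pair
  net <- build_network(seed = 1)
  dil <- which(net$spec$dilations > 1)[1]
  expect_identical(nrow(net$weights[[dil]]$W), 27L * 4L)
})

test_that("feature maps at the bottleneck have the documented resolutions", {
  net <- build_network(seed = 3)
  x <- as.array(mini_shell())   # 32 x 32 x 8
  pre <- feature_maps(net, x, "pre_dilation")
  expect_length(pre, 4)
  expect_identical(dim(pre[[1]]), c(8L, 8L, 2L))   # quarter resolution
  post <- feature_maps(net, x, "post_dilation_pooled")
  expect_length(post, 4)
  expect_identical(dim(post[[1]]), c(4L, 4L, 1L))  # eighth resolution
  expect_error(feature_maps(net, x, "bogus"), "available")
})

test_that("zero input propagates the biases through the ReLU maps", {
  net <- build_network(seed = 4)
  net$weights[[1]]$b <- c(-0.5, 0.25, -0.1, 0.3, 0.2, -0.2, 0.15, 0)
  z <- array(0, c(16, 16, 8))
  fm <- feature_maps(net, z, "conv1")
  for (c in seq_along(fm)) {
    expect_true(all(fm[[c]] >= 0))
    expect_equal(unique(as.numeric(fm[[c]])),
                 max(0, net$weights[[1]]$b[c]))
  }
})

test_that("architecture specs round-trip through JSON and YAML configs", {
  spec <- cranionet_spec()
  for (ext in c("json", "yaml")) {
    tf <- file.path(tempdir(), paste0("spec.", ext))
    write_spec(spec, tf)
    back <- read_spec(tf)
    expect_identical(back$channels, spec$channels)
    expect_identical(back$dilations, spec$dilations)
    expect_identical(back$skips, spec$skips)
    expect_identical(count_parameters(build_network(back, seed = 1)), 8269)
  }
})

test_that("checkpoints round-trip to bitwise-identical forward outputs", {
  net <- build_network(seed = 9)
  tf <- file.path(tempdir(), "ckpt.rds")
  save_network(net, tf)
  back <- load_network(tf)
  x <- as.array(mini_shell())
  expect_identical(as.array(forward(back, x)), as.array(forward(net, x)))
})
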