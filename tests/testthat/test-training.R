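# Splitting, loss, optimization loop.

test_that("the validation split is disjoint, exhaustive and rounds correctly", {
  parts <- split_dataset(as.list(1:7150), split = 0.1, seed = 3)
  expect_length(parts$validation, 715)
  expect_length(parts$train, 6435)
  expect_length(intersect(unlist(parts$train), unlist(parts$validation)), 0)
  expect_setequal(c(unlist(parts$train), unlist(parts$validation)), 1:7150)
  expect_length(split_dataset(as.list(1:10), 0.1, 1)$validation, 1)
  expect_identical(attr(split_dataset(as.list(1:100), 0.1, 5), "indices"),
                   attr(split_dataset(as.list(1:100), 0.1, 5), "indices"))
  expect_error(split_dataset(as.list(1:3), 0.01, 1), "empty")
  expect_error(split_dataset(list(1), 0.5, 1), "at least 2")
})

test_that("group-aware splitting never separates augmented variants of one source", {
  groups <- rep(1:10, each = 98)
  parts <- split_dataset(as.list(seq_along(groups)), 0.1, seed = 2,
                         groups = groups)
  val_groups <- unique(groups[attr(parts, "indices")])
  train_groups <- unique(groups[-attr(parts, "indices")])
  expect_length(intersect(val_groups, train_groups), 0)
})

test_that("binary cross entropy matches its closed forms", {
  gs <- c(4, 4, 2)
  t1 <- array(rep(c(0, 1), 16), gs)
  expect_equal(bce_loss(array(0.5, gs), t1), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(array(0.25, c(1, 1, 1)), array(1, c(1, 1, 1))),
               -log(0.25), tolerance = 1e-12)
  expect_lt(bce_loss(t1, t1), 1e-6)
  expect_error(bce_loss(array(0.5, gs), array(1, c(2, 2, 2))), "match")
})

test_that("zero-epoch training returns the initial weights and empty history", {
  pairs <- random_pairs(4, seed = 31)
  net0 <- build_network(seed = 5)
  net <- cranionet(pairs, control = cranionet_control(epochs = 0, seed = 5,
                                                      validation_split = 0,
                                                      calibrate_bias = FALSE))
  expect_identical(coef(net), coef(net0))
  expect_identical(nrow(net$history), 0L)
})

test_that("training is a pure function of data and seed", {
  pairs <- random_pairs(6, seed = 41)
  ctrl <- cranionet_control(epochs = 2, batch_size = 3, seed = 17,
                            validation_split = 0.2)
  a <- cranionet(pairs, control = ctrl)
  b <- cranionet(pairs, control = ctrl)
  expect_identical(a$history[c("epoch", "loss", "val_loss")],
                   b$history[c("epoch", "loss", "val_loss")])
  expect_identical(coef(a), coef(b))
})

test_that("the loss decreases over short training on a small phantom set", {
  pairs <- random_pairs(24, seed = 51)
  net <- cranionet(pairs, control = cranionet_control(
    epochs = 8, batch_size = 10, validation_split = 0, seed = 1))
  h <- net$history
  expect_identical(nrow(h), 8L)
  expect_true(all(is.finite(h$loss)))
  expect_lt(tail(h$loss, 1), h$loss[1])
})

test_that("the fused training pass matches the reference engine", {
  pr <- random_pairs(1, seed = 71)[[1]]
  net <- build_network(seed = 19)
  fast <- cranionet:::grad_one(net, pr)
  ref <- cranionet:::grad_one_ref(net, pr)
  expect_equal(fast$loss, ref$loss, tolerance = 1e-6)
  for (l in seq_along(fast$gW)) {
    scale <- max(abs(ref$gW[[l]]))
    expect_lt(max(abs(fast$gW[[l]] - ref$gW[[l]])) / scale, 1e-4)
    expect_equal(fast$gb[[l]], as.numeric(ref$gb[[l]]), tolerance = 1e-4)
  }
})

test_that("analytic gradients agree with finite differences", {
  set.seed(8)
  gs <- c(8, 8, 8)
  net <- build_network(seed = 13)
  pair <- structure(list(
    defective = voxel_volume(array(as.numeric(runif(prod(gs)) > 0.6), gs)),
    intact = voxel_volume(array(as.numeric(runif(prod(gs)) > 0.5), gs))),
    class = "training_pair")
  g <- cranionet:::grad_one(net, pair)
  loss_at <- function(n) cranionet:::grad_one(n, pair)$loss
  for (l in c(1, 6, 12)) {
    i <- which.max(abs(g$gW[[l]]))
    eps <- 1e-3
    up <- net; up$weights[[l]]$W[i] <- up$weights[[l]]$W[i] + eps
    dn <- net; dn$weights[[l]]$W[i] <- dn$weights[[l]]$W[i] - eps
    numeric_grad <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    expect_equal(g$gW[[l]][i], numeric_grad, tolerance = 2e-2)
  }
})

test_that("training continues from a checkpoint deterministically", {
  pairs <- random_pairs(4, seed = 61)
  ctrl1 <- cranionet_control(epochs = 2, validation_split = 0, seed = 3)
  net <- cranionet(pairs, control = ctrl1)
  tf <- file.path(tempdir(), "resume.rds")
  save_network(net, tf)
  resumed <- cranionet(pairs, control = ctrl1, net = load_network(tf))
  expect_identical(nrow(resumed$history), 4L)   # cumulative history
  expect_equal(resumed$history$epoch, 1:4)
  expect_false(identical(coef(resumed), coef(net)))
})
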