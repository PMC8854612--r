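# Volumetric error rate and the evaluation harness.

# independent brute-force 1-norm oracle
brute_rate <- function(p, q) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - q[i])
  100 * s / sum(p)
}

test_that("the error rate equals the brute-force 1-norm oracle on all 4-voxel toys", {
  gs <- c(4, 1, 1)
  combos <- expand.grid(rep(list(0:1), 4))
  for (a in seq_len(nrow(combos))) {
    p <- as.numeric(combos[a, ])
    if (sum(p) == 0) next
    for (b in seq_len(nrow(combos))) {
      q <- as.numeric(combos[b, ])
      r <- volumetric_error_rate(voxel_volume(array(p, gs)),
                                 voxel_volume(array(q, gs)))
      expect_identical(r, brute_rate(p, q))
      if (identical(p, q)) expect_identical(r, 0) else expect_gt(r, 0)
    }
  }
})

test_that("error-rate identities: perfect repair, arithmetic, overfill beyond 100%", {
  gs <- c(40, 25, 1)
  p <- array(0, gs)
  p[1:40, 1:25, 1] <- 1            # 1000 voxels
  q <- p
  q[1:2, 1:25, 1] <- 0             # remove 50
  q[3, 1:16, 1] <- 0               # remove 16 -> 66... adjust to 82
  q[4, 1:16, 1] <- 0
  P <- voxel_volume(p)
  expect_identical(volumetric_error_rate(P, P), 0)
  expect_equal(volumetric_error_rate(P, voxel_volume(q)), 8.2)
  # disjoint singletons: one miss + one false positive = 200%
  a <- toy_volume(c(2, 1, 1), cbind(1, 1, 1))
  b <- toy_volume(c(2, 1, 1), cbind(2, 1, 1))
  expect_identical(volumetric_error_rate(a, b), 200)
  expect_error(volumetric_error_rate(voxel_volume(array(0, c(2, 1, 1))), a),
               "empty")
})

test_that("the error rate is invariant under a common rigid shift", {
  gs <- c(10, 10, 4)
  p <- array(0, gs); p[2:4, 2:4, 2:3] <- 1
  q <- array(0, gs); q[2:4, 2:5, 2:3] <- 1
  shift <- function(v, d) {
    w <- array(0, dim(v))
    w[(1 + d):dim(v)[1], , ] <- v[1:(dim(v)[1] - d), , ]
    w
  }
  r0 <- volumetric_error_rate(voxel_volume(p), voxel_volume(q))
  r1 <- volumetric_error_rate(voxel_volume(shift(p, 5)),
                              voxel_volume(shift(q, 5)))
  expect_identical(r0, r1)
})

test_that("the identity oracle scores zero and the null predictor 100% on every case", {
  pairs <- random_pairs(6, seed = 91)
  ev_id <- evaluate_pairs("identity", pairs)
  expect_true(all(ev_id$reports$r == 0))
  expect_identical(ev_id$summary$mean_r, 0)
  ev_null <- evaluate_pairs("null", pairs)
  expect_true(all(ev_null$reports$r == 100))
  expect_identical(ev_null$summary$max_r, 100)
  expect_named(ev_id$summary, c("mean_r", "max_r", "n", "by_family"))
})

test_that("the capability curve is computable across fraction bins with oracle endpoints", {
  phantoms <- generate_cohort(3, seed = 111, grid_shape = mini_grid)
  cc_id <- capability_curve("identity", phantoms,
                            breaks = c(0.05, 0.15, 0.25, 0.35), seed = 5)
  expect_s3_class(cc_id, "capability_curve")
  expect_identical(nrow(cc_id), 3L)
  expect_true(all(cc_id$mean_r[cc_id$n > 0] == 0))
  expect_true(all(cc_id$satisfactory[cc_id$n > 0]))
  cc_null <- capability_curve("null", phantoms,
                              breaks = c(0.05, 0.15, 0.25, 0.35), seed = 5)
  expect_true(all(cc_null$mean_r[cc_null$n > 0] == 100))
  expect_true(all(!cc_null$satisfactory[cc_null$n > 0]))
})

test_that("storage accounting matches the dense single-precision layout", {
  expect_identical(volume_storage_bytes(c(112, 112, 40)), 2007040)
  expect_identical(volume_storage_bytes(c(112, 112, 40), 7150), 14350336000)
})
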