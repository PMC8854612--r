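# Defect-mask families, Boolean pair construction, fraction targeting.

test_that("cylinder masks have z-parallel boundaries spanning the full depth", {
  gs <- c(32, 32, 8)
  m <- make_mask("cylinder", list(center = c(15.5, 15.5), radius = 6), gs)
  v <- as.array(m$values)
  cols <- apply(v, c(1, 2), sum)
  expect_true(all(cols %in% c(0, gs[3])))
  for (k in 2:gs[3]) expect_identical(v[, , k], v[, , 1])
  m2 <- make_mask("elliptical_cylinder",
                  list(center = c(15.5, 15.5), semi_axes = c(8, 4),
                       rotation = 30), gs)
  v2 <- as.array(m2$values)
  for (k in 2:gs[3]) expect_identical(v2[, , k], v2[, , 1])
})

test_that("ellipsoid masks match the brute-force analytic voxelizer", {
  gs <- c(28, 28, 24)
  ctr <- c(13.5, 13.5, 11.5)
  m <- make_mask("ellipsoid", list(center = ctr, semi_axes = c(10, 10, 10)), gs)
  n <- voxel_count(m$values)
  expect_identical(n, brute_ellipsoid_count(ctr, c(10, 10, 10), gs))
  expect_lt(abs(n - 4 / 3 * pi * 1000) / (4 / 3 * pi * 1000), 0.05)
  # symmetric family: equal in-plane semi-axes by construction
  ms <- make_mask("symmetric_ellipsoid",
                  list(center = ctr, r_plane = 8, r_z = 5), gs)
  expect_identical(voxel_count(ms$values),
                   brute_ellipsoid_count(ctr, c(8, 8, 5), gs))
})

test_that("mixed masks are unions: overlap makes the count subadditive", {
  gs <- c(32, 32, 16)
  c1 <- list(center = c(14, 14, 8), semi_axes = c(7, 6, 5))
  c2 <- list(center = c(18, 16, 8), semi_axes = c(6, 7, 5))
  mixed <- make_mask("mixed_ellipsoid", list(components = list(c1, c2)), gs)
  n1 <- voxel_count(make_mask("ellipsoid", c1, gs)$values)
  n2 <- voxel_count(make_mask("ellipsoid", c2, gs)$values)
  expect_lt(voxel_count(mixed$values), n1 + n2)
  expect_gt(voxel_count(mixed$values), max(n1, n2))
  expect_error(make_mask("mixed_ellipsoid", list(components = list(c1)), gs),
               ">= 2")
})

test_that("masks entirely outside the grid or empty are rejected", {
  gs <- c(16, 16, 8)
  expect_error(make_mask("ellipsoid",
                         list(center = c(60, 60, 60), semi_axes = c(3, 3, 3)),
                         gs), "outside")
})

test_that("apply_defect is exact set algebra with its degenerate cases", {
  gs <- c(3, 1, 1)
  intact <- toy_volume(gs, cbind(1:3, 1, 1))
  mask <- toy_volume(gs, cbind(2, 1, 1))
  pair <- apply_defect(intact, mask)
  expect_equal(as.array(pair$defective), array(c(1, 0, 1), gs))
  expect_equal(as.array(pair$ideal_implant), array(c(0, 1, 0), gs))
  # total removal
  total <- apply_defect(intact, toy_volume(gs, cbind(1:3, 1, 1)))
  expect_equal(voxel_count(total$defective), 0)
  expect_identical(as.array(total$ideal_implant), as.array(intact))
  # empty intersection
  empty_mask <- voxel_volume(array(0, gs))
  expect_error(apply_defect(intact, empty_mask), "degenerate")
})

test_that("every sampled pair satisfies the exact pair invariants", {
  pairs <- random_pairs(8, seed = 21)
  for (pr in pairs) {
    expect_equal(voxel_count(vox_and(pr$defective, pr$ideal_implant)), 0)
    expect_identical(as.array(vox_or(pr$defective, pr$ideal_implant)),
                     as.array(pr$intact))
    f <- defect_fraction(pr)
    expect_gte(f, 0.05)
    expect_lte(f, 0.30)
  }
})

test_that("defect sampling is deterministic and fraction-targeted", {
  shell <- mini_shell()
  a <- sample_training_pair(shell, seed = 7, fraction_range = c(0.05, 0.35))
  b <- sample_training_pair(shell, seed = 7, fraction_range = c(0.05, 0.35))
  expect_identical(as.array(a$defective), as.array(b$defective))
  expect_identical(a$mask$family, b$mask$family)
  expect_error(sample_training_pair(shell, 1, fraction_range = c(0.2, 0.1)),
               "interval")
  expect_error(sample_training_pair(shell, 1, fraction_range = c(0.0, 0.5)),
               "interval")
})

test_that("defect_fraction is count arithmetic, invariant under translation", {
  gs <- c(12, 12, 6)
  intact <- toy_volume(gs, cbind(rep(2:6, 2), rep(2:3, each = 5), 2))
  mask <- toy_volume(gs, cbind(2:3, 2, 2))
  pr <- apply_defect(intact, mask)
  expect_equal(defect_fraction(pr), 2 / 10)
  shift <- function(vol, dx) {
    v <- as.array(vol)
    w <- array(0, dim(v))
    w[(1 + dx):dim(v)[1], , ] <- v[1:(dim(v)[1] - dx), , ]
    voxel_volume(w)
  }
  pr2 <- apply_defect(shift(intact, 3), shift(mask, 3))
  expect_equal(defect_fraction(pr2), defect_fraction(pr))
})

test_that("mask families are drawn uniformly", {
  shell <- mini_shell()
  seeds <- cranionet:::derive_seeds(99, 1800)
  fams <- vapply(seeds, function(s)
    sample_training_pair(shell, s, fraction_range = c(0.03, 0.45))$mask$family,
    character(1))
  counts <- table(factor(fams, levels = defect_families()))
  expect_identical(length(counts), 6L)
  p <- stats::chisq.test(counts)$p.value
  expect_gt(p, 0.001)
})

test_that("masks crossing the mid-sagittal plane are flagged", {
  gs <- c(32, 32, 8)
  central <- make_mask("cylinder", list(center = c(15.5, 15.5), radius = 5), gs)
  expect_true(central$crosses_midline)
  lateral <- make_mask("cylinder", list(center = c(5, 15.5), radius = 3), gs)
  expect_false(lateral$crosses_midline)
})
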