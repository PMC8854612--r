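# Binarization, Boolean implant extraction, high-resolution
# post-processing, STL export.

test_that("binarize applies the >= tie rule and is monotone in the threshold", {
  gs <- c(2, 2, 1)
  v <- voxel_volume(array(c(0.2, 0.5, 0.6, 0.9), gs))
  expect_equal(as.array(binarize(v, 0.5)), array(c(0, 1, 1, 1), gs))
  expect_equal(as.array(binarize(voxel_volume(array(0.6, gs)), 0.5)),
               array(1, gs))
  lowthr <- voxel_count(binarize(v, 0.3))
  highthr <- voxel_count(binarize(v, 0.7))
  expect_gte(lowthr, highthr)
  expect_error(binarize(v, 0), "strictly inside")
  expect_error(binarize(v, 1), "strictly inside")
})

test_that("extract_implant is exact Boolean subtraction", {
  gs <- c(3, 1, 1)
  completed <- toy_volume(gs, cbind(1:3, 1, 1))
  defective <- toy_volume(gs, cbind(1, 1, 1))
  imp <- extract_implant(completed, defective)
  expect_equal(as.array(imp$volume), array(c(0, 1, 1), gs))
  # perfect skull needs no implant
  expect_equal(voxel_count(extract_implant(defective, defective)$volume), 0)
  expect_error(extract_implant(completed, toy_volume(c(2, 1, 1), cbind(1, 1, 1))),
               "identical shapes")
})

test_that("the ideal completion reproduces the ideal implant exactly", {
  for (pr in random_pairs(5, seed = 71)) {
    imp <- extract_implant(pr$intact, pr$defective)
    expect_identical(as.array(imp$volume), as.array(pr$ideal_implant))
    expect_equal(voxel_count(vox_and(imp$volume, pr$defective)), 0)
  }
})

test_that("postprocess resamples to the 4x plane, stays disjoint from the skull, and is idempotent", {
  pr <- random_pairs(1, seed = 81)[[1]]
  d <- dim(pr$intact)
  target <- c(4L * d[1:2], d[3])
  # high-res defective model: plane-upsampled working model
  A <- diag(c(d[1] / target[1], d[2] / target[2], 1))
  dh <- cranionet:::.cn_affine_resample(
    as.numeric(as.array(pr$defective)), as.integer(d), A, (d - 1) / 2,
    c((target[1:2] - 1) / 2, (d[3] - 1) / 2), as.integer(target))
  defective_hr <- voxel_volume(cranionet:::binarize_values(array(dh, target)))
  imp <- extract_implant(pr$intact, pr$defective)
  post <- postprocess(imp, defective_hr, target)
  expect_identical(dim(post$volume), target)
  expect_equal(voxel_count(vox_and(post$volume, defective_hr)), 0)
  # re-subtraction is idempotent
  again <- vox_subtract(post$volume, defective_hr)
  expect_identical(as.array(again), as.array(post$volume))
  expect_error(postprocess(imp, defective_hr, c(2L * d[1:2], d[3])), "4x")
})

test_that("the smoothing operator changes a large solid's volume by less than 5%", {
  gs <- c(24, 24, 16)
  cube <- array(0, gs)
  cube[7:18, 7:18, 3:14] <- 1
  target <- c(96L, 96L, 16L)
  empty_hr <- voxel_volume(array(0, target))
  post <- postprocess(voxel_volume(cube), empty_hr, target)
  expected <- sum(cube) * 16   # 4x plane upsampling
  expect_lt(abs(voxel_count(post$volume) - expected) / expected, 0.05)
})

test_that("degenerate smoothing falls back to the unsmoothed implant with a warning", {
  gs <- c(8, 8, 8)
  dot <- array(0, gs)
  dot[4, 4, 4] <- 1
  target <- c(32L, 32L, 8L)
  empty_hr <- voxel_volume(array(0, target))
  expect_warning(post <- postprocess(voxel_volume(dot), empty_hr, target,
                                     closing_radius = 0, sigma = 4),
                 "fall")
  expect_gt(voxel_count(post$volume), 0)
})

test_that("a single voxel exports as a closed mesh of positive volume", {
  gs <- c(4, 4, 4)
  v <- array(0, gs)
  v[2, 2, 2] <- 1
  tf <- file.path(tempdir(), "dot.stl")
  n <- export_mesh(voxel_volume(v), tf)
  expect_identical(n, 12L)   # 6 faces x 2 triangles
  mesh <- read_stl(tf)
  expect_identical(mesh$n_triangles, 12L)
  expect_equal(mesh_volume(mesh), 1)
})

test_that("the mesh volume of a 20-voxel cube matches the analytic volume within 2%", {
  gs <- c(24, 24, 24)
  v <- array(0, gs)
  v[3:22, 3:22, 3:22] <- 1
  tf <- file.path(tempdir(), "cube.stl")
  export_mesh(voxel_volume(v, spacing = c(1, 1, 1)), tf)
  mesh <- read_stl(tf)
  expect_lt(abs(mesh_volume(mesh) - 8000) / 8000, 0.02)
  # STL round trip preserves the triangle count
  tf2 <- file.path(tempdir(), "cube2.stl")
  export_mesh(voxel_volume(v), tf2)
  expect_identical(read_stl(tf2)$n_triangles, mesh$n_triangles)
})

test_that("mesh bounding box tracks the occupied voxels with spacing applied", {
  gs <- c(8, 8, 8)
  v <- array(0, gs)
  v[3:5, 2:4, 6:7] <- 1
  tf <- file.path(tempdir(), "bb.stl")
  export_mesh(voxel_volume(v, spacing = c(2, 1, 0.5)), tf)
  mesh <- read_stl(tf)
  xs <- mesh$vertices[, c(1, 4, 7)]
  ys <- mesh$vertices[, c(2, 5, 8)]
  zs <- mesh$vertices[, c(3, 6, 9)]
  expect_equal(range(xs), c(2 * 2, 5 * 2))
  expect_equal(range(ys), c(1 * 1, 4 * 1))
  expect_equal(range(zs), c(5 * 0.5, 7 * 0.5))
  expect_error(export_mesh(voxel_volume(array(0, gs)), tf), "empty")
})
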