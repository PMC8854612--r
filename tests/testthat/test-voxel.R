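# Voxel data model, HU thresholding, cropping, augmentation, NIfTI I/O.

test_that("HU thresholding applies the closed interval rule", {
  gs <- c(3, 1, 1)
  hu <- hu_volume(array(c(1200, 1817, 1818), gs))
  expect_equal(as.array(threshold_hu(hu)), array(c(1, 1, 0), gs))
  expect_equal(as.array(threshold_hu(hu_volume(array(1500, c(2, 2, 2))))),
               array(1, c(2, 2, 2)))
  expect_equal(as.array(threshold_hu(hu_volume(array(1199, c(2, 2, 2))))),
               array(0, c(2, 2, 2)))
  expect_error(threshold_hu(hu, 1800, 1200), "strictly less")
})

test_that("widening the HU interval never removes occupied voxels", {
  set.seed(4)
  hu <- hu_volume(array(runif(4^3, 800, 2200), c(4, 4, 4)))
  inner <- as.array(threshold_hu(hu, 1200, 1817))
  wider <- as.array(threshold_hu(hu, 1100, 1900))
  expect_true(all(wider >= inner))
})

test_that("crop_and_downsample maps a 512-plane CT model to the working grid", {
  gs <- c(512, 512, 42)
  v <- array(0, gs)
  # centered ball
  for (k in 1:42) {
    r2 <- 200^2 - ((k - 21) * 10)^2
    if (r2 > 0) {
      ij <- expand.grid(i = 1:512, j = 1:512)
      sel <- (ij$i - 256)^2 + (ij$j - 256)^2 <= r2
      sl <- array(0, c(512, 512))
      sl[cbind(ij$i[sel], ij$j[sel])] <- 1
      v[, , k] <- sl
    }
  }
  out <- crop_and_downsample(voxel_volume(v), c(112, 112, 40))
  expect_identical(dim(out), c(112L, 112L, 40L))
  expect_true(is_binary_volume(out))
  expect_gt(voxel_count(out), 0)
})

test_that("crop_and_downsample is the identity on an already-normalized model and preserves solid slabs", {
  v <- as.array(mini_shell())
  out <- crop_and_downsample(voxel_volume(v), dim(v))
  expect_equal(as.array(out), v)
  slab <- voxel_volume(array(1, c(128, 128, 10)))
  out2 <- crop_and_downsample(slab, c(32, 32, 10))
  expect_equal(as.array(out2), array(1, c(32, 32, 10)))
  expect_error(crop_and_downsample(voxel_volume(array(0, c(128, 128, 10))),
                                   c(32, 32, 10)), "no occupied")
  expect_error(crop_and_downsample(slab, c(256, 256, 10)), "plane resolution")
})

test_that("the default augmentation grid yields 98 variants per model, 7154 for 73 models", {
  grid <- augmentation_grid()
  expect_length(grid$rotations, 7)
  expect_length(grid$tilts, 7)
  expect_length(grid$z_translations, 2)
  vars <- augment(mini_shell(), grid, clip_tolerance = 0.1)
  expect_length(vars, 98)
  expect_identical(73L * length(vars), 7154L)
  for (v in vars[c(1, 50, 98)]) {
    expect_true(is_binary_volume(v))
    expect_identical(dim(v), dim(mini_shell()))
  }
})

test_that("the identity-only augmentation grid returns the input unchanged", {
  grid <- augmentation_grid(0, 0, 0)
  out <- augment(mini_shell(), grid)
  expect_length(out, 1)
  expect_identical(as.array(out[[1]]), as.array(mini_shell()))
})

test_that("pure z-rotations nearly preserve a rotationally symmetric volume", {
  gs <- c(112, 112, 8)
  ctr <- (gs[1] + 1) / 2
  v <- array(0, gs)
  for (i in 1:gs[1]) for (j in 1:gs[2])
    if ((i - ctr)^2 + (j - ctr)^2 <= 50^2) v[i, j, 3:6] <- 1
  out <- augment(voxel_volume(v), augmentation_grid(c(-6, 0, 6), 0, 0))
  for (o in out) {
    disagree <- sum(abs(as.array(o) - v)) / sum(v)
    expect_lt(disagree, 0.01)
  }
})

test_that("a clipped augmentation variant warns but is retained", {
  v <- array(0, c(16, 16, 8))
  v[1:3, 1:3, 1:8] <- 1   # mass at the corner gets pushed out by rotation
  expect_warning(out <- augment(voxel_volume(v), augmentation_grid(45, 0, 0)),
                 "lost")
  expect_length(out, 1)
})

test_that("binary volumes round-trip through NIfTI", {
  tf <- file.path(tempdir(), "vol.nii.gz")
  vol <- voxel_volume(as.array(mini_shell()), spacing = c(1.6, 1.6, 2.5))
  write_volume(vol, tf)
  back <- read_volume(tf)
  expect_identical(as.array(back), as.array(vol))
  expect_equal(back$spacing, c(1.6, 1.6, 2.5))
  expect_error(read_volume(file.path(tempdir(), "absent.nii")), "not found")
})

test_that("volumes with flipped on-disk orientation are reoriented on read", {
  tf <- file.path(tempdir(), "flip.nii.gz")
  v <- as.array(mini_shell())
  img <- RNifti::asNifti(v[dim(v)[1]:1, , ], pixdim = c(1, 1, 1))
  RNifti::qform(img) <- structure(diag(c(-1, 1, 1, 1)), code = 2L)
  RNifti::writeNifti(img, tf)
  back <- read_volume(tf)
  expect_identical(as.array(back), v)
})

test_that("boolean volume algebra is exact set algebra", {
  a <- toy_volume(c(2, 2, 1), cbind(c(1, 2), c(1, 1), c(1, 1)))
  b <- toy_volume(c(2, 2, 1), cbind(2, 1, 1))
  expect_equal(voxel_count(vox_and(a, b)), 1)
  expect_equal(voxel_count(vox_or(a, b)), 2)
  expect_equal(voxel_count(vox_subtract(a, b)), 1)
  expect_equal(voxel_count(vox_not(a)), 2)
  expect_error(vox_and(a, toy_volume(c(3, 2, 1), cbind(1, 1, 1))),
               "identical shapes")
})
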