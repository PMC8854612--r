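# Shared in-code fixtures. Everything is generated programmatically; the
# small "mini" grid (32 x 32 x 8) keeps geometry tests fast while
# preserving all structural properties (three pooling levels, shells with
# open bottoms, defect families).

mini_grid <- resolve_grid("mini")
reduced_grid <- resolve_grid("reduced")

# one deterministic mini shell, memoised across tests
mini_shell <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- generate_cohort(1, seed = 11,
                                              grid_shape = mini_grid)[[1]]
    val
  }
})

# brute-force voxelizer used as the independent oracle for analytic
# solids: occupancy by direct per-voxel inequality evaluation
brute_ellipsoid_count <- function(center, semi_axes, grid_shape) {
  n <- 0L
  for (k in 0:(grid_shape[3] - 1))
    for (j in 0:(grid_shape[2] - 1))
      for (i in 0:(grid_shape[1] - 1)) {
        p <- (c(i, j, k) - center) / semi_axes
        if (sum(p^2) <= 1) n <- n + 1L
      }
  n
}

# brute-force shell (ellipsoid difference) count, truncated at z >= 0
brute_shell_count <- function(center, outer, thickness, grid_shape) {
  inner <- outer - thickness
  n <- 0L
  for (k in 0:(grid_shape[3] - 1))
    for (j in 0:(grid_shape[2] - 1))
      for (i in 0:(grid_shape[1] - 1)) {
        p <- c(i, j, k) - center
        ro <- sum((p / outer)^2)
        ri <- sum((p / inner)^2)
        if (ro <= 1 && ri > 1) n <- n + 1L
      }
  n
}

# tiny deterministic binary volume on an arbitrary grid
toy_volume <- function(grid_shape, fill, value = 1) {
  v <- array(0, grid_shape)
  v[fill] <- value
  voxel_volume(v)
}

random_pairs <- function(n, seed, grid_shape = mini_grid,
                         fraction_range = c(0.05, 0.30)) {
  cohort <- generate_cohort(n, seed = seed, grid_shape = grid_shape)
  make_training_pairs(cohort, seed = seed + 1L,
                      fraction_range = fraction_range)
}
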