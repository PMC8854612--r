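# Synthetic upper-cranium shell phantoms.
#
# A phantom is the set difference of two concentric ellipsoids (outer
# minus inner), optionally perturbed by a smooth low-order radial
# harmonic, rotated/tilted, and truncated at the bottom face of the grid
# so that only the upper cranium remains (open bottom). This captures the
# convex closed-shell geometry with finite, smoothly varying thickness
# that the completion network must learn, without any anatomical data
# dependency.

#' Phantom shell parameters
#'
#' @param outer_semi_axes 3 positive semi-axis lengths (voxels) of the
#'   outer ellipsoid: in-plane x, in-plane y, vertical z.
#' @param shell_thickness positive thickness (voxels), strictly less than
#'   the smallest outer semi-axis; with surface noise the realized
#'   thickness varies smoothly over the surface.
#' @param center position of the ellipsoid center (0-based voxel
#'   coordinates); may lie below the grid so the shell is truncated at the
#'   bottom face. `NULL` centers the shell in-plane and places it
#'   vertically so the top clears the grid by the margin used in
#'   validation.
#' @param rotation rotation about the vertical axis (degrees).
#' @param tilt tilt about the in-plane x axis (degrees).
#' @param surface_noise_amplitude amplitude (voxels) of the smooth radial
#'   perturbation of the outer surface; 0 disables it.
#' @param seed integer seed driving the noise harmonics.
#' @return an object of class `phantom_params`.
#' @export
phantom_params <- function(outer_semi_axes, shell_thickness,
                           center = NULL, rotation = 0, tilt = 0,
                           surface_noise_amplitude = 0, seed = 0L) {
  outer_semi_axes <- as.numeric(outer_semi_axes)
  if (length(outer_semi_axes) != 3L || any(outer_semi_axes <= 0))
    stop("`outer_semi_axes` must be 3 positive lengths")
  if (!is.numeric(shell_thickness) || shell_thickness <= 0)
    stop("`shell_thickness` must be positive")
  if (shell_thickness >= min(outer_semi_axes))
    stop("`shell_thickness` must be smaller than the smallest outer semi-axis")
  if (surface_noise_amplitude < 0)
    stop("`surface_noise_amplitude` must be nonnegative")
  structure(list(outer_semi_axes = outer_semi_axes,
                 shell_thickness = as.numeric(shell_thickness),
                 center = if (is.null(center)) NULL else as.numeric(center),
                 rotation = as.numeric(rotation), tilt = as.numeric(tilt),
                 surface_noise_amplitude = as.numeric(surface_noise_amplitude),
                 seed = as.integer(seed)),
            class = "phantom_params")
}

# support (half-extent) of the rotated outer ellipsoid along a world axis
ellipsoid_support <- function(axes, R, world_axis) {
  u <- crossprod(R, world_axis)          # R^T u
  sqrt(sum((axes * as.numeric(u))^2))
}

# smooth degree-2 spherical harmonic field evaluated on unit directions
harmonic_field <- function(ux, uy, uz, coef) {
  coef[1] * ux * uy + coef[2] * uy * uz + coef[3] * ux * uz +
    coef[4] * (ux^2 - uy^2) + coef[5] * (3 * uz^2 - 1) / 2
}

#' Generate one synthetic cranial shell
#'
#' Voxelizes the ellipsoid-difference shell described by `params` on the
#' target grid, truncated at the grid's bottom face (open bottom).
#' Deterministic given `params$seed`.
#'
#' @param params a [phantom_params()] object.
#' @param grid_shape integer vector of 3, default `c(112, 112, 40)`.
#' @return a binary `voxel_volume`; the occupied voxels form a single
#'   connected shell interior to the grid except at the open bottom face.
#' @export
generate_phantom <- function(params, grid_shape = c(112, 112, 40)) {
  if (!inherits(params, "phantom_params")) stop("`params` must be phantom_params")
  gs <- as.integer(grid_shape)
  if (length(gs) != 3L || any(gs < 8L)) stop("`grid_shape` must be 3 ints >= 8")
  a <- params$outer_semi_axes
  amp <- params$surface_noise_amplitude
  R <- rot_x(params$tilt) %*% rot_z(params$rotation)
  margin <- 2
  sup <- vapply(1:3, function(i)
    ellipsoid_support(a, R, diag(3)[, i]), numeric(1)) + amp
  ctr <- params$center
  if (is.null(ctr))
    ctr <- c((gs[1] - 1) / 2, (gs[2] - 1) / 2, (gs[3] - 1) - margin - sup[3])
  lims <- ctr + sup
  lims_lo <- ctr[1:2] - sup[1:2]
  if (lims[1] > gs[1] - 1 - margin || lims_lo[1] < margin ||
      lims[2] > gs[2] - 1 - margin || lims_lo[2] < margin)
    stop(sprintf(
      "shell does not fit: in-plane extent [%.1f, %.1f] x [%.1f, %.1f] violates the %d-voxel margin of the %d x %d plane",
      lims_lo[1], lims[1], lims_lo[2], lims[2], margin, gs[1], gs[2]))
  if (lims[3] > gs[3] - 1 - margin)
    stop(sprintf(
      "shell does not fit: top extent %.1f violates the %d-voxel margin below slice %d",
      lims[3], margin, gs[3] - 1))
  coef <- if (amp > 0)
    with_seed(params$seed, stats::rnorm(5, sd = 1 / sqrt(2.5)))
  else rep(0, 5)

  px <- (0:(gs[1] - 1)) - ctr[1]
  py <- (0:(gs[2] - 1)) - ctr[2]
  pz <- (0:(gs[3] - 1)) - ctr[3]
  # body-frame coordinates q = R^T p, built by broadcasting
  q1 <- outer(outer(R[1, 1] * px, R[2, 1] * py, "+"), R[3, 1] * pz, "+")
  q2 <- outer(outer(R[1, 2] * px, R[2, 2] * py, "+"), R[3, 2] * pz, "+")
  q3 <- outer(outer(R[1, 3] * px, R[2, 3] * py, "+"), R[3, 3] * pz, "+")
  rad <- sqrt(q1^2 + q2^2 + q3^2)
  rad[rad == 0] <- 1
  delta <- if (amp > 0) {
    amp / mean(a) * harmonic_field(q1 / rad, q2 / rad, q3 / rad, coef)
  } else 0
  rho_out <- sqrt((q1 / a[1])^2 + (q2 / a[2])^2 + (q3 / a[3])^2)
  ai <- a - params$shell_thickness
  rho_in <- sqrt((q1 / ai[1])^2 + (q2 / ai[2])^2 + (q3 / ai[3])^2)
  occ <- (rho_out <= 1 + delta) & (rho_in > 1 + delta)
  voxel_volume(array(as.numeric(occ), gs))
}

#' Default inter-subject variation ranges for a grid
#'
#' Parameter ranges used by [generate_cohort()], scaled to the grid so the
#' full, reduced and test profiles produce geometrically similar cohorts:
#' outer semi-axes around 0.35-0.43 of the plane extent, vertical
#' semi-axis exceeding the grid depth (so the bottom face truncates the
#' shell), thickness around 4-7 voxels at the full 112-voxel plane, mild
#' pose perturbation and low-amplitude surface noise.
#'
#' @param grid_shape integer vector of 3.
#' @return a named list of `c(lo, hi)` ranges.
#' @export
default_variation <- function(grid_shape = c(112, 112, 40)) {
  gs <- as.numeric(grid_shape)
  # hard cap so that jitter + surface noise + pose mixing always clears
  # the 2-voxel boundary margin, also on small grids
  cap <- min(gs[1:2]) / 2 - 3.6 - 0.03 * min(gs[1:2]) -
    (0.137 * gs[3])^2 / (0.7 * min(gs[1:2]))
  list(semi_axis_x   = c(min(0.34 * gs[1], 0.93 * cap),
                         min(0.41 * gs[1], cap)),
       semi_axis_y   = c(min(0.36 * gs[2], 0.94 * cap),
                         min(0.42 * gs[2], cap)),
       semi_axis_z   = c(1.05, 1.30) * gs[3],
       thickness     = c(0.040, 0.065) * gs[1],
       rotation      = c(-10, 10),
       tilt          = c(-6, 6),
       center_jitter = c(-0.015, 0.015) * gs[1],
       noise_amplitude = c(0, 0.015) * gs[1])
}

#' Sample one phantom's parameters from variation ranges
#'
#' @param variation named list of ranges as from [default_variation()].
#' @param grid_shape integer vector of 3.
#' @param seed integer seed; the draw is a pure function of it.
#' @return a [phantom_params()] object.
#' @export
sample_phantom_params <- function(variation, grid_shape, seed) {
  rng <- function(r) stats::runif(1, r[1], r[2])
  with_seed(seed, {
    a <- c(rng(variation$semi_axis_x), rng(variation$semi_axis_y),
           rng(variation$semi_axis_z))
    th <- rng(variation$thickness)
    rot <- rng(variation$rotation)
    tilt <- rng(variation$tilt)
    jit <- c(rng(variation$center_jitter), rng(variation$center_jitter))
    amp <- rng(variation$noise_amplitude)
    gs <- as.numeric(grid_shape)
    R <- rot_x(tilt) %*% rot_z(rot)
    supz <- ellipsoid_support(a, R, c(0, 0, 1)) + amp
    ctr <- c((gs[1] - 1) / 2 + jit[1], (gs[2] - 1) / 2 + jit[2],
             (gs[3] - 1) - 2 - supz)
    phantom_params(a, th, center = ctr, rotation = rot, tilt = tilt,
                   surface_noise_amplitude = amp, seed = seed)
  })
}

#' Generate a reproducible phantom cohort
#'
#' Draws `n` phantoms with parameters sampled independently from
#' `variation`; per-phantom seeds are derived from the master seed, so the
#' cohort is a pure function of `(n, variation, seed)`.
#'
#' @param n number of phantoms, >= 1.
#' @param variation named list of non-degenerate ranges; default
#'   [default_variation()] for the grid.
#' @param seed master integer seed.
#' @param grid_shape integer vector of 3.
#' @return a list of `n` binary `voxel_volume`s with the sampled
#'   `phantom_params` attached as attribute `"params"`.
#' @export
generate_cohort <- function(n, variation = NULL, seed = 1L,
                            grid_shape = c(112, 112, 40)) {
  if (!is.numeric(n) || n < 1) stop("`n` must be >= 1")
  if (is.null(variation)) variation <- default_variation(grid_shape)
  needed <- c("semi_axis_x", "semi_axis_y", "semi_axis_z", "thickness",
              "rotation", "tilt", "center_jitter", "noise_amplitude")
  if (!all(needed %in% names(variation)))
    stop("`variation` is missing ranges: ",
         paste(setdiff(needed, names(variation)), collapse = ", "))
  for (nm in needed) {
    r <- variation[[nm]]
    if (length(r) != 2L || anyNA(r) || r[2] < r[1])
      stop("invalid range for `", nm, "`")
  }
  if (variation$semi_axis_x[1] <= 0 || variation$thickness[1] <= 0)
    stop("degenerate variation ranges: sizes must be positive")
  seeds <- derive_seeds(seed, n)
  lapply(seq_len(n), function(i) {
    p <- sample_phantom_params(variation, grid_shape, seeds[i])
    vol <- generate_phantom(p, grid_shape)
    attr(vol, "params") <- p
    vol
  })
}

# reproducible stream of sub-seeds below 2^31
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE))
    get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", old, envir = genv)
  })
  set.seed(seed)
  code
}

#' Connected components of a binary volume
#'
#' 6-connectivity component labelling, used to verify that generated
#' shells are single connected components.
#'
#' @param vol a binary `voxel_volume` or 3D array.
#' @return integer array of labels (0 = background) with attribute `"n"`,
#'   the number of components.
#' @export
label_components <- function(vol) {
  v <- as_values(vol)
  lab <- .cn_label6(as.numeric(v), as.integer(dim(v)))
  n <- attr(lab, "n")
  out <- array(lab, dim(v))
  attr(out, "n") <- n
  out
}

#' Binary erosion / dilation
#'
#' One or more steps of 6-neighbourhood morphology; voxels outside the
#' grid are treated as empty.
#'
#' @param vol a binary `voxel_volume` or 3D array.
#' @param steps number of elementary steps (radius).
#' @return a binary `voxel_volume`.
#' @export
erode <- function(vol, steps = 1L) morph_n(vol, steps, dilate = FALSE)

#' @rdname erode
#' @export
dilate <- function(vol, steps = 1L) morph_n(vol, steps, dilate = TRUE)

morph_n <- function(vol, steps, dilate) {
  v <- as.numeric(as_values(vol))
  d <- as.integer(dim(as_values(vol)))
  for (i in seq_len(steps)) v <- .cn_morph6(v, d, dilate)
  voxel_volume(array(v, d), vox_spacing(vol))
}
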