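# Six families of 3D defect masks and supervised training pairs.
#
# Cylinder-family masks have boundaries parallel to the axial (z)
# direction: their in-plane cross-section is identical on every slice and
# every occupied column spans the full grid depth. Ellipsoid-family
# boundaries are curved. "Mixed" families are unions of 2-3 overlapping
# primitives of the base family, giving irregular compound outlines.
# Defects are applied by exact Boolean subtraction; the removed portion of
# the skull is the ideal implant P.

DEFECT_FAMILIES <- c("symmetric_ellipsoid", "ellipsoid", "mixed_ellipsoid",
                     "cylinder", "elliptical_cylinder",
                     "mixed_elliptical_cylinder")

#' Defect-mask families
#' @return character vector of the six supported mask families.
#' @export
defect_families <- function() DEFECT_FAMILIES

# evaluate one ellipsoid primitive into an existing array (in place union)
add_ellipsoid <- function(m, center, semi_axes, rotation) {
  gs <- dim(m)
  R <- rot_z(rotation)
  sup <- vapply(1:3, function(i)
    ellipsoid_support(semi_axes, R, diag(3)[, i]), numeric(1))
  lo <- pmax(0, floor(center - sup))
  hi <- pmin(gs - 1, ceiling(center + sup))
  if (any(lo > hi)) stop("defect primitive lies entirely outside the grid")
  ix <- (lo[1]:hi[1])
  iy <- (lo[2]:hi[2])
  iz <- (lo[3]:hi[3])
  px <- ix - center[1]; py <- iy - center[2]; pz <- iz - center[3]
  q1 <- outer(outer(R[1, 1] * px, R[2, 1] * py, "+"), R[3, 1] * pz, "+")
  q2 <- outer(outer(R[1, 2] * px, R[2, 2] * py, "+"), R[3, 2] * pz, "+")
  q3 <- outer(outer(R[1, 3] * px, R[2, 3] * py, "+"), R[3, 3] * pz, "+")
  inside <- (q1 / semi_axes[1])^2 + (q2 / semi_axes[2])^2 +
    (q3 / semi_axes[3])^2 <= 1
  sub <- m[ix + 1, iy + 1, iz + 1, drop = FALSE]
  m[ix + 1, iy + 1, iz + 1] <- pmax(sub, as.numeric(inside))
  m
}

# elliptical cylinder, axis parallel to z, spanning the full grid depth
add_cylinder <- function(m, center_xy, semi_axes_xy, rotation) {
  gs <- dim(m)
  a <- rotation * pi / 180
  sup <- c(sqrt((semi_axes_xy[1] * cos(a))^2 + (semi_axes_xy[2] * sin(a))^2),
           sqrt((semi_axes_xy[1] * sin(a))^2 + (semi_axes_xy[2] * cos(a))^2))
  lo <- pmax(0, floor(center_xy - sup))
  hi <- pmin(gs[1:2] - 1, ceiling(center_xy + sup))
  if (any(lo > hi)) stop("defect primitive lies entirely outside the grid")
  ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]
  px <- ix - center_xy[1]; py <- iy - center_xy[2]
  q1 <- outer(cos(a) * px, sin(a) * py, "+")
  q2 <- outer(-sin(a) * px, cos(a) * py, "+")
  inside <- (q1 / semi_axes_xy[1])^2 + (q2 / semi_axes_xy[2])^2 <= 1
  for (k in seq_len(gs[3]))
    m[ix + 1, iy + 1, k] <- pmax(m[ix + 1, iy + 1, k], as.numeric(inside))
  m
}

#' Construct a defect mask
#'
#' Builds a binary removal mask of one of the six families. A
#' `symmetric_ellipsoid` has equal in-plane semi-axes; cylinder-family
#' masks span the full grid depth with z-parallel boundaries; mixed
#' families are unions of at least two overlapping primitives.
#'
#' Family parameters (`params`):
#' \describe{
#'   \item{symmetric_ellipsoid}{`center` (3), `r_plane`, `r_z`}
#'   \item{ellipsoid}{`center` (3), `semi_axes` (3), optional `rotation`}
#'   \item{cylinder}{`center` (2, in-plane), `radius`}
#'   \item{elliptical_cylinder}{`center` (2), `semi_axes` (2), optional
#'     `rotation`}
#'   \item{mixed_*}{`components`: list of >= 2 base-family param lists}
#' }
#'
#' @param family one of [defect_families()].
#' @param params named list of family parameters (above).
#' @param grid_shape integer vector of 3.
#' @param seed integer recorded with the mask (masks are deterministic
#'   given family and params).
#' @return an object of class `defect_mask` with fields `values` (binary
#'   `voxel_volume`), `family`, `params`, `seed`, `crosses_midline`.
#' @export
make_mask <- function(family, params, grid_shape, seed = 0L) {
  family <- match.arg(family, DEFECT_FAMILIES)
  gs <- as.integer(grid_shape)
  m <- array(0, gs)
  add_one <- function(m, fam, p) {
    switch(fam,
      symmetric_ellipsoid = add_ellipsoid(m, p$center,
        c(p$r_plane, p$r_plane, p$r_z), 0),
      ellipsoid = add_ellipsoid(m, p$center, p$semi_axes,
        if (is.null(p$rotation)) 0 else p$rotation),
      cylinder = add_cylinder(m, p$center[1:2], c(p$radius, p$radius), 0),
      elliptical_cylinder = add_cylinder(m, p$center[1:2], p$semi_axes[1:2],
        if (is.null(p$rotation)) 0 else p$rotation))
  }
  if (family %in% c("mixed_ellipsoid", "mixed_elliptical_cylinder")) {
    if (is.null(params$components) || length(params$components) < 2L)
      stop("mixed families need >= 2 primitive components")
    base <- if (family == "mixed_ellipsoid") "ellipsoid"
            else "elliptical_cylinder"
    for (p in params$components) m <- add_one(m, base, p)
  } else {
    m <- add_one(m, family, params)
  }
  if (sum(m) == 0) stop("mask is empty on this grid")
  mid <- (gs[1] - 1) / 2
  occ_x <- which(apply(m, 1, sum) > 0) - 1
  crosses <- any(occ_x <= mid) && any(occ_x >= mid)
  structure(list(values = voxel_volume(m), family = family, params = params,
                 seed = as.integer(seed), crosses_midline = crosses),
            class = "defect_mask")
}

#' @export
print.defect_mask <- function(x, ...) {
  cat(sprintf("<defect_mask %s, %d voxels%s>\n", x$family,
              voxel_count(x$values),
              if (x$crosses_midline) ", crosses mid-sagittal plane" else ""))
  invisible(x)
}

#' Apply a defect mask to an intact model
#'
#' Exact set algebra: `defective = intact AND NOT mask`,
#' `ideal_implant = intact AND mask`. No resampling is involved, so the
#' pair invariants hold exactly: defective and ideal implant are disjoint
#' and their union is the intact model.
#'
#' @param intact a binary `voxel_volume`.
#' @param mask a `defect_mask` (or binary `voxel_volume`) of the same
#'   shape.
#' @return an object of class `training_pair` with fields `defective`,
#'   `intact`, `mask`, `ideal_implant`.
#' @export
apply_defect <- function(intact, mask) {
  mv <- if (inherits(mask, "defect_mask")) mask$values else mask
  if (!is_binary_volume(intact)) stop("`intact` must be binary")
  check_same_shape(intact, mv)
  ideal <- vox_and(intact, mv)
  if (voxel_count(ideal) == 0)
    stop("degenerate pair: mask does not intersect the intact model")
  structure(list(defective = vox_subtract(intact, mv),
                 intact = intact,
                 mask = if (inherits(mask, "defect_mask")) mask else NULL,
                 ideal_implant = ideal),
            class = "training_pair")
}

#' @export
print.training_pair <- function(x, ...) {
  cat(sprintf("<training_pair %s: intact %d, defective %d, implant %d voxels (fraction %.3f)>\n",
              if (!is.null(x$mask)) x$mask$family else "?",
              voxel_count(x$intact), voxel_count(x$defective),
              voxel_count(x$ideal_implant), defect_fraction(x)))
  invisible(x)
}

#' Defect volume fraction of a pair
#'
#' @param pair a `training_pair`.
#' @return voxel count of the ideal implant divided by the voxel count of
#'   the intact model, in (0, 1\].
#' @export
defect_fraction <- function(pair) {
  ni <- voxel_count(pair$intact)
  if (ni == 0) stop("intact model is empty")
  voxel_count(pair$ideal_implant) / ni
}

sample_primitive <- function(family, center, size, rot, gs) {
  switch(family,
    symmetric_ellipsoid = list(center = center,
                               r_plane = size[1], r_z = size[2]),
    ellipsoid = list(center = center, semi_axes = size[1:3], rotation = rot),
    cylinder = list(center = center[1:2], radius = size[1]),
    elliptical_cylinder = list(center = center[1:2], semi_axes = size[1:2],
                               rotation = rot))
}

#' Randomly sample one training pair
#'
#' Draws a mask family uniformly from the six, centers a primitive on a
#' randomly chosen occupied voxel in the upper part of the shell, and
#' rescales the primitive until the defect volume fraction falls inside
#' `fraction_range` (bounded retries). Reproducible given `seed`.
#'
#' @param intact a binary `voxel_volume`.
#' @param seed integer seed.
#' @param fraction_range target interval of defect fractions, a subset of
#'   (0, 1).
#' @param families families to draw from (default all six, equal
#'   probability).
#' @param max_retries rescaling/resampling budget.
#' @return a `training_pair`.
#' @export
sample_training_pair <- function(intact, seed,
                                 fraction_range = c(0.05, 0.35),
                                 families = defect_families(),
                                 max_retries = 60L) {
  if (fraction_range[1] <= 0 || fraction_range[2] >= 1 ||
      fraction_range[1] >= fraction_range[2])
    stop("`fraction_range` must be an interval inside (0, 1)")
  v <- as_values(intact)
  gs <- dim(v)
  n_int <- sum(v)
  if (n_int == 0) stop("intact model is empty")
  with_seed(seed, {
    fam <- sample(families, 1)
    f_target <- stats::runif(1, fraction_range[1], fraction_range[2])
    occ <- which(v > 0, arr.ind = TRUE) - 1
    zq <- stats::quantile(occ[, 3], 0.4)
    upper <- occ[occ[, 3] >= zq, , drop = FALSE]
    achieved <- numeric(0)
    # initial linear scale: defect removes roughly a shell patch whose
    # area grows with the square of the primitive size
    r0 <- 0.22 * gs[1] * sqrt(f_target / 0.15)
    shape_jit <- stats::runif(3, 0.6, 1.4)
    rot <- stats::runif(1, 0, 180)
    zfrac <- stats::runif(1, 0.5, 1)
    comp_n <- sample(2:3, 1)
    comp_off <- matrix(stats::runif(3 * comp_n, -0.8, 0.8), comp_n, 3)
    comp_sc <- stats::runif(comp_n, 0.5, 1)
    for (i in seq_len(max_retries)) {
      r0 <- min(max(r0, 1.5), 0.45 * max(gs))
      ctr <- upper[sample(nrow(upper), 1), ] + stats::runif(3, -1, 1)
      base <- sub("mixed_", "", fam)
      params <- if (startsWith(fam, "mixed_")) {
        comps <- lapply(seq_len(comp_n), function(j) {
          sample_primitive(base, ctr + comp_off[j, ] * r0 * comp_sc[j],
                           rep(r0 * comp_sc[j], 3) * shape_jit,
                           rot + 40 * j, gs)
        })
        list(components = comps)
      } else {
        size <- switch(fam,
          symmetric_ellipsoid = c(r0, r0 * zfrac, r0),
          ellipsoid = r0 * shape_jit,
          cylinder = c(r0 * 0.8, r0),
          elliptical_cylinder = r0 * shape_jit)
        sample_primitive(fam, ctr, size, rot, gs)
      }
      mask <- tryCatch(make_mask(fam, params, gs, seed),
                       error = function(e) NULL)
      if (is.null(mask)) {           # primitive missed the grid: shrink
        r0 <- r0 * 0.7
        next
      }
      f <- sum(v * as_values(mask$values)) / n_int
      if (f >= fraction_range[1] && f <= fraction_range[2])
        return(apply_defect(intact, mask))
      achieved <- c(achieved, f)
      r0 <- r0 * min(1.8, max(0.6, sqrt(f_target / max(f, 1e-4))))
    }
    stop(sprintf(
      "defect sampling failed after %d retries (achieved fractions %s ... target [%.3f, %.3f])",
      max_retries,
      paste(sprintf("%.3f", utils::tail(achieved, 3)), collapse = ", "),
      fraction_range[1], fraction_range[2]))
  })
}

#' Build training pairs for a phantom cohort
#'
#' One pair per cohort member, with per-pair seeds derived from the master
#' seed.
#'
#' @param cohort list of binary `voxel_volume`s.
#' @param seed master integer seed.
#' @param fraction_range passed to [sample_training_pair()].
#' @param families passed to [sample_training_pair()].
#' @return list of `training_pair`s.
#' @export
make_training_pairs <- function(cohort, seed,
                                fraction_range = c(0.05, 0.35),
                                families = defect_families()) {
  seeds <- derive_seeds(seed, length(cohort))
  lapply(seq_along(cohort), function(i)
    sample_training_pair(cohort[[i]], seeds[i], fraction_range, families))
}
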