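# Voxel-volume data model and CT preprocessing.
#
# A voxel_volume is a dense 3D rectilinear grid of occupancy values in
# [0, 1] (binary volumes contain only {0, 1}), with x and y spanning the
# axial plane and z the vertical axis, index increasing upward. All
# coordinates are 0-based voxel indices; pairwise Boolean operations
# require identical shapes.

#' Construct a voxel volume
#'
#' Wraps a dense 3D array of occupancy values. Binary volumes contain only
#' 0 and 1; probabilistic volumes (e.g. network output) lie in \[0, 1\].
#' Axis convention: x and y span the axial plane, z is vertical with the
#' index increasing upward.
#'
#' @param values numeric 3D array with values in \[0, 1\].
#' @param spacing optional numeric vector of 3 positive voxel spacings (mm);
#'   may be `NULL` for synthetic data.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(values, spacing = NULL) {
  values <- as.array(values)
  if (length(dim(values)) != 3L)
    stop("`values` must be a 3D array")
  if (anyNA(values) || any(values < 0) || any(values > 1))
    stop("voxel values must be finite and lie in [0, 1]")
  if (!is.null(spacing)) {
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be 3 positive lengths (mm)")
  }
  structure(list(values = values, spacing = spacing),
            class = "voxel_volume")
}

#' Construct a CT intensity volume
#'
#' Holds calibrated CT intensities (Hounsfield units after applying the
#' scanner rescale), prior to bone thresholding.
#'
#' @param values numeric 3D array of finite intensities.
#' @param spacing numeric vector of 3 positive voxel spacings (mm).
#' @return an object of class `hu_volume`.
#' @export
hu_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- as.array(values)
  if (length(dim(values)) != 3L) stop("`values` must be a 3D array")
  if (anyNA(values) || any(!is.finite(values)))
    stop("intensity values must be finite")
  spacing <- as.numeric(spacing)
  if (length(spacing) != 3L || any(spacing <= 0))
    stop("`spacing` must be 3 positive lengths (mm)")
  structure(list(values = values, spacing = spacing), class = "hu_volume")
}

#' @export
dim.voxel_volume <- function(x) dim(x$values)

#' @export
as.array.voxel_volume <- function(x, ...) x$values

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$values)
  occ <- sum(x$values > 0)
  cat(sprintf("<voxel_volume %d x %d x %d, %s, %d occupied (%.1f%%)>\n",
              d[1], d[2], d[3],
              if (is_binary_volume(x)) "binary" else "probabilistic",
              occ, 100 * occ / prod(d)))
  invisible(x)
}

#' Test whether a volume is binary
#' @param vol a `voxel_volume`.
#' @return `TRUE` if every value is 0 or 1.
#' @export
is_binary_volume <- function(vol) {
  v <- as.array(vol)
  all(v == 0 | v == 1)
}

#' Count occupied voxels
#' @param vol a `voxel_volume` or 3D array.
#' @return number of voxels with value > 0.5.
#' @export
voxel_count <- function(vol) sum(as.array(vol) > 0.5)

as_values <- function(vol) {
  if (inherits(vol, "voxel_volume")) vol$values else as.array(vol)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(as_values(a)), dim(as_values(b))))
    stop("volumes must have identical shapes")
}

#' Voxelwise Boolean operations
#'
#' Exact set algebra on binary volumes of identical shape:
#' intersection (`vox_and`), union (`vox_or`), complement (`vox_not`),
#' and set difference `a AND NOT b` (`vox_subtract`).
#'
#' @param a,b binary `voxel_volume`s of identical shape.
#' @return a binary `voxel_volume`.
#' @export
vox_and <- function(a, b) {
  check_same_shape(a, b)
  voxel_volume(as_values(a) * as_values(b), vox_spacing(a))
}

#' @rdname vox_and
#' @export
vox_or <- function(a, b) {
  check_same_shape(a, b)
  voxel_volume(pmax(as_values(a), as_values(b)), vox_spacing(a))
}

#' @rdname vox_and
#' @export
vox_not <- function(a) voxel_volume(1 - as_values(a), vox_spacing(a))

#' @rdname vox_and
#' @export
vox_subtract <- function(a, b) {
  check_same_shape(a, b)
  voxel_volume(as_values(a) * (1 - as_values(b)), vox_spacing(a))
}

vox_spacing <- function(vol) {
  if (inherits(vol, "voxel_volume")) vol$spacing else NULL
}

#' Threshold a CT volume to a binary bone model
#'
#' Bone occupies a characteristic high band of the Hounsfield scale; a
#' voxel is kept iff its intensity lies in the closed interval
#' \[`lo`, `hi`\]. The default band \[1200, 1817\] preserves cranial bone
#' while discarding soft tissue.
#'
#' @param hu an `hu_volume` (or numeric 3D array).
#' @param lo,hi interval bounds, `lo < hi`; the interval is closed at both
#'   ends.
#' @return a binary `voxel_volume`.
#' @export
threshold_hu <- function(hu, lo = 1200, hi = 1817) {
  if (!(is.numeric(lo) && is.numeric(hi)) || lo >= hi)
    stop("`lo` must be strictly less than `hi`")
  v <- if (inherits(hu, "hu_volume")) hu$values else as.array(hu)
  sp <- if (inherits(hu, "hu_volume")) hu$spacing else NULL
  voxel_volume(array(as.numeric(v >= lo & v <= hi), dim(v)), sp)
}

binarize_values <- function(v, threshold = 0.5) {
  array(as.numeric(v >= threshold), dim(v))
}

#' Crop and downsample a cranial model to the working grid
#'
#' Downsamples the axial plane (e.g. 512 x 512 from CT) to the target
#' plane resolution by trilinear interpolation followed by 0.5
#' binarization, then crops the z-range to the topmost band of occupied
#' slices covering the target depth (the upper cranium). Slices below the
#' occupied band are zero-padded if the input is shallower than the
#' target.
#'
#' @param vol a binary `voxel_volume`; plane resolution must be at least
#'   the target plane resolution.
#' @param target_shape integer vector of 3, default `c(112, 112, 40)`.
#' @return a binary `voxel_volume` of shape `target_shape`.
#' @export
crop_and_downsample <- function(vol, target_shape = c(112, 112, 40)) {
  v <- as_values(vol)
  d <- dim(v)
  if (d[1] < target_shape[1] || d[2] < target_shape[2])
    stop("input plane resolution must be >= target plane resolution")
  if (sum(v) == 0)
    stop("input contains no occupied voxels")
  if (d[1] != target_shape[1] || d[2] != target_shape[2]) {
    A <- diag(c(d[1] / target_shape[1], d[2] / target_shape[2], 1))
    out <- .cn_affine_resample(
      as.numeric(v), as.integer(d), A,
      (d - 1) / 2, c((target_shape[1:2] - 1) / 2, (d[3] - 1) / 2),
      as.integer(c(target_shape[1:2], d[3])))
    v <- binarize_values(array(out, c(target_shape[1:2], d[3])))
  } else {
    v <- binarize_values(v)
  }
  if (dim(v)[3] == target_shape[3])       # depth already normalized
    return(voxel_volume(v, vox_spacing(vol)))
  occ <- which(apply(v, 3, sum) > 0)
  ztop <- max(occ)
  zlo <- ztop - target_shape[3] + 1
  out <- array(0, target_shape)
  src <- max(1, zlo):ztop
  out[, , (target_shape[3] - length(src) + 1):target_shape[3]] <- v[, , src]
  voxel_volume(out, vox_spacing(vol))
}

#' Augmentation grid of rigid perturbations
#'
#' The pose grid used to expand a cranial cohort: rotations about the
#' vertical axis, tilts about an in-plane axis, and vertical translations.
#' The default 7 x 7 x 2 grid uses 2-degree steps and a 2-voxel shift,
#' yielding 98 variants per model.
#'
#' @param rotations rotation angles about z (degrees).
#' @param tilts tilt angles about the in-plane x axis (degrees).
#' @param z_translations vertical offsets (voxels).
#' @return an object of class `augmentation_grid`.
#' @export
augmentation_grid <- function(rotations = seq(-6, 6, by = 2),
                              tilts = seq(-6, 6, by = 2),
                              z_translations = c(0, 2)) {
  if (!length(rotations) || !length(tilts) || !length(z_translations))
    stop("augmentation grid must be non-empty in every factor")
  structure(list(rotations = as.numeric(rotations),
                 tilts = as.numeric(tilts),
                 z_translations = as.numeric(z_translations)),
            class = "augmentation_grid")
}

rot_z <- function(deg) {
  a <- deg * pi / 180
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

rot_x <- function(deg) {
  a <- deg * pi / 180
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}

#' Expand one model over an augmentation grid
#'
#' Applies every combination of rotation, tilt and vertical translation
#' (in that order, about the volume center) to a binary volume, each
#' followed by trilinear resampling and 0.5 re-binarization. The result
#' list follows the lexicographic product order: rotation slowest, then
#' tilt, then translation.
#'
#' @param vol a binary `voxel_volume`.
#' @param grid an [augmentation_grid()].
#' @param clip_tolerance relative occupancy loss above which a clipped
#'   variant triggers a warning (the variant is still returned).
#' @return a list of binary `voxel_volume`s of length
#'   `|rotations| * |tilts| * |z_translations|`.
#' @export
augment <- function(vol, grid = augmentation_grid(), clip_tolerance = 0.05) {
  if (!inherits(grid, "augmentation_grid")) stop("`grid` must be an augmentation_grid")
  v <- as_values(vol)
  if (!all(v == 0 | v == 1)) stop("`vol` must be binary")
  d <- dim(v)
  ctr <- (d - 1) / 2
  n_in <- sum(v)
  out <- vector("list",
                length(grid$rotations) * length(grid$tilts) *
                  length(grid$z_translations))
  idx <- 1L
  for (rot in grid$rotations) {
    for (tilt in grid$tilts) {
      R <- rot_x(tilt) %*% rot_z(rot)
      for (tz in grid$z_translations) {
        if (rot == 0 && tilt == 0 && tz == 0) {
          out[[idx]] <- voxel_volume(v, vox_spacing(vol))
          idx <- idx + 1L
          next
        }
        res <- .cn_affine_resample(as.numeric(v), as.integer(d), t(R),
                                   ctr, ctr + c(0, 0, tz), as.integer(d))
        b <- binarize_values(array(res, d))
        lost <- 1 - sum(b) / n_in
        if (lost > clip_tolerance)
          warning(sprintf(
            "augmented variant (rot %g, tilt %g, dz %g) lost %.1f%% of its occupancy at the grid boundary",
            rot, tilt, tz, 100 * lost))
        out[[idx]] <- voxel_volume(b, vox_spacing(vol))
        idx <- idx + 1L
      }
    }
  }
  out
}

#' Read and write voxel volumes as NIfTI
#'
#' Binary volumes round-trip losslessly through NIfTI (`.nii`/`.nii.gz`).
#' On read, a volume stored with a non-canonical axis orientation is
#' reoriented to the package's x/y axial, z-up convention (RAS-like axes).
#'
#' @param path file path; the parent directory must exist for writing.
#' @param vol a `voxel_volume`.
#' @return `read_volume` returns a `voxel_volume`; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("malformed NIfTI file '", path, "': ",
                         conditionMessage(e)))
  try(RNifti::orientation(img) <- "RAS", silent = TRUE)
  sp <- tryCatch(RNifti::pixdim(img)[1:3], error = function(e) NULL)
  if (!is.null(sp) && (length(sp) != 3L || any(!is.finite(sp)) || any(sp <= 0)))
    sp <- NULL
  v <- array(as.numeric(img), dim(img)[1:3])
  v[v < 0] <- 0
  v[v > 1] <- 1
  voxel_volume(v, sp)
}

#' @rdname read_volume
#' @export
write_volume <- function(vol, path) {
  if (!dir.exists(dirname(path))) stop("directory does not exist: ", dirname(path))
  v <- as_values(vol)
  sp <- vox_spacing(vol)
  img <- RNifti::asNifti(v)
  if (is.null(sp)) sp <- c(1, 1, 1)
  RNifti::qform(img) <- structure(diag(c(sp, 1)), code = 2L)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}
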