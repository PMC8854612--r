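# From network completion to printable implant geometry:
# binarize -> Boolean-subtract the defective model -> (optionally)
# upsample, smooth and re-subtract at high resolution -> export an STL
# surface mesh.

#' Binarize a probabilistic volume
#'
#' @param prob a probabilistic `voxel_volume` (values in \[0, 1\]).
#' @param threshold threshold in (0, 1); a voxel is set iff its value is
#'   `>= threshold`.
#' @return a binary `voxel_volume`.
#' @export
binarize <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    stop("`threshold` must lie strictly inside (0, 1)")
  voxel_volume(binarize_values(as_values(prob), threshold),
               vox_spacing(prob))
}

#' Extract implant geometry by Boolean subtraction
#'
#' The implant is the completed model minus the defective model:
#' `implant = completed AND NOT defective`, exact set algebra. The result
#' never intersects the defective input.
#'
#' @param completed binary `voxel_volume` (network completion after
#'   binarization, or an intact model for the ideal case).
#' @param defective binary `voxel_volume` of the same shape.
#' @param provenance optional named list recorded with the implant
#'   (checkpoint id, threshold, settings).
#' @return an object of class `implant_model` with fields `volume` (a
#'   binary `voxel_volume`) and `provenance`.
#' @export
extract_implant <- function(completed, defective, provenance = list()) {
  check_same_shape(completed, defective)
  structure(list(volume = vox_subtract(completed, defective),
                 provenance = provenance),
            class = "implant_model")
}

#' @export
print.implant_model <- function(x, ...) {
  cat(sprintf("<implant_model %d voxels>\n", voxel_count(x$volume)))
  invisible(x)
}

#' High-resolution implant post-processing
#'
#' For fabrication the working-resolution implant is resampled to a
#' 4x-finer axial plane (e.g. 112 x 112 x 40 to 448 x 448 x 40),
#' smoothed — morphological closing followed by Gaussian smoothing and
#' 0.5 re-binarization — and then the high-resolution defective model is
#' subtracted again so that no residual voxel of the implant intersects
#' the skull. The re-subtraction is idempotent. If smoothing empties the
#' implant, the unsmoothed upsampled implant is used with a warning.
#'
#' @param implant an `implant_model` (or binary `voxel_volume`).
#' @param defective_highres binary `voxel_volume` at `target_shape`.
#' @param target_shape output shape; plane resolution must be 4x the
#'   working plane and depth unchanged (default `c(448, 448, 40)` for the
#'   full profile).
#' @param closing_radius morphological closing radius (voxels at high
#'   resolution).
#' @param sigma Gaussian standard deviation (voxels at high resolution).
#' @return an `implant_model` at `target_shape`.
#' @export
postprocess <- function(implant, defective_highres,
                        target_shape = c(448, 448, 40),
                        closing_radius = 1L, sigma = 1) {
  vol <- if (inherits(implant, "implant_model")) implant$volume else implant
  v <- as_values(vol)
  d <- dim(v)
  target_shape <- as.integer(target_shape)
  if (!identical(target_shape[1:2], 4L * d[1:2]) ||
      target_shape[3] != d[3])
    stop("`target_shape` must be 4x the working plane resolution with unchanged depth")
  if (!identical(dim(as_values(defective_highres)), target_shape))
    stop("`defective_highres` must be at the target shape")
  A <- diag(c(d[1] / target_shape[1], d[2] / target_shape[2], 1))
  up <- .cn_affine_resample(as.numeric(v), as.integer(d), A,
                            (d - 1) / 2,
                            c((target_shape[1:2] - 1) / 2, (d[3] - 1) / 2),
                            target_shape)
  up <- binarize_values(array(up, target_shape))
  sm <- up
  if (closing_radius > 0) {
    sm <- as_values(dilate(voxel_volume(sm), closing_radius))
    sm <- as_values(erode(voxel_volume(sm), closing_radius))
  }
  if (sigma > 0) {
    sm <- array(.cn_gauss3d(as.numeric(sm), target_shape, sigma),
                target_shape)
    sm <- binarize_values(sm)
  }
  out <- sm * (1 - as_values(defective_highres))
  if (sum(out) == 0 && sum(up) > 0) {
    warning("smoothing emptied the implant; falling back to the unsmoothed geometry")
    out <- up * (1 - as_values(defective_highres))
  }
  prov <- if (inherits(implant, "implant_model")) implant$provenance else list()
  prov$postprocess <- list(target_shape = target_shape,
                           closing_radius = closing_radius, sigma = sigma)
  structure(list(volume = voxel_volume(out, vox_spacing(vol)),
                 provenance = prov),
            class = "implant_model")
}

# exposed voxel faces as triangles; vertices at voxel corners scaled by
# spacing, outward normals, watertight for any 6-connected solid
voxel_faces <- function(v, spacing) {
  d <- dim(v)
  pad <- array(0, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- v
  tris <- list()
  # face template: for axis ax and side s (0 low, 1 high), 4 corner
  # offsets in CCW order seen from outside
  faces <- list(
    list(ax = 1, s = 0, n = c(-1, 0, 0),
         c = rbind(c(0,0,0), c(0,0,1), c(0,1,1), c(0,1,0))),
    list(ax = 1, s = 1, n = c(1, 0, 0),
         c = rbind(c(1,0,0), c(1,1,0), c(1,1,1), c(1,0,1))),
    list(ax = 2, s = 0, n = c(0, -1, 0),
         c = rbind(c(0,0,0), c(1,0,0), c(1,0,1), c(0,0,1))),
    list(ax = 2, s = 1, n = c(0, 1, 0),
         c = rbind(c(0,1,0), c(0,1,1), c(1,1,1), c(1,1,0))),
    list(ax = 3, s = 0, n = c(0, 0, -1),
         c = rbind(c(0,0,0), c(0,1,0), c(1,1,0), c(1,0,0))),
    list(ax = 3, s = 1, n = c(0, 0, 1),
         c = rbind(c(0,0,1), c(1,0,1), c(1,1,1), c(0,1,1))))
  occ <- which(pad > 0.5, arr.ind = TRUE)
  nb_off <- rbind(c(-1,0,0), c(1,0,0), c(0,-1,0), c(0,1,0),
                  c(0,0,-1), c(0,0,1))
  out_v <- list()
  out_n <- list()
  for (f in seq_len(6)) {
    nb <- occ + matrix(nb_off[f, ], nrow(occ), 3, byrow = TRUE)
    open <- pad[nb] <= 0.5
    if (!any(open)) next
    base <- occ[open, , drop = FALSE] - 2  # back to 0-based voxel corner
    fc <- faces[[f]]
    for (tri in list(c(1, 2, 3), c(1, 3, 4))) {
      verts <- lapply(tri, function(ci)
        t((t(base) + fc$c[ci, ]) * spacing))
      out_v[[length(out_v) + 1L]] <-
        cbind(verts[[1]], verts[[2]], verts[[3]])
      out_n[[length(out_n) + 1L]] <-
        matrix(fc$n, nrow(base), 3, byrow = TRUE)
    }
  }
  list(vertices = do.call(rbind, out_v), normals = do.call(rbind, out_n))
}

#' Export implant geometry as a binary STL mesh
#'
#' Writes the implant's voxel isosurface (exposed voxel faces, two
#' triangles each, with voxel spacing applied) as a watertight binary
#' STL. The mesh bounding box matches the occupied-voxel bounding box.
#'
#' @param implant an `implant_model` or binary `voxel_volume`; must be
#'   nonempty.
#' @param path output file path.
#' @return invisibly, the number of triangles written.
#' @export
export_mesh <- function(implant, path) {
  vol <- if (inherits(implant, "implant_model")) implant$volume else implant
  v <- as_values(vol)
  if (sum(v) == 0) stop("cannot mesh an empty implant")
  sp <- vox_spacing(vol)
  if (is.null(sp)) sp <- c(1, 1, 1)
  fm <- voxel_faces(v, sp)
  ntri <- nrow(fm$vertices)
  con <- file(path, "wb")
  on.exit(close(con))
  header <- charToRaw(sprintf("%-80s", "cranionet voxel isosurface"))
  writeBin(header[1:80], con)
  writeBin(as.integer(ntri), con, size = 4, endian = "little")
  dat <- t(cbind(fm$normals, fm$vertices))  # 12 floats per triangle
  for (i in seq_len(ntri)) {
    writeBin(as.numeric(dat[, i]), con, size = 4, endian = "little")
    writeBin(0L, con, size = 2, endian = "little")
  }
  invisible(ntri)
}

#' Read a binary STL mesh
#'
#' @param path STL file path.
#' @return list with `n_triangles`, `normals` (n x 3) and `vertices`
#'   (n x 9, the three corners of each triangle).
#' @export
read_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 80)
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  rec <- matrix(0, n, 12)
  for (i in seq_len(n)) {
    rec[i, ] <- readBin(con, "numeric", 12, size = 4, endian = "little")
    readBin(con, "integer", 1, size = 2, endian = "little")
  }
  list(n_triangles = n, normals = rec[, 1:3, drop = FALSE],
       vertices = rec[, 4:12, drop = FALSE])
}

#' Signed volume enclosed by a triangle mesh
#'
#' Divergence-theorem volume of a closed mesh as read by [read_stl()].
#'
#' @param mesh list as returned by [read_stl()].
#' @return enclosed volume in spacing units cubed.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  a <- v[, 1:3, drop = FALSE]
  b <- v[, 4:6, drop = FALSE]
  c_ <- v[, 7:9, drop = FALSE]
  cr <- cbind(b[, 2] * c_[, 3] - b[, 3] * c_[, 2],
              b[, 3] * c_[, 1] - b[, 1] * c_[, 3],
              b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  abs(sum(a * cr) / 6)
}
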