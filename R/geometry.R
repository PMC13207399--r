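# Coordinate-system handling: RAS/LPS conversion, rigid volume alignment and
# the world <-> voxel index transforms used throughout the patch pipeline.
#
# Conventions: world coordinates are in mm; voxel indices are 0-based and
# continuous unless explicitly rounded; volumes are axis-aligned (origin +
# positive spacing per axis) and carry a frame tag ("RAS" or "LPS").

#' Construct a voxel volume
#'
#' A rank-3 intensity grid with physical metadata: the world position of voxel
#' `(0,0,0)` (`origin`, mm), the per-axis voxel size (`spacing`, mm) and the
#' anatomical frame the coordinates live in.
#'
#' @param data 3D numeric array, indexed `(i, j, k)`.
#' @param origin Numeric length-3, world mm position of the first voxel.
#' @param spacing Numeric length-3, positive, mm per voxel along each axis.
#' @param frame `"LPS"` or `"RAS"`.
#' @return An object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, origin = c(0, 0, 0), spacing = c(1, 1, 1),
                         frame = c("LPS", "RAS")) {
  frame <- match.arg(frame)
  if (!is.array(data) || length(dim(data)) != 3L)
    stop("`data` must be a rank-3 array")
  origin <- as.numeric(origin)
  spacing <- as.numeric(spacing)
  stopifnot(length(origin) == 3L, length(spacing) == 3L,
            all(is.finite(origin)), all(is.finite(spacing)))
  if (any(spacing <= 0)) stop("spacing components must be > 0")
  structure(list(data = data, origin = origin, spacing = spacing,
                 frame = frame),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat("<voxel_volume> ", paste(dim(x$data), collapse = " x "),
      " voxels, frame ", x$frame, "\n", sep = "")
  cat("  origin  (mm):", format(x$origin, digits = 6), "\n")
  cat("  spacing (mm):", format(x$spacing, digits = 6), "\n")
  invisible(x)
}

volume_dims <- function(volume) dim(volume$data)

#' Convert points or a volume from RAS to LPS
#'
#' The Right-Anterior-Superior and Left-Posterior-Superior conventions differ
#' by the direction of the first two axes, so the x and y coordinates are
#' sign-flipped; z is preserved. For a volume, the data array is flipped along
#' i and j and the origin recomputed so every voxel keeps its physical world
#' position; for points, signs are negated directly.
#'
#' @param x A numeric length-3 point, an `n x 3` matrix of points, or a
#'   [voxel_volume()] tagged `"RAS"`.
#' @return The same kind of object, in the LPS frame. Passing an already-LPS
#'   volume is a no-op with a warning.
#' @export
ras_to_lps <- function(x) {
  if (inherits(x, "voxel_volume")) {
    if (x$frame == "LPS") {
      warning("volume is already in LPS; returning unchanged")
      return(x)
    }
    return(flip_xy_frame(x, "LPS"))
  }
  flip_xy_points(x)
}

#' Convert points or a volume from LPS to RAS
#'
#' Inverse of [ras_to_lps()]; the two conversions compose to the identity.
#' @inheritParams ras_to_lps
#' @return The same kind of object, in the RAS frame.
#' @export
lps_to_ras <- function(x) {
  if (inherits(x, "voxel_volume")) {
    if (x$frame == "RAS") {
      warning("volume is already in RAS; returning unchanged")
      return(x)
    }
    return(flip_xy_frame(x, "RAS"))
  }
  flip_xy_points(x)
}

flip_xy_points <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    x[, 1:2] <- -x[, 1:2]
    return(x)
  }
  stopifnot(length(x) == 3L)
  c(-x[1], -x[2], x[3])
}

flip_xy_frame <- function(volume, new_frame) {
  d <- volume_dims(volume)
  dat <- volume$data[d[1]:1, d[2]:1, , drop = FALSE]
  origin <- volume$origin
  # After negating x, the voxel previously at index (n-1) has the smallest
  # coordinate; flipping the array restores origin + positive spacing form.
  origin[1] <- -volume$origin[1] - volume$spacing[1] * (d[1] - 1)
  origin[2] <- -volume$origin[2] - volume$spacing[2] * (d[2] - 1)
  voxel_volume(dat, origin, volume$spacing, new_frame)
}

#' Volume center
#'
#' Computes the reference center used by the alignment procedure: half of the
#' element-wise product between the sum of the origin and spacing and the
#' volume dimensions, `0.5 * (origin + spacing) * dims`. Note this differs
#' from the usual geometric center of the voxel lattice, which is available as
#' [volume_center_geometric()]; alignment correctness is established
#' end-to-end rather than by either formula in isolation.
#'
#' @param origin Length-3 origin (mm), or a [voxel_volume()] (then `spacing`
#'   and `dims` are taken from it).
#' @param spacing Length-3 spacing (mm).
#' @param dims Length-3 integer volume dimensions.
#' @return Length-3 center (mm).
#' @export
volume_center <- function(origin, spacing = NULL, dims = NULL) {
  if (inherits(origin, "voxel_volume")) {
    v <- origin
    return(0.5 * (v$origin + v$spacing) * volume_dims(v))
  }
  stopifnot(length(origin) == 3L, length(spacing) == 3L, length(dims) == 3L,
            all(dims >= 0), all(dims == floor(dims)))
  0.5 * (as.numeric(origin) + as.numeric(spacing)) * as.numeric(dims)
}

#' Geometric center of the voxel lattice
#'
#' The conventional center `origin + 0.5 * spacing * (dims - 1)`, i.e. the
#' world position midway between the first and last voxel centers.
#' @inheritParams volume_center
#' @return Length-3 center (mm).
#' @export
volume_center_geometric <- function(origin, spacing = NULL, dims = NULL) {
  if (inherits(origin, "voxel_volume")) {
    v <- origin
    return(v$origin + 0.5 * v$spacing * (volume_dims(v) - 1))
  }
  as.numeric(origin) + 0.5 * as.numeric(spacing) * (as.numeric(dims) - 1)
}

#' Rigidly align a volume to an artery-tree center
#'
#' Translates the volume so its center (in the [volume_center()] sense) moves
#' to `tree_center`, optionally followed by a 180-degree rotation about the
#' x-axis through the new center (a -180 and +180 degree rotation about the
#' same axis coincide; it maps `y -> 2*cy - y`, `z -> 2*cz - z`). Both
#' operations are rigid: pairwise distances between voxel world positions are
#' preserved.
#'
#' @param volume A [voxel_volume()] in the LPS frame.
#' @param tree_center Length-3 target center (mm).
#' @param rotate_x_180 Apply the 180-degree x-rotation. Default `FALSE`;
#'   synthetic phantoms are generated frame-consistent and do not need it.
#' @return The aligned [voxel_volume()].
#' @export
align_volume_to_tree <- function(volume, tree_center, rotate_x_180 = FALSE) {
  stopifnot(inherits(volume, "voxel_volume"), length(tree_center) == 3L)
  if (volume$frame != "LPS")
    stop("volume must be in LPS before alignment; see ras_to_lps()")
  shift <- as.numeric(tree_center) - volume_center(volume)
  out <- volume
  out$origin <- volume$origin + shift
  if (rotate_x_180) {
    d <- volume_dims(out)
    ctr <- as.numeric(tree_center)
    # Flip j and k so indices still increase with y and z after rotation.
    out$data <- out$data[, d[2]:1, d[3]:1, drop = FALSE]
    out$origin[2] <- 2 * ctr[2] - (out$origin[2] + out$spacing[2] * (d[2] - 1))
    out$origin[3] <- 2 * ctr[3] - (out$origin[3] + out$spacing[3] * (d[3] - 1))
  }
  out
}

#' World coordinates to local (continuous) voxel indices
#'
#' `(i, j, k) = (C - VO) / S`, component-wise, where `C` is the world point,
#' `VO` the volume origin and `S` the voxel spacing. Indices are 0-based and
#' continuous; rounding happens only at patch-extraction time (nearest, ties
#' toward +Inf, see [round_voxel_index()]).
#'
#' @param point Length-3 world point (mm) or an `n x 3` matrix of points.
#' @param origin Length-3 volume origin (mm), or a [voxel_volume()].
#' @param spacing Length-3 voxel spacing (mm); ignored when `origin` is a
#'   volume.
#' @return Continuous voxel indices, same shape as `point`.
#' @export
world_to_local_voxel <- function(point, origin, spacing = NULL) {
  if (inherits(origin, "voxel_volume")) {
    spacing <- origin$spacing
    origin <- origin$origin
  }
  stopifnot(length(origin) == 3L, length(spacing) == 3L)
  if (any(spacing == 0)) stop("spacing components must be non-zero")
  if (any(spacing < 0)) stop("spacing components must be > 0")
  if (is.matrix(point)) {
    stopifnot(ncol(point) == 3L)
    return(sweep(sweep(point, 2, as.numeric(origin)), 2,
                 as.numeric(spacing), "/"))
  }
  (as.numeric(point) - as.numeric(origin)) / as.numeric(spacing)
}

#' Voxel indices to world coordinates
#'
#' Inverse of [world_to_local_voxel()]: `C = VO + index * S`.
#' @param index Length-3 (continuous) 0-based voxel index or `n x 3` matrix.
#' @inheritParams world_to_local_voxel
#' @return World coordinates (mm), same shape as `index`.
#' @export
voxel_to_world <- function(index, origin, spacing = NULL) {
  if (inherits(origin, "voxel_volume")) {
    spacing <- origin$spacing
    origin <- origin$origin
  }
  if (is.matrix(index)) {
    stopifnot(ncol(index) == 3L)
    return(sweep(sweep(index, 2, as.numeric(spacing), "*"), 2,
                 as.numeric(origin), "+"))
  }
  as.numeric(origin) + as.numeric(index) * as.numeric(spacing)
}

#' Round continuous voxel indices
#'
#' Nearest integer with ties toward +Inf (`floor(x + 0.5)`).
#' @param index Numeric vector/matrix of continuous indices.
#' @return Integer-valued indices, same shape.
#' @export
round_voxel_index <- function(index) floor(index + 0.5)

#' Write a volume to NIfTI
#'
#' The affine encodes origin, spacing and frame. NIfTI world coordinates are
#' RAS+ by convention, so an LPS-tagged volume is written with negated x/y
#' axis directions, preserving physical positions.
#'
#' @param volume A [voxel_volume()].
#' @param path Output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "voxel_volume"))
  sgn <- if (volume$frame == "LPS") c(-1, -1, 1) else c(1, 1, 1)
  aff <- diag(4)
  diag(aff)[1:3] <- sgn * volume$spacing
  aff[1:3, 4] <- sgn * volume$origin
  img <- RNifti::asNifti(volume$data)
  img <- RNifti::`pixdim<-`(img, volume$spacing)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  img <- RNifti::`qform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a volume from NIfTI
#'
#' Only axis-aligned affines are supported. The frame is detected from the
#' affine's axis signs: negative x and y directions are read back as an
#' LPS-tagged volume, positive as RAS.
#'
#' @param path NIfTI file path.
#' @return A [voxel_volume()].
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- RNifti::xform(img)
  rot <- aff[1:3, 1:3]
  if (any(abs(rot[upper.tri(rot) | lower.tri(rot)]) > 1e-6))
    stop("only axis-aligned volumes are supported")
  d <- diag(rot)
  spacing <- abs(d)
  frame <- if (d[1] < 0 && d[2] < 0) "LPS" else "RAS"
  sgn <- if (frame == "LPS") c(-1, -1, 1) else c(1, 1, 1)
  origin <- sgn * aff[1:3, 4]
  voxel_volume(array(as.numeric(img), dim = dim(img)), origin, spacing, frame)
}
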