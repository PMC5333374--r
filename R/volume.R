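#' Construct a scalar volume
#'
#' A volume is a 3D scalar grid (Hounsfield units for CT) together with a 4x4
#' affine mapping 0-based voxel indices to world coordinates in mm.
#'
#' @param data 3D numeric array.
#' @param affine 4x4 voxel-to-world transform (mm); must be invertible.
#' @param units character tag recording the intensity units (default `"HU"`).
#' @return An object of class `iel_volume`.
#' @export
as_volume <- function(data, affine = diag(4), units = "HU") {
  if (length(dim(data)) != 3L) {
    abort(sprintf("expected 3D volume, got %dD", length(dim(data))))
  }
  affine <- as.matrix(affine)
  stopifnot(all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < 1e-12) abort("singular affine")
  structure(
    list(data = data, affine = unname(affine), units = units),
    class = "iel_volume"
  )
}

#' Construct a binary mask sharing a volume's grid
#'
#' @param data 3D logical (or 0/1 numeric) array.
#' @param affine 4x4 voxel-to-world transform shared with the masked volume.
#' @return An object of class `iel_mask` (also an `iel_volume`).
#' @export
as_mask <- function(data, affine = diag(4)) {
  v <- as_volume(array(as.logical(data), dim = dim(data)), affine, units = "binary")
  class(v) <- c("iel_mask", class(v))
  v
}

#' @export
print.iel_volume <- function(x, ...) {
  cat(sprintf("<%s> %s, %s\n",
              class(x)[1], paste(dim(x$data), collapse = " x "), x$units))
  invisible(x)
}

#' @export
dim.iel_volume <- function(x) dim(x$data)

#' Read a 3D NIfTI volume
#'
#' Loads a NIfTI-1/2 file without any resampling; the affine is taken from the
#' file header (sform preferred). CT and mask images are assumed pre-registered
#' on a shared grid.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param units intensity units tag to record.
#' @return An [as_volume()] object.
#' @export
load_volume <- function(path, units = "HU") {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L) abort(sprintf("expected 3D volume, got %dD: %s", length(d), path))
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  arr <- as.array(img)
  attributes(arr) <- list(dim = dim(arr))
  as_volume(arr, aff, units = units)
}

#' @rdname load_volume
#' @export
load_mask <- function(path) {
  v <- load_volume(path, units = "binary")
  as_mask(v$data != 0, v$affine)
}

#' Write a volume or mask to NIfTI
#'
#' @param v an `iel_volume` or `iel_mask`.
#' @param path output file path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
save_volume <- function(v, path) {
  dat <- v$data
  if (is.logical(dat)) dat <- array(as.integer(dat), dim = dim(dat))
  img <- RNifti::asNifti(dat)
  img <- RNifti::`sform<-`(img, structure(v$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

check_same_grid <- function(a, b) {
  if (!all(dim(a$data) == dim(b$data)) ||
      max(abs(a$affine - b$affine)) > 1e-6) {
    abort("volumes do not share a grid (shape/affine mismatch); resample upstream")
  }
  invisible(TRUE)
}

#' Convert between voxel indices and world coordinates
#'
#' Voxel indices are 0-based, world coordinates are mm (the affine's frame,
#' RAS+ assumed for reporting). `voxel_to_world` computes `affine %*% (ijk, 1)`;
#' `world_to_voxel` is its exact inverse (continuous, not rounded).
#'
#' @param v an `iel_volume`.
#' @param ijk integer triple or n x 3 matrix of 0-based voxel indices.
#' @param xyz coordinate triple or n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix (or length-3 vector for vector input).
#' @export
voxel_to_world <- function(v, ijk) {
  m <- to_mat3(ijk)
  d <- dim(v$data)
  if (any(m < 0) || any(sweep(m, 2, d, ">="))) {
    abort("voxel index out of bounds")
  }
  out <- t(v$affine %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(ijk))) out[1, ] else out
}

#' @rdname voxel_to_world
#' @export
world_to_voxel <- function(v, xyz) {
  m <- to_mat3(xyz)
  out <- t(solve(v$affine) %*% rbind(t(m), 1))[, 1:3, drop = FALSE]
  if (is.null(dim(xyz))) out[1, ] else out
}

to_mat3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    matrix(as.numeric(x), ncol = 3L)
  } else {
    stopifnot(ncol(x) == 3L)
    unname(as.matrix(x))
  }
}

# world coordinates (n x 3) of 0-based voxel indices without bounds checking
voxels_to_world_fast <- function(affine, ijk0) {
  t(affine %*% rbind(t(ijk0), 1))[, 1:3, drop = FALSE]
}
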