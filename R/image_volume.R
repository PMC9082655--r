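# 3-D scalar image volume with physical geometry (spacing/origin/direction).
# Voxel indices are 1-based (R convention); world coordinates in mm, LPS.

#' Image volume with physical geometry
#'
#' A 3-D scalar grid plus the mapping from voxel indices to world millimetres:
#' `world = origin + direction %*% (spacing * (ijk - 1))` with 1-based voxel
#' indices `ijk`. The direction matrix must be orthonormal (axis-aligned
#' identity for all phantoms generated here).
#'
#' @param array 3-D numeric array of voxel values.
#' @param spacing length-3 positive voxel size, mm (default 0.3 isotropic,
#'   the cone-beam CT resolution the planner is designed around).
#' @param origin world position of voxel (1,1,1), mm.
#' @param direction 3 x 3 orthonormal direction cosine matrix.
#' @return object of class `image_volume`.
#' @export
image_volume <- function(array, spacing = c(0.3, 0.3, 0.3),
                         origin = c(0, 0, 0), direction = diag(3)) {
  if (length(dim(array)) != 3L) stop("array must be 3-dimensional")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  direction <- as.matrix(direction)
  storage.mode(direction) <- "double"
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive values (mm/voxel)")
  if (length(origin) != 3L || any(!is.finite(origin))) stop("origin must be a finite 3-vector")
  if (!all(dim(direction) == c(3L, 3L)) ||
      max(abs(crossprod(direction) - diag(3))) > 1e-9)
    stop("direction must be a 3 x 3 orthonormal matrix")
  structure(list(array = array, spacing = spacing, origin = origin,
                 direction = direction),
            class = "image_volume")
}

#' @export
print.image_volume <- function(x, ...) {
  cat("<image_volume>", paste(dim(x$array), collapse = " x "),
      "voxels @", paste(signif(x$spacing, 4), collapse = "/"), "mm\n")
  cat("origin (mm):", paste(signif(x$origin, 6), collapse = " "), "\n")
  invisible(x)
}

#' Convert voxel indices to world coordinates
#'
#' @param vol an [image_volume()].
#' @param ijk 1-based voxel indices, length-3 vector or n x 3 matrix
#'   (fractional indices allowed for sub-voxel positions).
#' @return n x 3 matrix of world coordinates, mm.
#' @export
voxel_to_world <- function(vol, ijk) {
  stopifnot(inherits(vol, "image_volume"))
  p <- as_points3(ijk)
  sweep(p - 1, 2L, vol$spacing, "*") %*% t(vol$direction) +
    matrix(vol$origin, nrow(p), 3L, byrow = TRUE)
}

#' Convert world coordinates to (fractional, 1-based) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param xyz world coordinates, length-3 vector or n x 3 matrix, mm.
#' @export
world_to_voxel <- function(vol, xyz) {
  stopifnot(inherits(vol, "image_volume"))
  p <- as_points3(xyz)
  q <- (p - matrix(vol$origin, nrow(p), 3L, byrow = TRUE)) %*% vol$direction
  sweep(q, 2L, vol$spacing, "/") + 1
}

#' Sample a volume at world positions (nearest neighbour)
#'
#' Positions outside the grid return `outside_value`.
#'
#' @inheritParams world_to_voxel
#' @param outside_value value returned for samples outside the grid.
#' @return numeric vector of sampled intensities.
#' @export
sample_volume <- function(vol, xyz, outside_value = NA_real_) {
  idx <- round(world_to_voxel(vol, xyz))
  dm <- dim(vol$array)
  ok <- idx[, 1L] >= 1 & idx[, 1L] <= dm[1L] &
        idx[, 2L] >= 1 & idx[, 2L] <= dm[2L] &
        idx[, 3L] >= 1 & idx[, 3L] <= dm[3L]
  out <- rep(outside_value, nrow(idx))
  if (any(ok)) {
    lin <- idx[ok, 1L] + dm[1L] * (idx[ok, 2L] - 1) + dm[1L] * dm[2L] * (idx[ok, 3L] - 1)
    out[ok] <- vol$array[lin]
  }
  out
}

#' Read / write volumes as NIfTI
#'
#' Serialization uses NIfTI-1 (`.nii` / `.nii.gz`) via the RNifti package.
#' The affine stored in the sform encodes origin, spacing and direction
#' exactly as held in the [image_volume()]; world coordinates follow the
#' header affine directly.
#'
#' @param path file path ending in `.nii` or `.nii.gz`.
#' @return `read_volume` returns an [image_volume()]; `write_volume` returns
#'   `path` invisibly.
#' @export
read_volume <- function(path) {
  img <- RNifti::readNifti(path)
  aff <- structure(RNifti::xform(img), code = NULL)
  R <- aff[1:3, 1:3]
  spacing <- sqrt(colSums(R^2))
  direction <- sweep(R, 2L, spacing, "/")
  image_volume(array(as.numeric(img), dim = dim(img)),
               spacing = spacing,
               origin = aff[1:3, 4L],
               direction = direction)
}

#' @rdname read_volume
#' @param vol an [image_volume()] to write.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  aff <- diag(4)
  aff[1:3, 1:3] <- vol$direction %*% diag(vol$spacing)
  aff[1:3, 4L] <- vol$origin
  img <- RNifti::asNifti(vol$array)
  RNifti::sform(img) <- structure(aff, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}
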