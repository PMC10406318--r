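#' Define a 3-D volume grid
#'
#' A `volume_grid` fixes the sampling lattice every volumetric object in the
#' package lives on: the number of voxels per axis, the voxel size in mm, and
#' the 4x4 affine mapping 0-based voxel indices to world (MNI) millimetres.
#' All cross-volume operations require *identical* grids; nothing resamples
#' silently (see [resample_to_grid()]).
#'
#' @param shape integer vector of length 3, voxels per axis (each >= 1).
#' @param voxel_size numeric vector of length 3, mm per axis (each > 0).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world mm.
#'   Defaults to an axis-aligned affine with the grid centred on the origin.
#' @return An object of class `volume_grid`.
#' @export
volume_grid <- function(shape, voxel_size = c(2, 2, 2), affine = NULL) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  voxel_size <- as.numeric(voxel_size)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0))
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
    # centre the field of view on the world origin
    affine[1:3, 4] <- -voxel_size * (shape - 1L) / 2
  }
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 64)
    stop("grid affine is not invertible")
  structure(list(shape = shape, voxel_size = voxel_size, affine = affine),
            class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, %.3g x %.3g x %.3g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3]))
  invisible(x)
}

#' Test two grids for equality
#'
#' @param a,b `volume_grid` objects.
#' @param tol numeric tolerance on affine entries.
#' @return logical.
#' @export
grid_equal <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) &&
    max(abs(a$affine - b$affine)) <= tol &&
    max(abs(a$voxel_size - b$voxel_size)) <= tol
}

n_voxels <- function(grid) prod(grid$shape)

stop_if_grid_mismatch <- function(a, b, what = "operation") {
  if (!grid_equal(a, b))
    stop(sprintf("%s requires identical grids; resample explicitly first", what))
  invisible(TRUE)
}

#' Convert voxel indices to world coordinates
#'
#' Indices are 1-based (R array convention) on input; the affine follows the
#' NIfTI convention of mapping 0-based indices, so 1 is subtracted internally.
#'
#' @param grid a `volume_grid`.
#' @param idx n x 3 matrix of 1-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, idx) {
  idx <- matrix(as.numeric(idx), ncol = 3L)
  h <- cbind(idx - 1, 1)
  out <- h %*% t(grid$affine)
  out[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (continuous, 1-based) voxel indices
#'
#' @param grid a `volume_grid`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of continuous 1-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3L)
  h <- cbind(xyz, 1)
  out <- h %*% t(solve(grid$affine))
  out[, 1:3, drop = FALSE] + 1
}

# All voxel centres of a grid in world mm, in array (column-major) order.
grid_voxel_centers <- function(grid) {
  s <- grid$shape
  idx <- cbind(
    rep.int(seq_len(s[1]), s[2] * s[3]),
    rep.int(rep(seq_len(s[2]), each = s[1]), s[3]),
    rep(seq_len(s[3]), each = s[1] * s[2])
  )
  voxel_to_world(grid, idx)
}
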