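#' Resample a volume onto another grid
#'
#' Maps every target voxel centre through the target affine into world space,
#' then through the inverse source affine into source voxel coordinates, and
#' interpolates. Probability maps use trilinear interpolation (clipped to
#' \[0, 1\]); label volumes (parcellations, network partitions) must use
#' nearest-neighbour — interpolating labels is meaningless and is rejected.
#' Target voxels falling outside the source field of view receive 0
#' (background).
#'
#' @param source a `probability_map`, `parcellation` or `network_partition`.
#' @param target a [volume_grid()].
#' @param method `"trilinear"` or `"nearest"`.
#' @return an object of the same class as `source` on the target grid.
#' @export
resample_to_grid <- function(source, target,
                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  UseMethod("resample_to_grid")
}

#' @export
resample_to_grid.probability_map <- function(source, target,
                                             method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  vals <- if (method == "trilinear")
    interp_trilinear(source$values, source$grid, target)
  else
    interp_nearest(source$values, source$grid, target)
  vals <- pmin(pmax(vals, 0), 1)
  probability_map(target, array(vals, dim = target$shape), name = source$name)
}

#' @export
resample_to_grid.parcellation <- function(source, target,
                                          method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (method != "nearest")
    stop("label volumes must be resampled with method = 'nearest'")
  vals <- interp_nearest(source$labels, source$grid, target)
  parcellation(target, array(as.integer(vals), dim = target$shape),
               table = source$table)
}

#' @export
resample_to_grid.network_partition <- function(source, target,
                                               method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  if (method != "nearest")
    stop("label volumes must be resampled with method = 'nearest'")
  vals <- interp_nearest(source$labels, source$grid, target)
  network_partition(target, array(as.integer(vals), dim = target$shape),
                    networks = source$networks)
}

# continuous source-voxel coordinates (1-based) of all target voxel centres
source_coords_of_target <- function(src_grid, target) {
  world <- grid_voxel_centers(target)
  world_to_voxel(src_grid, world)
}

interp_nearest <- function(values, src_grid, target) {
  co <- round(source_coords_of_target(src_grid, target))
  s <- src_grid$shape
  inside <- co[, 1] >= 1 & co[, 1] <= s[1] &
    co[, 2] >= 1 & co[, 2] <= s[2] &
    co[, 3] >= 1 & co[, 3] <= s[3]
  out <- numeric(nrow(co))
  if (any(inside)) {
    lin <- co[inside, 1] + (co[inside, 2] - 1) * s[1] +
      (co[inside, 3] - 1) * s[1] * s[2]
    out[inside] <- values[lin]
  }
  out
}

interp_trilinear <- function(values, src_grid, target) {
  co <- source_coords_of_target(src_grid, target)
  s <- src_grid$shape
  f <- floor(co)
  w <- co - f
  out <- numeric(nrow(co))
  # accumulate the 8 corner contributions; out-of-bounds corners contribute 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    cx <- f[, 1] + dx; cy <- f[, 2] + dy; cz <- f[, 3] + dz
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
      (if (dy) w[, 2] else 1 - w[, 2]) *
      (if (dz) w[, 3] else 1 - w[, 3])
    ok <- wt > 0 & cx >= 1 & cx <= s[1] & cy >= 1 & cy <= s[2] &
      cz >= 1 & cz <= s[3]
    if (any(ok)) {
      lin <- cx[ok] + (cy[ok] - 1) * s[1] + (cz[ok] - 1) * s[1] * s[2]
      out[ok] <- out[ok] + wt[ok] * values[lin]
    }
  }
  out
}
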