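#' Probability map on a volume grid
#'
#' Per-voxel probabilities in \[0, 1\], e.g. a probabilistic
#' (cytoarchitectonic) seed map.
#'
#' @param grid a [volume_grid()].
#' @param values numeric array (or vector) conforming to `grid$shape`,
#'   all values in \[0, 1\].
#' @param name optional identifier.
#' @return An object of class `probability_map`.
#' @export
probability_map <- function(grid, values, name = NULL) {
  values <- as_grid_array(values, grid)
  rng <- range(values)
  if (is.na(rng[1]) || rng[1] < 0 || rng[2] > 1)
    stop("probability values must be finite and in [0, 1]")
  structure(list(grid = grid, values = values, name = name),
            class = "probability_map")
}

#' Boolean region mask on a volume grid
#'
#' @param grid a [volume_grid()].
#' @param members logical array (or vector) conforming to `grid$shape`.
#' @param name identifier for the region.
#' @return An object of class `region_mask`.
#' @export
region_mask <- function(grid, members, name = "mask") {
  members <- as_grid_array(members, grid)
  storage.mode(members) <- "logical"
  if (anyNA(members)) stop("mask membership must not contain NA")
  structure(list(grid = grid, members = members, name = name),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat(sprintf("<region_mask> '%s': %d voxels\n", x$name, mask_size(x)))
  invisible(x)
}

#' Number of member voxels in a mask
#' @param mask a `region_mask`.
#' @return integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$members)

#' Integer-labelled parcellation on a volume grid
#'
#' Label 0 is background. `table` describes every label that can occur:
#' columns `label`, `name`, `hemisphere` (`"L"`/`"R"`), `group`.
#'
#' @param grid a [volume_grid()].
#' @param labels integer array conforming to `grid$shape`, values >= 0.
#' @param table data.frame with columns label, name, hemisphere, group.
#' @return An object of class `parcellation`.
#' @export
parcellation <- function(grid, labels, table) {
  labels <- as_grid_array(labels, grid)
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || any(labels < 0L)) stop("labels must be non-negative integers")
  stopifnot(is.data.frame(table),
            all(c("label", "name", "hemisphere", "group") %in% names(table)))
  table$label <- as.integer(table$label)
  present <- setdiff(sort(unique(as.vector(labels))), 0L)
  missing <- setdiff(present, table$label)
  if (length(missing))
    stop("labels present in volume but absent from table: ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(table$label)) stop("duplicate labels in parcellation table")
  structure(list(grid = grid, labels = labels, table = table),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  cat(sprintf("<parcellation> %d parcels, %d labelled voxels\n",
              nrow(x$table), sum(x$labels > 0L)))
  invisible(x)
}

#' Extract one parcel (or a union of parcels) as a region mask
#'
#' @param parc a `parcellation`.
#' @param labels integer label(s); all must exist in the parcellation table.
#' @param name mask name; defaults to the parcel name(s).
#' @return a `region_mask`.
#' @export
parcel_mask <- function(parc, labels, name = NULL) {
  labels <- as.integer(labels)
  unknown <- setdiff(labels, parc$table$label)
  if (length(unknown))
    stop("unknown parcel label(s): ", paste(unknown, collapse = ", "))
  if (is.null(name)) {
    nm <- parc$table$name[match(labels, parc$table$label)]
    name <- paste(nm, collapse = "+")
  }
  region_mask(parc$grid, array(parc$labels %in% labels, dim = parc$grid$shape),
              name = name)
}

#' Intrinsic-network partition on a volume grid
#'
#' Voxel labels in `0..K` where 0 means unassigned and `1..K` index the named
#' networks (canonically the seven intrinsic connectivity networks).
#'
#' @param grid a [volume_grid()].
#' @param labels integer array conforming to `grid$shape`, values in 0..K.
#' @param networks character vector of K unique network names.
#' @return An object of class `network_partition`.
#' @export
network_partition <- function(grid, labels, networks) {
  labels <- as_grid_array(labels, grid)
  storage.mode(labels) <- "integer"
  networks <- as.character(networks)
  if (anyDuplicated(networks)) stop("network names must be unique")
  if (anyNA(labels) || any(labels < 0L) || any(labels > length(networks)))
    stop("network labels must lie in 0..K")
  structure(list(grid = grid, labels = labels, networks = networks),
            class = "network_partition")
}

as_grid_array <- function(values, grid) {
  if (is.null(dim(values))) {
    if (length(values) != n_voxels(grid))
      stop("values length does not match grid")
    dim(values) <- grid$shape
  } else if (!identical(as.integer(dim(values)), grid$shape)) {
    stop("values dimensions do not match grid shape")
  }
  values
}

#' Threshold a probability map into a region mask
#'
#' Retains voxels with probability *strictly* greater than `tau` (a
#' probability of ">25%" reads as `value > 0.25`).
#'
#' @param pmap a `probability_map`.
#' @param tau threshold in \[0, 1); default 0.25.
#' @param name mask name; defaults to the map's name.
#' @return a `region_mask` (possibly empty).
#' @export
threshold_probability <- function(pmap, tau = 0.25, name = NULL) {
  stopifnot(inherits(pmap, "probability_map"), tau >= 0, tau < 1)
  if (is.null(name)) name <- if (is.null(pmap$name)) "thresholded" else pmap$name
  region_mask(pmap$grid, pmap$values > tau, name = name)
}

#' Fraction of a parcel covered by a mask
#'
#' Returns `|parcel voxels inside cover| / |parcel voxels|` — the coverage is
#' a property of the *parcel* (the direction used when retaining functionally
#' coupled regions with at least 80% overlap).
#'
#' @param cover a `region_mask`.
#' @param parc a `parcellation` on the same grid.
#' @param label a single parcel label with at least one voxel.
#' @return fraction in \[0, 1\].
#' @export
overlap_fraction <- function(cover, parc, label) {
  stop_if_grid_mismatch(cover$grid, parc$grid, "overlap_fraction")
  label <- as.integer(label)
  in_parcel <- parc$labels == label
  n <- sum(in_parcel)
  if (n == 0L) stop(sprintf("parcel %d is empty", label))
  sum(cover$members[in_parcel]) / n
}

#' Mask set algebra
#'
#' Standard set semantics on voxel membership; both masks must share a grid.
#'
#' @param a,b `region_mask` objects on the same grid.
#' @param name output mask name.
#' @return a `region_mask` (`mask_union`, `mask_intersect`) or logical
#'   (`any_overlap`).
#' @export
mask_union <- function(a, b, name = paste0(a$name, "|", b$name)) {
  stop_if_grid_mismatch(a$grid, b$grid, "mask_union")
  region_mask(a$grid, a$members | b$members, name = name)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b, name = paste0(a$name, "&", b$name)) {
  stop_if_grid_mismatch(a$grid, b$grid, "mask_intersect")
  region_mask(a$grid, a$members & b$members, name = name)
}

#' @rdname mask_union
#' @export
any_overlap <- function(a, b) {
  stop_if_grid_mismatch(a$grid, b$grid, "any_overlap")
  any(a$members & b$members)
}

# 1-based voxel index triples (n x 3) of a mask's member voxels.
mask_voxel_indices <- function(mask) {
  which(mask$members, arr.ind = TRUE)
}

# world-mm centres of a mask's member voxels
mask_voxel_centers <- function(mask) {
  voxel_to_world(mask$grid, mask_voxel_indices(mask))
}
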