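#' Rasterize topic surface maps to voxel masks
#'
#' Converts each (seed, topic) parcel set of a topic surface map into the
#' union of the parcels' voxels.
#'
#' @param topic_map a `topic_surface_map` (see [group_into_topics()]).
#' @param parc the `parcellation` whose labels the map references.
#' @return data.frame with columns seed, topic_id and a list-column `mask`
#'   of `region_mask` objects.
#' @export
rasterize_topic_map <- function(topic_map, parc) {
  r <- topic_map$regions
  keys <- unique(r[, c("seed", "topic_id")])
  masks <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    labs <- r$label[r$seed == keys$seed[i] & r$topic_id == keys$topic_id[i]]
    masks[[i]] <- parcel_mask(parc, labs,
                              name = sprintf("%s:topic%d", keys$seed[i],
                                             keys$topic_id[i]))
  }
  keys$mask <- masks
  rownames(keys) <- NULL
  keys
}

#' Directional percentage overlap of a mask with a network partition
#'
#' For every network k (plus the label-0 "unassigned" pseudo-network):
#' `pct_topic_in_network = 100 * |mask n net_k| / |mask|` and
#' `pct_network_in_topic = 100 * |mask n net_k| / |net_k|`. The first
#' direction sums to 100 across networks + unassigned. Empty networks get
#' a vice-versa percentage of 0 and `empty_network = TRUE`.
#'
#' @param mask a nonempty `region_mask`.
#' @param nets a `network_partition` on the same grid.
#' @return data.frame with columns network_label, network,
#'   pct_topic_in_network, pct_network_in_topic, empty_network.
#' @export
overlap_percentages <- function(mask, nets) {
  stop_if_grid_mismatch(mask$grid, nets$grid, "overlap_percentages")
  msize <- mask_size(mask)
  if (msize == 0L) stop("mask is empty")
  K <- length(nets$networks)
  lab <- as.vector(nets$labels)
  inter <- tabulate(lab[as.vector(mask$members)] + 1L, nbins = K + 1L)
  nsize <- tabulate(lab + 1L, nbins = K + 1L)
  data.frame(
    network_label = 0:K,
    network = c("unassigned", nets$networks),
    pct_topic_in_network = 100 * inter / msize,
    pct_network_in_topic = ifelse(nsize > 0, 100 * inter / nsize, 0),
    empty_network = nsize == 0,
    stringsAsFactors = FALSE
  )
}

#' Overlap table between all topic surface maps and a network partition
#'
#' @param topic_map a `topic_surface_map`.
#' @param parc the `parcellation` used to rasterize the maps.
#' @param nets a `network_partition` on the parcellation's grid.
#' @return data.frame with columns seed, topic_id, network_label, network,
#'   pct_topic_in_network, pct_network_in_topic, empty_network.
#' @export
network_overlap_table <- function(topic_map, parc, nets) {
  rast <- rasterize_topic_map(topic_map, parc)
  out <- vector("list", nrow(rast))
  for (i in seq_len(nrow(rast))) {
    tab <- overlap_percentages(rast$mask[[i]], nets)
    tab <- cbind(seed = rast$seed[i], topic_id = rast$topic_id[i], tab)
    out[[i]] <- tab
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seed = character(0), topic_id = integer(0),
               network_label = integer(0), network = character(0),
               pct_topic_in_network = numeric(0),
               pct_network_in_topic = numeric(0),
               empty_network = logical(0))
  rownames(res) <- NULL
  res
}
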