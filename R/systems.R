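#' Joint activation of a seed-cortical pair
#'
#' Mode `"both"` (the default co-activation reading): a study is active iff
#' it activates the seed AND the parcel, each per [activation_vector()].
#' Mode `"union"`: active iff it activates the union mask of the two
#' regions. The two masks must be disjoint.
#'
#' @param db a `coordinate_db`.
#' @param seed,parcel nonempty, disjoint `region_mask` objects.
#' @param radius_mm activation radius in mm.
#' @param mode `"both"` (default) or `"union"`.
#' @return an `activation_vector`.
#' @export
pair_activation <- function(db, seed, parcel, radius_mm = 6,
                            mode = c("both", "union")) {
  mode <- match.arg(mode)
  if (mask_size(seed) == 0L || mask_size(parcel) == 0L)
    stop("pair masks must be nonempty")
  if (any_overlap(seed, parcel))
    stop("seed and parcel masks overlap; pairs must be disjoint")
  nm <- paste0(seed$name, "+", parcel$name)
  if (mode == "both") {
    a <- activation_vector(db, seed, radius_mm)
    b <- activation_vector(db, parcel, radius_mm)
    structure(list(active = a$active & b$active, roi_name = nm,
                   radius_mm = radius_mm), class = "activation_vector")
  } else {
    activation_vector(db, mask_union(seed, parcel, name = nm), radius_mm)
  }
}

#' Decode a seed-cortical pair
#'
#' Applies the decoder twice: once to the joint seed-parcel activation and
#' once to the parcel alone. The two selected term lists are compared with a
#' set difference (terms specific to the pair) and a conjunction (terms
#' shared with the region's own decoding).
#'
#' @inheritParams pair_activation
#' @param prior,f_min,alpha,k,allowlist,order passed to
#'   [decode_activation()] and [select_terms()].
#' @return An object of class `pair_decoding` with `seed_name`,
#'   `parcel_name`, `terms_pair`, `terms_region`, `terms_specific`,
#'   `terms_shared`.
#' @export
decode_pair <- function(db, seed, parcel, radius_mm = 6,
                        mode = c("both", "union"), prior = 0.5,
                        f_min = 0.001, alpha = 0.05, k = 30,
                        allowlist = NULL,
                        order = c("rank_then_filter", "filter_then_rank")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  act_pair <- pair_activation(db, seed, parcel, radius_mm, mode)
  res_pair <- decode_activation(db, act_pair, prior, f_min, alpha)
  res_region <- decode_roi(db, parcel, radius_mm, prior, f_min, alpha)
  terms_pair <- select_terms(res_pair, k = k, allowlist = allowlist,
                             order = order)
  terms_region <- select_terms(res_region, k = k, allowlist = allowlist,
                               order = order)
  structure(list(
    seed_name = seed$name, parcel_name = parcel$name,
    terms_pair = terms_pair, terms_region = terms_region,
    terms_specific = setdiff(terms_pair, terms_region),
    terms_shared = intersect(terms_pair, terms_region)
  ), class = "pair_decoding")
}

#' @export
print.pair_decoding <- function(x, ...) {
  cat(sprintf("<pair_decoding> %s x %s: %d pair terms (%d specific, %d shared)\n",
              x$seed_name, x$parcel_name, length(x$terms_pair),
              length(x$terms_specific), length(x$terms_shared)))
  invisible(x)
}

#' Systems-level decoding across all seed-cortical pairs
#'
#' Iterates [decode_pair()] over every (seed, connected parcel) pair and
#' collects the pair-specific terms into a system map:
#' `(seed, term) -> set of parcel labels` for which the term was specific.
#'
#' @param db a `coordinate_db`.
#' @param seeds named list of seed `region_mask` objects.
#' @param connected a `connected_regions` table (or data.frame with columns
#'   `seed`, `label`) restricted to the given seeds.
#' @param parc the `parcellation` supplying parcel masks.
#' @inheritParams decode_pair
#' @return An object of class `system_map`: list with `entries` (long
#'   data.frame seed, term, label, status in {specific, shared}) and
#'   `pairs` (the individual `pair_decoding` objects).
#' @export
systems_decode <- function(db, seeds, connected, parc, radius_mm = 6,
                           mode = c("both", "union"), prior = 0.5,
                           f_min = 0.001, alpha = 0.05, k = 30,
                           allowlist = NULL,
                           order = c("rank_then_filter", "filter_then_rank")) {
  mode <- match.arg(mode)
  order <- match.arg(order)
  stopifnot(!is.null(names(seeds)))
  pairs <- list()
  rows <- list()
  for (sname in sort(names(seeds))) {
    labs <- sort(connected$label[connected$seed == sname])
    for (lab in labs) {
      pd <- decode_pair(db, seeds[[sname]], parcel_mask(parc, lab),
                        radius_mm = radius_mm, mode = mode, prior = prior,
                        f_min = f_min, alpha = alpha, k = k,
                        allowlist = allowlist, order = order)
      pairs[[paste(sname, lab, sep = ":")]] <- pd
      if (length(pd$terms_pair))
        rows[[length(rows) + 1L]] <- data.frame(
          seed = sname, term = pd$terms_pair, label = lab,
          status = ifelse(pd$terms_pair %in% pd$terms_specific,
                          "specific", "shared"),
          stringsAsFactors = FALSE)
    }
  }
  entries <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seed = character(0), term = character(0),
               label = integer(0), status = character(0))
  entries <- entries[order(entries$seed, entries$term, entries$label), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  structure(list(entries = entries, pairs = pairs), class = "system_map")
}

#' @export
print.system_map <- function(x, ...) {
  sp <- x$entries[x$entries$status == "specific", , drop = FALSE]
  cat(sprintf("<system_map> %d pairs decoded; %d specific (seed, term, region) entries over %d (seed, term) systems\n",
              length(x$pairs), nrow(sp),
              nrow(unique(sp[, c("seed", "term")]))))
  invisible(x)
}

#' Specific entries of a system map
#'
#' @param system a `system_map`.
#' @return data.frame with columns seed, term, label (specific status only).
#' @export
system_entries <- function(system) {
  system$entries[system$entries$status == "specific",
                 c("seed", "term", "label"), drop = FALSE]
}

#' Hard term-to-topic mapping
#'
#' @param topic_of named integer vector: term -> topic id.
#' @param topic_names named character vector: topic id -> name (names are
#'   the ids as character).
#' @return An object of class `topic_mapping`.
#' @export
topic_mapping <- function(topic_of, topic_names = NULL) {
  stopifnot(!is.null(names(topic_of)))
  if (anyDuplicated(names(topic_of)))
    stop("a term may map to exactly one topic")
  ids <- sort(unique(as.integer(topic_of)))
  if (is.null(topic_names))
    topic_names <- stats::setNames(paste0("topic", ids), ids)
  structure(list(topic_of = topic_of, topic_names = topic_names,
                 n_topics = length(unique(topic_of))),
            class = "topic_mapping")
}

#' Aggregate a system map into topic surface maps
#'
#' For every (seed, topic): the union over the topic's mapped terms of the
#' system map's region sets, plus the contributing term list. Terms present
#' in the system map but absent from the mapping are reported via the
#' `unmapped` element (never dropped silently).
#'
#' @param system a `system_map` (or its specific-entry data.frame).
#' @param mapping a `topic_mapping`.
#' @return An object of class `topic_surface_map`: list with `regions`
#'   (data.frame seed, topic_id, topic_name, label), `terms` (data.frame
#'   seed, topic_id, term) and `unmapped` (character vector).
#' @export
group_into_topics <- function(system, mapping) {
  sp <- if (inherits(system, "system_map")) system_entries(system) else system
  unmapped <- sort(setdiff(unique(sp$term), names(mapping$topic_of)))
  if (length(unmapped) && nrow(sp) > 0 &&
      length(unmapped) == length(unique(sp$term)))
    stop("topic mapping covers no term present in the system map")
  if (length(unmapped))
    message("terms without topic assignment: ",
            paste(unmapped, collapse = ", "))
  mapped <- sp[sp$term %in% names(mapping$topic_of), , drop = FALSE]
  mapped$topic_id <- as.integer(mapping$topic_of[mapped$term])
  regions <- unique(mapped[, c("seed", "topic_id", "label")])
  regions$topic_name <- unname(mapping$topic_names[as.character(regions$topic_id)])
  regions <- regions[order(regions$seed, regions$topic_id, regions$label),
                     c("seed", "topic_id", "topic_name", "label")]
  terms <- unique(mapped[, c("seed", "topic_id", "term")])
  terms <- terms[order(terms$seed, terms$topic_id, terms$term), , drop = FALSE]
  rownames(regions) <- rownames(terms) <- NULL
  structure(list(regions = regions, terms = terms, unmapped = unmapped),
            class = "topic_surface_map")
}

#' Per-seed region counts of a topic surface map
#'
#' Counts, per (topic, seed, hemisphere), the number of system regions, and
#' per (topic, region) the number of seeds whose system includes the region
#' (the seed multiplicity used for colour grading).
#'
#' @param topic_map a `topic_surface_map`.
#' @param parc the `parcellation` carrying hemisphere tags.
#' @return list with `counts` (topic_id, seed, hemisphere, n_regions) and
#'   `multiplicity` (topic_id, label, n_seeds).
#' @export
seed_contribution <- function(topic_map, parc) {
  r <- topic_map$regions
  if (nrow(r) == 0L)
    return(list(counts = data.frame(topic_id = integer(0), seed = character(0),
                                    hemisphere = character(0),
                                    n_regions = integer(0)),
                multiplicity = data.frame(topic_id = integer(0),
                                          label = integer(0),
                                          n_seeds = integer(0))))
  r$hemisphere <- parc$table$hemisphere[match(r$label, parc$table$label)]
  counts <- stats::aggregate(list(n_regions = r$label),
                             by = r[, c("topic_id", "seed", "hemisphere")],
                             FUN = length)
  counts <- counts[order(counts$topic_id, counts$seed, counts$hemisphere), ]
  mult <- stats::aggregate(list(n_seeds = r$seed),
                           by = r[, c("topic_id", "label")],
                           FUN = function(s) length(unique(s)))
  mult <- mult[order(mult$topic_id, mult$label), ]
  rownames(counts) <- rownames(mult) <- NULL
  list(counts = counts, multiplicity = mult)
}
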