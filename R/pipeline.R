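#' Pipeline configuration
#'
#' Collects every tunable of the systems-decoding pipeline with its
#' default: the printed method constants (seed probability threshold 0.25,
#' voxel-level FWE 0.05, minimum parcel overlap 0.8, prior 0.5, top-30 term
#' selection, FDR 0.05) plus the package's own defaults (term binarization
#' 0.001, 6 mm activation radius, co-activation pair mode, Bonferroni FWE).
#'
#' @param ... named overrides of any default.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed_threshold = 0.25,
    fwe_alpha = 0.05,
    fwe_method = "bonferroni",
    n_perm = 1000L,
    min_overlap = 0.8,
    prior = 0.5,
    f_min = 0.001,
    radius_mm = 6,
    k = 30L,
    selection_order = "rank_then_filter",
    pair_mode = "both",
    fdr_alpha = 0.05,
    seed = 1L,
    n_subjects = 20L,
    n_timepoints = 400L,
    tr = 0.8,
    effect_r = 0.5,
    noise_sd = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  validate_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$seed_threshold >= 0, cfg$seed_threshold < 1,
    cfg$fwe_alpha > 0, cfg$fwe_alpha < 1,
    cfg$fwe_method %in% c("bonferroni", "permutation"),
    cfg$min_overlap >= 0, cfg$min_overlap <= 1,
    cfg$prior >= 0, cfg$prior <= 1,
    cfg$f_min >= 0, cfg$f_min <= 1,
    cfg$radius_mm >= 0,
    cfg$k >= 1,
    cfg$selection_order %in% c("rank_then_filter", "filter_then_rank"),
    cfg$pair_mode %in% c("both", "union"),
    cfg$fdr_alpha > 0, cfg$fdr_alpha < 1,
    cfg$n_subjects >= 2, cfg$n_timepoints >= 2, cfg$tr > 0,
    cfg$effect_r > 0, cfg$effect_r < 1
  )
  invisible(cfg)
}

#' Run the full systems-decoding pipeline
#'
#' Executes the stages in order: seed definition (resample + threshold),
#' seed-based RSFC with a random-effects group map and voxel-level FWE
#' thresholding, connected-region selection, per-seed decoding,
#' systems-level pair decoding, topic aggregation, and network overlap.
#' When `data` is `NULL` a default [synthetic_dataset()] is generated from
#' `config$seed` and BOLD volumes are streamed one subject at a time.
#'
#' @param config a [pipeline_config()].
#' @param data a dataset list as returned by [synthetic_dataset()]; `NULL`
#'   generates one.
#' @param output_dir optional directory; when given, every product is
#'   written there (NIfTI volumes, TSV tables, provenance JSON).
#' @param bold optional list of `bold4d` to use instead of streaming
#'   simulated subjects.
#' @return list with `seeds`, `group_maps`, `suprathreshold`, `connected`,
#'   `seed_decodings`, `seed_terms`, `system`, `topic_map`, `overlap`,
#'   `recovery` (when the data carry planted truth) and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL,
                         output_dir = NULL, bold = NULL) {
  validate_config(config)
  if (is.null(data)) data <- synthetic_dataset(seed = config$seed)
  grid <- data$parc$grid

  # stage 1: seed definition — resample onto the analysis grid, threshold
  seed_maps <- lapply(data$seed_maps, resample_to_grid, target = grid,
                      method = "trilinear")
  seeds <- lapply(seed_maps, threshold_probability,
                  tau = config$seed_threshold)
  for (s in names(seeds)) {
    seeds[[s]]$name <- s
    if (mask_size(seeds[[s]]) == 0L)
      stop(sprintf("[seed-definition] seed '%s' empty at threshold %g",
                   s, config$seed_threshold))
  }

  # stage 2: RSFC — subject maps (streamed), group map, FWE threshold
  brain <- region_mask(grid, array(TRUE, dim = grid$shape), name = "brain")
  subj_maps <- stats::setNames(
    lapply(seeds, function(.) vector("list", config$n_subjects)),
    names(seeds))
  for (i in seq_len(config$n_subjects)) {
    b <- if (!is.null(bold)) bold[[i]] else
      simulate_bold(grid, seeds, data$truth, data$parc,
                    n_subjects = config$n_subjects,
                    n_timepoints = config$n_timepoints, tr = config$tr,
                    effect_r = config$effect_r, noise_sd = config$noise_sd,
                    seed = config$seed, subjects = i)[[1]]
    for (s in names(seeds)) {
      ts <- seed_timeseries(b, seeds[[s]])
      subj_maps[[s]][[i]] <- seed_connectivity(b, ts, brain)
    }
  }
  group_maps <- lapply(subj_maps, group_map)
  supra <- stats::setNames(lapply(names(seeds), function(s)
    fwe_threshold(group_maps[[s]], alpha = config$fwe_alpha,
                  method = config$fwe_method, maps = subj_maps[[s]],
                  n_perm = config$n_perm, seed = config$seed)),
    names(seeds))

  # stage 3: connected regions with seed-overlap exclusion
  connected <- do.call(rbind, lapply(names(seeds), function(s)
    connected_regions(supra[[s]], data$parc, seeds,
                      min_overlap = config$min_overlap, seed_name = s)))

  # stage 4: per-seed decoding
  seed_decodings <- lapply(seeds, function(s)
    decode_roi(data$db, s, radius_mm = config$radius_mm,
               prior = config$prior, f_min = config$f_min,
               alpha = config$fdr_alpha))
  seed_terms <- lapply(seed_decodings, select_terms, k = config$k,
                       allowlist = data$allowlist,
                       order = config$selection_order)

  # stage 5: systems-level decoding
  system <- systems_decode(data$db, seeds, connected, data$parc,
                           radius_mm = config$radius_mm,
                           mode = config$pair_mode, prior = config$prior,
                           f_min = config$f_min, alpha = config$fdr_alpha,
                           k = config$k, allowlist = data$allowlist,
                           order = config$selection_order)

  # stage 6: topic aggregation; stage 7: network overlap
  topic_map <- group_into_topics(system, data$topics)
  overlap <- network_overlap_table(topic_map, data$parc, data$networks)

  recovery <- if (!is.null(data$truth))
    system_recovery(system, data$truth) else NULL

  result <- list(seeds = seeds, group_maps = group_maps,
                 suprathreshold = supra, connected = connected,
                 seed_decodings = seed_decodings, seed_terms = seed_terms,
                 system = system, topic_map = topic_map, overlap = overlap,
                 recovery = recovery, config = config)
  if (!is.null(output_dir)) write_pipeline_outputs(result, data, output_dir)
  result
}

#' Compare a system map against planted ground truth
#'
#' Planted (seed, term) associations are the `pair` and `seed` type rows of
#' the truth. Recovery is the fraction of planted (seed, term) pairs present
#' in the system map's specific entries; the spurious rate is the fraction
#' of emitted (seed, term) entries that were not planted. Pair-term purity
#' checks that pair-only terms appear in `terms_specific` and never in
#' `terms_region` of their planted pair.
#'
#' @param system a `system_map`.
#' @param truth a [synthetic_truth()].
#' @return list with `recovered_fraction`, `spurious_fraction`, counts, and
#'   `pair_purity` (fraction of planted pair couplings whose term is
#'   specific and absent from the region-alone list).
#' @export
system_recovery <- function(system, truth) {
  sp <- system_entries(system)
  emitted <- unique(sp[, c("seed", "term")])
  assoc <- truth$associations
  planted <- unique(assoc[assoc$type %in% c("pair", "seed"),
                          c("seed", "term")])
  key <- function(df) paste(df$seed, df$term, sep = "\r")
  recovered <- mean(key(planted) %in% key(emitted))
  spurious <- if (nrow(emitted)) mean(!(key(emitted) %in% key(planted)))
    else 0
  pair_rows <- assoc[assoc$type == "pair", , drop = FALSE]
  purity <- vapply(seq_len(nrow(pair_rows)), function(i) {
    pd <- system$pairs[[paste(pair_rows$seed[i], pair_rows$label[i],
                              sep = ":")]]
    if (is.null(pd)) return(NA)
    (pair_rows$term[i] %in% pd$terms_specific) &&
      !(pair_rows$term[i] %in% pd$terms_region)
  }, logical(1))
  list(recovered_fraction = recovered,
       spurious_fraction = spurious,
       n_planted = nrow(planted), n_emitted = nrow(emitted),
       n_spurious = sum(!(key(emitted) %in% key(planted))),
       pair_purity = mean(purity, na.rm = TRUE))
}

write_pipeline_outputs <- function(result, data, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(output_dir, ...)
  for (s in names(result$seeds)) {
    write_region_mask(result$seeds[[s]], p(sprintf("seed_%s_mask.nii.gz", s)))
    gm <- result$group_maps[[s]]
    img <- RNifti::asNifti(array(gm$tstat, dim = gm$grid$shape),
                           datatype = "double")
    img <- RNifti::`sform<-`(img, structure(gm$grid$affine, code = 2L))
    RNifti::writeNifti(img, p(sprintf("group_t_%s.nii.gz", s)))
    write_region_mask(result$suprathreshold[[s]],
                      p(sprintf("suprathreshold_%s.nii.gz", s)))
    write_decoding_result(result$seed_decodings[[s]],
                          p(sprintf("decoding_%s.tsv", s)))
  }
  write_tsv(result$connected, p("connected_regions.tsv"))
  write_tsv(result$system$entries, p("system_map.tsv"))
  write_tsv(result$topic_map$regions, p("topic_regions.tsv"))
  write_tsv(result$topic_map$terms, p("topic_terms.tsv"))
  ov <- result$overlap
  ov$pct_topic_in_network <- sprintf("%.6f", ov$pct_topic_in_network)
  ov$pct_network_in_topic <- sprintf("%.6f", ov$pct_network_in_topic)
  write_tsv(ov, p("network_overlap.tsv"))
  prov <- list(package = "sysdecode",
               version = as.character(utils::packageVersion("sysdecode")),
               config = unclass(result$config))
  if (!is.null(result$recovery)) prov$recovery <- result$recovery
  jsonlite::write_json(prov, p("provenance.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(data$truth)) write_truth(data$truth, p("truth.json"))
  invisible(output_dir)
}
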