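#' Toy cortical atlas with an intrinsic-network partition
#'
#' Tiles the grid interior (a 1-voxel background margin is kept) with
#' contiguous rectangular-block parcels and assigns every parcel to one of
#' `n_networks` named networks. Hemispheres are split at the midline x
#' index; the block grid uses an even number of x-blocks so no parcel
#' straddles the midline.
#'
#' @param grid_shape voxels per axis (default 24^3).
#' @param n_parcels number of parcels; must factorize into a feasible
#'   block grid.
#' @param seed RNG seed (network assignment).
#' @param n_networks number of networks (default 7).
#' @param voxel_size mm per axis.
#' @return list with elements `parc` (a [parcellation()]) and `networks`
#'   (a [network_partition()]).
#' @export
make_atlas <- function(grid_shape = c(24, 24, 24), n_parcels = 40,
                       seed = 1, n_networks = 7, voxel_size = c(2, 2, 2)) {
  grid <- volume_grid(grid_shape, voxel_size = voxel_size)
  inner <- grid_shape - 2L  # 1-voxel background margin per side
  fac <- block_factorization(n_parcels, inner)
  cuts <- lapply(1:3, function(ax) {
    k <- fac[ax]
    sizes <- diff(round(seq(0, inner[ax], length.out = k + 1)))
    if (any(sizes < 1)) stop("n_parcels infeasible for this grid")
    bounds <- cumsum(c(1L, sizes)) + 1L  # 1-based start indices, margin offset
    cbind(lo = utils::head(bounds, -1), hi = utils::tail(bounds, -1) - 1L)
  })
  labels <- array(0L, dim = grid_shape)
  tab <- vector("list", n_parcels)
  lab <- 0L
  for (bz in seq_len(fac[3])) for (by in seq_len(fac[2]))
    for (bx in seq_len(fac[1])) {
      lab <- lab + 1L
      xr <- cuts[[1]][bx, ]; yr <- cuts[[2]][by, ]; zr <- cuts[[3]][bz, ]
      labels[xr[1]:xr[2], yr[1]:yr[2], zr[1]:zr[2]] <- lab
      hemi <- if (mean(xr) <= (grid_shape[1] + 1) / 2) "L" else "R"
      tab[[lab]] <- data.frame(label = lab,
                               name = sprintf("P%03d", lab),
                               hemisphere = hemi, group = "block",
                               stringsAsFactors = FALSE)
    }
  table <- do.call(rbind, tab)
  net_names <- c("visual", "somatomotor", "dorsal_attention",
                 "ventral_attention", "limbic", "frontoparietal",
                 "default")[seq_len(n_networks)]
  if (n_networks > 7)
    net_names <- c(net_names, paste0("network", 8:n_networks))
  with_local_seed(seed, {
    net_of <- sample(rep_len(seq_len(n_networks), n_parcels))
  })
  net_labels <- array(0L, dim = grid_shape)
  nz <- labels > 0L
  net_labels[nz] <- net_of[labels[nz]]
  list(parc = parcellation(grid, labels, table),
       networks = network_partition(grid, net_labels, net_names))
}

block_factorization <- function(n, inner) {
  best <- NULL; best_score <- Inf
  for (nx in 1:n) if (n %% nx == 0) for (ny in 1:(n / nx))
    if ((n / nx) %% ny == 0) {
      nz <- n / nx / ny
      if (nx > inner[1] || ny > inner[2] || nz > inner[3]) next
      # prefer even x (hemisphere split) and several x/z levels (the
      # separation geometry the planted couplings need), balance overall
      score <- stats::var(c(nx, ny, nz)) + (nx %% 2 == 1) * 100 +
        (nx < 4) * 50 + (nz < 4) * 50
      if (score < best_score) { best_score <- score; best <- c(nx, ny, nz) }
    }
  if (is.null(best)) stop("n_parcels infeasible for this grid")
  as.integer(best)
}

with_local_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Probabilistic seed maps with disjoint suprathreshold cores
#'
#' Each seed is a Gaussian probability bump (peak 0.9, spatial sd
#' `sigma_mm`) around a centre; centres are chosen by a seeded maximin
#' search so the `> 0.25` cores are mutually disjoint and separated by at
#' least `min_separation_mm`. Mimicking neighbouring subdivisions of one
#' sulcus, the centres are clustered in one slab of the volume (the lower
#' third of the y axis), which leaves the rest of the volume free for
#' distant cortical partners.
#'
#' @param grid a [volume_grid()].
#' @param k_seeds number of seeds (default 3).
#' @param seed RNG seed.
#' @param sigma_mm spatial sd of the bump in mm (default 5).
#' @param peak peak probability (default 0.9).
#' @param min_separation_mm minimum centre separation (default 24).
#' @param inner_margin voxels kept free at the grid border for centres.
#' @return named list of `probability_map` objects (`seed1`, `seed2`, ...).
#' @export
make_seed_probability_maps <- function(grid, k_seeds = 3, seed = 1,
                                       sigma_mm = 5, peak = 0.9,
                                       min_separation_mm = 24,
                                       inner_margin = 4L) {
  stopifnot(k_seeds >= 1)
  centers <- with_local_seed(seed, {
    s <- grid$shape
    lo <- rep(inner_margin + 1L, 3L); hi <- s - inner_margin
    if (any(hi < lo)) stop("grid too small for seed placement")
    hi_y <- lo[2] + 1L
    cand <- voxel_to_world(grid, cbind(
      sample(lo[1]:hi[1], 400, replace = TRUE),
      sample(lo[2]:hi_y, 400, replace = TRUE),
      sample(lo[3]:hi[3], 400, replace = TRUE)))
    chosen <- cand[1, , drop = FALSE]
    while (nrow(chosen) < k_seeds) {
      dmin <- apply(cand, 1, function(p)
        min(sqrt(rowSums(sweep(chosen, 2L, p)^2))))
      chosen <- rbind(chosen, cand[which.max(dmin), ])
    }
    chosen
  })
  d <- as.matrix(stats::dist(centers))
  diag(d) <- Inf
  if (min(d) < min_separation_mm)
    stop(sprintf("could not separate %d seeds by %g mm on this grid",
                 k_seeds, min_separation_mm))
  all_xyz <- grid_voxel_centers(grid)
  out <- list()
  for (i in seq_len(k_seeds)) {
    d2 <- rowSums(sweep(all_xyz, 2L, centers[i, ])^2)
    vals <- peak * exp(-d2 / (2 * sigma_mm^2))
    out[[sprintf("seed%d", i)]] <-
      probability_map(grid, array(vals, dim = grid$shape),
                      name = sprintf("seed%d", i))
  }
  out
}

#' Planted ground truth for a synthetic study
#'
#' Chooses, per seed, a set of connected parcels and plants three kinds of
#' term associations:
#' * `pair` terms: co-activation terms coupled, per seed, to one connected
#'   parcel via a marginal-preserving comonotone mechanism — studies
#'   carrying the term co-activate the seed and the parcel far more often
#'   than chance while each region's own activation rate stays exactly at
#'   its background value, so such terms are invisible to single-region
#'   decoding. Every pair term is planted for every seed.
#' * `seed` terms: literal associations with each seed core (foci placed in
#'   the core with probability `signal_rate`).
#' * `region` terms: one literal association per connected parcel — these
#'   are what the region-alone decoding recovers and the set difference
#'   subtracts.
#'
#' Geometric constraints keep the coupled mechanism exact: connected
#' parcels lie at least `2 * radius_mm` from every seed core and more than
#' `radius_mm` from every other connected parcel (any seed), so a planted
#' focus can never activate a second region and the activation
#' neighbourhoods used in the generator never interact.
#'
#' @param parc a [parcellation()].
#' @param seed_masks named list of seed-core `region_mask` objects.
#' @param seed RNG seed.
#' @param connected_per_seed parcels planted as connected per seed.
#' @param n_pair_terms number of global pair terms (default 4).
#' @param seed_terms_per_seed literal seed terms per seed (default 3).
#' @param n_null_constructs construct terms with no planted signal.
#' @param vocab_size total vocabulary size (filled with non-construct
#'   noise terms).
#' @param radius_mm activation radius the generator (and decoder) use.
#' @param prevalence study prevalence of pair and unplanted terms.
#' @param prevalence_literal study prevalence of the literal seed/region
#'   terms; kept low so their foci barely move the regions' marginal
#'   activation rates and the co-activation contrast stays sharp.
#' @param base_rate target background activation rate for a seed core.
#' @param signal_rate literal planting probability (must exceed base_rate).
#' @return An object of class `synthetic_truth`: list with `seeds`,
#'   `connected`, `associations`, `vocabulary`, `allowlist` and the
#'   generator parameters.
#' @export
synthetic_truth <- function(parc, seed_masks, seed = 1,
                            connected_per_seed = 2, n_pair_terms = 4,
                            seed_terms_per_seed = 3, n_null_constructs = 3,
                            vocab_size = 120, radius_mm = 6,
                            prevalence = 0.15, prevalence_literal = 0.05,
                            base_rate = 0.15, signal_rate = 0.8) {
  stopifnot(signal_rate > base_rate)
  seed_names <- names(seed_masks)
  # parcels must sit beyond jitter reach of literally-planted seed foci;
  # within a coupled triple the regions only need to exceed the activation
  # radius so one region's coupled focus can never activate another
  core_gap <- 2 * radius_mm
  triple_gap <- radius_mm
  boxes <- parcel_boxes(parc)
  seed_boxes <- lapply(seed_masks, function(m) {
    idx <- mask_voxel_indices(m)
    rbind(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
  })
  vs <- parc$grid$voxel_size
  labels_all <- parc$table$label
  eligible <- labels_all[vapply(labels_all, function(l) {
    all(vapply(seed_boxes, function(sb)
      box_gap_mm(boxes[[as.character(l)]], sb, vs) > core_gap, logical(1)))
  }, logical(1))]
  seed_centers <- t(vapply(seed_masks, function(m)
    colMeans(mask_voxel_centers(m)), numeric(3)))
  parcel_centers <- t(vapply(eligible, function(l) {
    b <- boxes[[as.character(l)]]
    voxel_to_world(parc$grid, matrix(colMeans(b), 1))[1, ]
  }, numeric(3)))
  # connected parcels are chosen as "rank" transversals: the r-th parcel of
  # every seed forms a triple whose members are pairwise > 2*radius apart,
  # because pair term i couples rank (i mod connected_per_seed) across all
  # seeds and the coupled regions of one term must not interact
  n_seeds <- length(seed_names)
  n_slots <- connected_per_seed * n_seeds
  pref <- lapply(seq_len(n_seeds), function(i)
    order(rowSums(sweep(parcel_centers, 2L, seed_centers[i, ])^2)))
  compat <- outer(seq_along(eligible), seq_along(eligible),
                  Vectorize(function(a, b)
                    box_gap_mm(boxes[[as.character(eligible[a])]],
                               boxes[[as.character(eligible[b])]],
                               vs) > triple_gap))
  # slots in (rank, seed) order; every chosen parcel must clear the
  # activation radius from every other chosen parcel, so no coupled focus
  # (own term or a neighbouring parcel's) can activate a second region
  assign_slots <- function(slot, chosen) {
    if (slot > n_slots) return(chosen)
    i <- (slot - 1L) %% n_seeds + 1L          # seed of this slot
    for (j in pref[[i]]) {
      if (j %in% chosen) next
      if (length(chosen) && !all(compat[j, chosen])) next
      res <- assign_slots(slot + 1L, c(chosen, j))
      if (!is.null(res)) return(res)
    }
    NULL
  }
  sol <- assign_slots(1L, integer(0))
  if (is.null(sol))
    stop("could not place well-separated connected parcels; ",
         "reduce connected_per_seed or radius_mm")
  connected <- stats::setNames(
    lapply(seq_len(n_seeds), function(i)
      eligible[sol[seq(i, n_slots, by = n_seeds)]]),
    seed_names)
  # vocabulary and associations
  pair_terms <- sprintf("coactivation_%02d", seq_len(n_pair_terms))
  assoc <- list()
  for (ti in seq_len(n_pair_terms)) for (si in seq_along(seed_names)) {
    labs <- connected[[si]]
    assoc[[length(assoc) + 1L]] <- data.frame(
      term = pair_terms[ti], type = "pair", seed = seed_names[si],
      label = labs[(ti - 1L) %% length(labs) + 1L], stringsAsFactors = FALSE)
  }
  seed_terms <- character(0)
  for (si in seq_along(seed_names)) for (k in seq_len(seed_terms_per_seed)) {
    tm <- sprintf("seedterm_%s_%d", seed_names[si], k)
    seed_terms <- c(seed_terms, tm)
    assoc[[length(assoc) + 1L]] <- data.frame(
      term = tm, type = "seed", seed = seed_names[si], label = NA_integer_,
      stringsAsFactors = FALSE)
  }
  region_terms <- character(0)
  for (si in seq_along(seed_names)) for (l in connected[[si]]) {
    tm <- sprintf("regionterm_%03d", l)
    region_terms <- c(region_terms, tm)
    assoc[[length(assoc) + 1L]] <- data.frame(
      term = tm, type = "region", seed = NA_character_, label = l,
      stringsAsFactors = FALSE)
  }
  null_constructs <- sprintf("construct_null_%02d", seq_len(n_null_constructs))
  n_noise <- vocab_size - n_pair_terms - length(seed_terms) -
    length(region_terms) - n_null_constructs
  if (n_noise < 0) stop("vocab_size too small for the planted terms")
  noise_terms <- sprintf("lexical_noise_%03d", seq_len(n_noise))
  vocabulary <- with_local_seed(seed + 7L, sample(c(
    pair_terms, seed_terms, region_terms, null_constructs, noise_terms)))
  structure(list(
    seeds = seed_names, connected = connected,
    associations = do.call(rbind, assoc),
    vocabulary = vocabulary,
    allowlist = sort(c(pair_terms, seed_terms, region_terms,
                       null_constructs)),
    radius_mm = radius_mm, prevalence = prevalence,
    prevalence_literal = prevalence_literal, base_rate = base_rate,
    signal_rate = signal_rate, rng_seed = seed
  ), class = "synthetic_truth")
}

parcel_boxes <- function(parc) {
  idx <- which(parc$labels > 0L, arr.ind = TRUE)
  labs <- parc$labels[parc$labels > 0L]
  out <- list()
  for (l in parc$table$label) {
    sub <- idx[labs == l, , drop = FALSE]
    if (nrow(sub))
      out[[as.character(l)]] <- rbind(lo = apply(sub, 2, min),
                                      hi = apply(sub, 2, max))
  }
  out
}

# minimum Euclidean gap (mm) between two axis-aligned voxel boxes
box_gap_mm <- function(a, b, voxel_size) {
  g <- pmax(0, pmax(b["lo", ] - a["hi", ], a["lo", ] - b["hi", ]))
  sqrt(sum((g * voxel_size)^2))
}

#' Serialize / restore a synthetic truth object
#'
#' @param truth a `synthetic_truth`.
#' @param file JSON path.
#' @export
write_truth <- function(truth, file) {
  jsonlite::write_json(unclass(truth), file, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(file)
}

#' @rdname write_truth
#' @export
read_truth <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  x$connected <- lapply(x$connected, as.integer)
  x$associations <- as.data.frame(x$associations, stringsAsFactors = FALSE)
  x$associations$label <- as.integer(x$associations$label)
  structure(x, class = "synthetic_truth")
}

#' Simulate a coordinate database with planted term-system associations
#'
#' Every study receives a fixed number of background foci placed uniformly
#' over labelled voxels (a fixed count keeps the background activations of
#' disjoint regions uncorrelated, which a random count would not). Literal (`seed`/`region`) associations add a focus inside the
#' target region with probability `signal_rate` (jittered, truncated to the
#' labelled region). `pair` associations use the marginal-preserving
#' coupling described in [synthetic_truth()]: for a study carrying the
#' term, background foci that would activate any coupled region are removed
#' and replaced by a single shared uniform draw that reinstates each
#' coupled region's activation at exactly its background probability —
#' jointly for the seed and its parcel, so only their co-activation carries
#' signal.
#'
#' @param vocabulary character vector of terms (defaults to the truth's).
#' @param rois named list of `region_mask` objects covering every seed core
#'   (by seed name) and every planted parcel (as `parcel_<label>`).
#' @param truth a [synthetic_truth()].
#' @param parc the [parcellation()] (defines the labelled focus space).
#' @param n_studies number of studies (default 2000).
#' @param foci_per_study background foci per study (integer); `NULL`
#'   derives it so an average seed core's background activation rate is
#'   close to `truth$base_rate`.
#' @param jitter_sd_mm Gaussian jitter sd for literal planted foci.
#' @param seed RNG seed.
#' @return a [coordinate_db()].
#' @export
simulate_coordinate_db <- function(vocabulary = NULL, rois, truth, parc,
                                   n_studies = 2000, foci_per_study = NULL,
                                   jitter_sd_mm = 4, seed = 1) {
  if (is.null(vocabulary)) vocabulary <- truth$vocabulary
  radius <- truth$radius_mm
  prevalence <- truth$prevalence
  grid <- parc$grid
  labelled_idx <- which(parc$labels > 0L)
  labelled_xyz <- voxel_to_world(
    grid, which(array(parc$labels > 0L, dim = grid$shape), arr.ind = TRUE))
  V <- length(labelled_idx)
  # per-coupled-region: member voxel linear ids and activation neighbourhood
  roi_info <- lapply(rois, function(m) {
    stop_if_grid_mismatch(m$grid, grid, "simulate_coordinate_db")
    vox <- which(m$members)
    hit <- labelled_idx[foci_hit_mask(labelled_xyz, m, radius)]
    list(vox = vox, hit = hit, q = NA_real_)
  })
  if (is.null(foci_per_study)) {
    seed_fracs <- vapply(truth$seeds, function(s)
      length(roi_info[[s]]$hit) / V, numeric(1))
    foci_per_study <- max(1, round(log(1 - truth$base_rate) /
                                     log(1 - mean(seed_fracs))))
  }
  foci_per_study <- as.integer(round(foci_per_study))
  for (nm in names(roi_info))
    roi_info[[nm]]$q <-
      1 - (1 - length(roi_info[[nm]]$hit) / V)^foci_per_study
  assoc <- truth$associations
  pair_terms <- unique(assoc$term[assoc$type == "pair"])
  lit <- assoc[assoc$type %in% c("seed", "region"), , drop = FALSE]
  pair_regions <- lapply(pair_terms, function(tm) {
    rows <- assoc[assoc$term == tm & assoc$type == "pair", , drop = FALSE]
    unique(c(rows$seed, sprintf("parcel_%d", rows$label)))
  })
  names(pair_regions) <- pair_terms

  with_local_seed(seed, {
    prev_of <- stats::setNames(rep(prevalence, length(vocabulary)),
                               vocabulary)
    lit_terms <- intersect(unique(lit$term), vocabulary)
    prev_of[lit_terms] <- truth$prevalence_literal %||% prevalence
    present <- matrix(stats::runif(n_studies * length(vocabulary)) <
                        rep(prev_of, each = n_studies),
                      n_studies, length(vocabulary),
                      dimnames = list(NULL, vocabulary))
    freq <- matrix(0, n_studies, length(vocabulary),
                   dimnames = list(sprintf("study_%04d", seq_len(n_studies)),
                                   vocabulary))
    freq[present] <- round(stats::runif(sum(present), 0.01, 0.2), 4)
    foci_rows <- vector("list", n_studies)
    is_hit <- logical(n_voxels(grid))
    for (i in seq_len(n_studies)) {
      fvox <- labelled_idx[sample.int(V, foci_per_study, replace = TRUE)]
      fjit <- matrix(numeric(0), 0, 3)
      # coupled pair terms: thin background in the coupled neighbourhoods,
      # then reinstate each coupled region's activation at exactly its
      # background probability from ONE shared uniform draw per study —
      # marginals stay at background, only co-activation carries signal
      present_pair <- pair_terms[present[i, pair_terms]]
      if (length(present_pair)) {
        regions <- unique(unlist(pair_regions[present_pair]))
        hits <- unique(unlist(lapply(regions, function(r) roi_info[[r]]$hit)))
        if (length(fvox)) {
          is_hit[hits] <- TRUE
          fvox <- fvox[!is_hit[fvox]]
          is_hit[hits] <- FALSE
        }
        u <- stats::runif(1)
        for (r in regions) {
          info <- roi_info[[r]]
          if (u < info$q)
            fvox <- c(fvox, info$vox[sample.int(length(info$vox), 1L)])
        }
      }
      # literal seed/region associations
      for (j in which(lit$term %in% vocabulary & present[i, lit$term])) {
        if (stats::runif(1) >= truth$signal_rate) next
        r <- if (lit$type[j] == "seed") lit$seed[j]
          else sprintf("parcel_%d", lit$label[j])
        info <- roi_info[[r]]
        v <- info$vox[sample.int(length(info$vox), 1L)]
        xyz <- linear_to_world(grid, v)
        fjit <- rbind(fjit, jitter_focus(xyz, jitter_sd_mm, grid, parc))
      }
      pts <- rbind(if (length(fvox)) linear_to_world(grid, fvox), fjit)
      if (!is.null(pts) && nrow(pts))
        foci_rows[[i]] <- data.frame(study_id = rownames(freq)[i],
                                     x = pts[, 1], y = pts[, 2], z = pts[, 3])
    }
    foci <- do.call(rbind, foci_rows[!vapply(foci_rows, is.null, logical(1))])
    if (is.null(foci))
      foci <- data.frame(study_id = character(0), x = numeric(0),
                         y = numeric(0), z = numeric(0))
    rownames(foci) <- NULL
    coordinate_db(foci, freq)
  })
}

linear_to_world <- function(grid, lin) {
  s <- grid$shape
  lin0 <- lin - 1L
  i <- lin0 %% s[1] + 1L
  j <- (lin0 %/% s[1]) %% s[2] + 1L
  k <- lin0 %/% (s[1] * s[2]) + 1L
  voxel_to_world(grid, cbind(i, j, k))
}

# jitter a focus; resample until it stays in the labelled region
jitter_focus <- function(xyz, sd_mm, grid, parc, max_tries = 20L) {
  if (sd_mm <= 0) return(xyz)
  for (k in seq_len(max_tries)) {
    cand <- xyz + stats::rnorm(3, sd = sd_mm)
    co <- round(world_to_voxel(grid, matrix(cand, 1)))
    s <- grid$shape
    if (all(co >= 1) && all(co <= s)) {
      if (parc$labels[co[1], co[2], co[3]] > 0L) return(cand)
    }
  }
  xyz
}

#' Simulate multi-subject resting-state BOLD with planted connectivity
#'
#' Each seed has a latent signal shared by its core voxels (strongly) and
#' by the voxels of its planted connected parcels (scaled so the population
#' correlation with the seed-mean series is `effect_r`). All other voxels
#' are i.i.d. Gaussian noise.
#'
#' @param grid a [volume_grid()].
#' @param seeds named list of seed-core `region_mask` objects.
#' @param truth a [synthetic_truth()] (supplies the connected parcels).
#' @param parc the [parcellation()].
#' @param n_subjects number of subjects (default 20).
#' @param n_timepoints timepoints T (default 400, >= 50).
#' @param tr repetition time in seconds (default 0.8).
#' @param effect_r planted population correlation in (0, 1).
#' @param noise_sd noise standard deviation.
#' @param seed master RNG seed; per-subject streams are derived from it so
#'   any subject subset regenerates identically.
#' @param subjects integer vector of subject indices to generate
#'   (default all).
#' @return list of `bold4d`, one per requested subject.
#' @export
simulate_bold <- function(grid, seeds, truth, parc, n_subjects = 20,
                          n_timepoints = 400, tr = 0.8, effect_r = 0.5,
                          noise_sd = 1, seed = 1, subjects = NULL) {
  stopifnot(effect_r > 0, effect_r < 1, n_timepoints >= 50)
  if (is.null(subjects)) subjects <- seq_len(n_subjects)
  subj_seeds <- with_local_seed(seed, sample.int(1e8, n_subjects))
  alpha <- effect_r / sqrt(1 - effect_r^2) * noise_sd
  seed_vox <- lapply(seeds, function(m) which(m$members))
  conn_vox <- lapply(truth$connected[names(seeds)], function(labs)
    which(array(parc$labels %in% labs, dim = grid$shape)))
  V <- n_voxels(grid)
  lapply(subjects, function(si) {
    with_local_seed(subj_seeds[si], {
      x <- matrix(stats::rnorm(V * n_timepoints, sd = noise_sd),
                  V, n_timepoints)
      for (s in names(seeds)) {
        g <- stats::rnorm(n_timepoints)
        sv <- seed_vox[[s]]
        x[sv, ] <- 0.3 * x[sv, , drop = FALSE] +
          matrix(g, length(sv), n_timepoints, byrow = TRUE)
        cv <- conn_vox[[s]]
        x[cv, ] <- x[cv, , drop = FALSE] +
          alpha * matrix(g, length(cv), n_timepoints, byrow = TRUE)
      }
      bold4d(grid, x, tr = tr, subject_id = sprintf("sub-%03d", si))
    })
  })
}

#' Deterministic hard term-to-topic assignment
#'
#' Every term is assigned to exactly one of `n_topics` topics; topics are
#' guaranteed nonempty when `n_topics <= length(vocabulary)`.
#'
#' @param vocabulary character vector of terms.
#' @param n_topics number of topics (default 8).
#' @param seed RNG seed.
#' @return a [topic_mapping()].
#' @export
make_topic_mapping <- function(vocabulary, n_topics = 8, seed = 1) {
  stopifnot(n_topics <= length(vocabulary))
  ids <- with_local_seed(seed, sample(rep_len(seq_len(n_topics),
                                              length(vocabulary))))
  topic_mapping(stats::setNames(ids, vocabulary),
                stats::setNames(sprintf("topic_%02d", seq_len(n_topics)),
                                seq_len(n_topics)))
}

#' Generate the complete default synthetic study
#'
#' One call that builds every pipeline input with planted ground truth at
#' toy scale: atlas + networks, probabilistic seed maps, truth, coordinate
#' database, topic mapping and construct allowlist. BOLD volumes are not
#' included (they are large); generate them with [simulate_bold()] or let
#' [run_pipeline()] stream them per subject.
#'
#' @param seed master RNG seed; sub-generators use offsets of it.
#' @param grid_shape,n_parcels,k_seeds,n_studies,vocab_size,n_topics scale
#'   parameters (defaults: 32^3 grid, 40 parcels, 3 seeds, 2000 studies,
#'   120 terms, 8 topics).
#' @param connected_per_seed planted connected parcels per seed.
#' @param ... passed to [synthetic_truth()].
#' @return list with `grid`, `parc`, `networks`, `seed_maps`,
#'   `seed_masks`, `rois`, `truth`, `db`, `topics`, `allowlist`.
#' @export
synthetic_dataset <- function(seed = 1, grid_shape = c(32, 32, 32),
                              n_parcels = 40, k_seeds = 3,
                              n_studies = 2000, vocab_size = 120,
                              n_topics = 8, connected_per_seed = 2, ...) {
  atlas <- make_atlas(grid_shape, n_parcels, seed = seed + 1L)
  grid <- atlas$parc$grid
  seed_maps <- make_seed_probability_maps(grid, k_seeds, seed = seed + 2L)
  seed_masks <- lapply(seed_maps, threshold_probability, tau = 0.25)
  truth <- synthetic_truth(atlas$parc, seed_masks, seed = seed + 3L,
                           connected_per_seed = connected_per_seed,
                           vocab_size = vocab_size, ...)
  planted_labels <- sort(unique(unlist(truth$connected)))
  rois <- c(seed_masks,
            stats::setNames(lapply(planted_labels, function(l)
              parcel_mask(atlas$parc, l)),
              sprintf("parcel_%d", planted_labels)))
  db <- simulate_coordinate_db(truth$vocabulary, rois, truth, atlas$parc,
                               n_studies = n_studies, seed = seed + 4L)
  topics <- make_topic_mapping(truth$vocabulary, n_topics, seed = seed + 5L)
  list(grid = grid, parc = atlas$parc, networks = atlas$networks,
       seed_maps = seed_maps, seed_masks = seed_masks, rois = rois,
       truth = truth, db = db, topics = topics,
       allowlist = truth$allowlist, seed = seed)
}
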