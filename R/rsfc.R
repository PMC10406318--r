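#' Multi-timepoint BOLD volume
#'
#' Stores the series as a `n_voxels x T` matrix in array (column-major)
#' voxel order.
#'
#' @param grid a [volume_grid()].
#' @param series numeric matrix, `prod(grid$shape)` rows, T >= 2 columns.
#' @param tr repetition time in seconds (> 0).
#' @param subject_id identifier.
#' @return An object of class `bold4d`.
#' @export
bold4d <- function(grid, series, tr, subject_id = NULL) {
  series <- as.matrix(series)
  stopifnot(nrow(series) == n_voxels(grid), ncol(series) >= 2L, tr > 0)
  if (!all(is.finite(series))) stop("BOLD series must be finite")
  structure(list(grid = grid, series = series, tr = tr,
                 subject_id = subject_id), class = "bold4d")
}

#' @export
print.bold4d <- function(x, ...) {
  cat(sprintf("<bold4d> subject %s: %d voxels x %d timepoints, TR %.3g s\n",
              x$subject_id %||% "?", nrow(x$series), ncol(x$series), x$tr))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean time series over a seed region
#'
#' @param bold a `bold4d`.
#' @param seed a nonempty `region_mask` on the same grid.
#' @return numeric vector of length T.
#' @export
seed_timeseries <- function(bold, seed) {
  stop_if_grid_mismatch(bold$grid, seed$grid, "seed_timeseries")
  idx <- which(seed$members)
  if (length(idx) == 0L) stop("seed mask is empty")
  colMeans(bold$series[idx, , drop = FALSE])
}

#' Subject-level seed connectivity map
#'
#' Correlates every in-brain voxel's time series with the seed series and
#' maps the Pearson correlation through the Fisher transform
#' `z = atanh(r)`, with `r` clipped to `+/-(1 - 1e-7)`. Zero-variance voxel
#' series receive a statistic of 0; a zero-variance seed series is rejected.
#'
#' @param bold a `bold4d`.
#' @param seed_ts numeric vector of length T (e.g. from [seed_timeseries()]).
#' @param brain nonempty `region_mask` of in-brain voxels.
#' @return An object of class `connectivity_map` with per-voxel `stat`
#'   (NA outside the brain mask).
#' @export
seed_connectivity <- function(bold, seed_ts, brain) {
  stop_if_grid_mismatch(bold$grid, brain$grid, "seed_connectivity")
  stopifnot(length(seed_ts) == ncol(bold$series))
  idx <- which(brain$members)
  if (length(idx) == 0L) stop("brain mask is empty")
  sc <- seed_ts - mean(seed_ts)
  ss <- sqrt(sum(sc^2))
  if (ss == 0) stop("seed time series has zero variance")
  x <- bold$series[idx, , drop = FALSE]
  x <- x - rowMeans(x)
  xs <- sqrt(rowSums(x^2))
  r <- as.vector(x %*% sc) / (xs * ss)
  r[xs == 0] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  stat <- rep(NA_real_, n_voxels(bold$grid))
  stat[idx] <- atanh(r)
  structure(list(grid = bold$grid, stat = stat,
                 subject_id = bold$subject_id, seed_name = NULL),
            class = "connectivity_map")
}

#' Random-effects group map
#'
#' One-sample t statistic of the subject-level Fisher-z values against zero,
#' per voxel, with `df = N - 1`. Voxels where all subjects agree on a
#' nonzero constant (zero between-subject variance) receive a signed
#' infinite sentinel; zero mean with zero variance gives 0.
#'
#' @param maps list of >= 2 `connectivity_map` objects on one grid.
#' @return An object of class `group_map` with per-voxel `tstat`, `df`,
#'   `n_subjects`.
#' @export
group_map <- function(maps) {
  stopifnot(length(maps) >= 2L)
  for (m in maps[-1]) stop_if_grid_mismatch(maps[[1]]$grid, m$grid, "group_map")
  z <- do.call(cbind, lapply(maps, `[[`, "stat"))
  n <- ncol(z)
  mu <- rowMeans(z)
  sdv <- sqrt(rowSums((z - mu)^2) / (n - 1))
  t <- mu / (sdv / sqrt(n))
  degen <- !is.na(sdv) & sdv == 0
  t[degen] <- sign(mu[degen]) * Inf
  t[degen & mu == 0] <- 0
  structure(list(grid = maps[[1]]$grid, tstat = t, df = n - 1L,
                 n_subjects = n), class = "group_map")
}

#' Voxel-level FWE thresholding of a group map
#'
#' Controls the family-wise error across in-brain voxels at the voxel level.
#' `"bonferroni"` compares each voxel's one-sided (or two-sided) t p-value
#' with `alpha / m` over the `m` in-brain voxels. `"permutation"` builds a
#' max-statistic null by sign-flipping the subject maps and retains voxels
#' whose t exceeds the `(1 - alpha)` quantile of the permutation maxima.
#'
#' @param group a `group_map`.
#' @param alpha FWE level in (0, 1); default 0.05.
#' @param method `"bonferroni"` (default) or `"permutation"`.
#' @param maps subject `connectivity_map` list; required for the
#'   permutation method.
#' @param sided `"one"` (positive coupling, default) or `"two"`.
#' @param n_perm number of sign flips for the permutation null.
#' @param seed RNG seed for the sign flips.
#' @return a `region_mask` of suprathreshold voxels.
#' @export
fwe_threshold <- function(group, alpha = 0.05,
                          method = c("bonferroni", "permutation"),
                          maps = NULL, sided = c("one", "two"),
                          n_perm = 1000L, seed = NULL) {
  method <- match.arg(method)
  sided <- match.arg(sided)
  stopifnot(alpha > 0, alpha < 1)
  inbrain <- which(!is.na(group$tstat))
  m <- length(inbrain)
  if (m == 0L) stop("group map has no in-brain voxels")
  t <- group$tstat[inbrain]
  members <- logical(n_voxels(group$grid))
  if (method == "bonferroni") {
    p <- stats::pt(abs(t), df = group$df, lower.tail = FALSE)
    if (sided == "two") p <- 2 * p
    if (sided == "one") p[t < 0] <- 1 - p[t < 0]
    p[is.infinite(t) & t > 0] <- 0
    if (sided == "two") p[is.infinite(t)] <- 0
    members[inbrain] <- p <= alpha / m
  } else {
    if (is.null(maps)) stop("permutation method requires the subject maps")
    if (group$n_subjects < 6L)
      warning("permutation null with < 6 subjects is very coarse")
    z <- do.call(cbind, lapply(maps, function(x) x$stat[inbrain]))
    n <- ncol(z)
    if (!is.null(seed)) {
      old <- get0(".Random.seed", envir = globalenv())
      on.exit(restore_rng(old), add = TRUE)
      set.seed(seed)
    }
    maxima <- numeric(n_perm)
    for (b in seq_len(n_perm)) {
      s <- sample(c(-1, 1), n, replace = TRUE)
      zb <- sweep(z, 2L, s, `*`)
      mu <- rowMeans(zb)
      sdv <- sqrt((rowSums(zb^2) - n * mu^2) / (n - 1))
      tb <- mu / (sdv / sqrt(n))
      tb[sdv == 0] <- 0
      maxima[b] <- if (sided == "two") max(abs(tb)) else max(tb)
    }
    crit <- stats::quantile(maxima, 1 - alpha, type = 1, names = FALSE)
    obs <- if (sided == "two") abs(t) else t
    members[inbrain] <- obs > crit
  }
  region_mask(group$grid, array(members, dim = group$grid$shape),
              name = sprintf("fwe<%g", alpha))
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Select cortical parcels functionally coupled to each seed
#'
#' Retains parcels whose voxels are covered by the suprathreshold map with
#' fraction at least `min_overlap` ("at least 80%" reads as `>=`), then
#' excludes any parcel sharing one or more voxels with any seed mask.
#'
#' @param suprathreshold `region_mask` of suprathreshold voxels (one seed's
#'   thresholded group map).
#' @param parc a `parcellation` on the same grid.
#' @param seeds list of seed `region_mask` objects (exclusion set).
#' @param min_overlap minimum parcel coverage fraction; default 0.8.
#' @param seed_name name recorded in the output.
#' @return data.frame of class `connected_regions` with columns `seed`,
#'   `label`, `name`, `overlap_fraction`.
#' @export
connected_regions <- function(suprathreshold, parc, seeds,
                              min_overlap = 0.8, seed_name = "seed") {
  stop_if_grid_mismatch(suprathreshold$grid, parc$grid, "connected_regions")
  seed_union <- Reduce(`|`, lapply(seeds, function(s) {
    stop_if_grid_mismatch(s$grid, parc$grid, "connected_regions")
    s$members
  }))
  lab <- as.vector(parc$labels)
  present <- setdiff(sort(unique(lab)), 0L)
  sizes <- tabulate(lab, nbins = max(present, 1L))
  cov_counts <- tabulate(lab[as.vector(suprathreshold$members)],
                         nbins = max(present, 1L))
  seed_hits <- tabulate(lab[as.vector(seed_union)], nbins = max(present, 1L))
  keep <- present[cov_counts[present] / sizes[present] >= min_overlap &
                    seed_hits[present] == 0L]
  out <- data.frame(
    seed = rep(seed_name, length(keep)),
    label = keep,
    name = parc$table$name[match(keep, parc$table$label)],
    overlap_fraction = if (length(keep)) cov_counts[keep] / sizes[keep] else numeric(0),
    stringsAsFactors = FALSE
  )
  class(out) <- c("connected_regions", class(out))
  out
}
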