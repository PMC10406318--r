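#' Coordinate database of studies, foci and term frequencies
#'
#' @param foci data.frame with columns `study_id`, `x`, `y`, `z`
#'   (MNI mm). Studies without foci are legal and stay inactive for every
#'   region.
#' @param term_freq numeric study x term matrix in \[0, 1\] with study ids
#'   as rownames and terms as colnames. Every focus must belong to a row.
#' @return An object of class `coordinate_db` with `studies`, `foci`,
#'   `term_freq`, `vocabulary`.
#' @export
coordinate_db <- function(foci, term_freq) {
  stopifnot(is.data.frame(foci),
            all(c("study_id", "x", "y", "z") %in% names(foci)))
  term_freq <- as.matrix(term_freq)
  if (is.null(rownames(term_freq)) || is.null(colnames(term_freq)))
    stop("term_freq needs study ids as rownames and terms as colnames")
  if (anyDuplicated(colnames(term_freq))) stop("duplicate terms in vocabulary")
  if (any(term_freq < 0) || any(term_freq > 1))
    stop("term frequencies must lie in [0, 1]")
  foci$study_id <- as.character(foci$study_id)
  unknown <- setdiff(unique(foci$study_id), rownames(term_freq))
  if (length(unknown))
    stop("foci reference unknown studies: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  structure(list(studies = rownames(term_freq), foci = foci,
                 term_freq = term_freq, vocabulary = colnames(term_freq)),
            class = "coordinate_db")
}

#' @export
print.coordinate_db <- function(x, ...) {
  cat(sprintf("<coordinate_db> %d studies, %d foci, %d terms\n",
              length(x$studies), nrow(x$foci), length(x$vocabulary)))
  invisible(x)
}

#' Binarize the study x term frequency matrix
#'
#' A study carries a term iff its frequency is at least `f_min`
#' (the usual meta-analytic convention, default 0.001).
#'
#' @param db a `coordinate_db`.
#' @param f_min frequency cutoff.
#' @return An object of class `term_labeling` wrapping a logical
#'   study x term matrix and the cutoff used.
#' @export
term_labeling <- function(db, f_min = 0.001) {
  structure(list(labels = db$term_freq >= f_min, f_min = f_min),
            class = "term_labeling")
}

#' Which studies activate a region of interest
#'
#' A study is active iff at least one of its foci lies within `radius_mm`
#' of some ROI voxel centre; `radius_mm = 0` requires the focus to fall
#' inside an ROI voxel.
#'
#' @param db a `coordinate_db`.
#' @param roi nonempty `region_mask`.
#' @param radius_mm nonnegative radius in mm (default 6).
#' @return An object of class `activation_vector`: logical per-study
#'   vector plus `roi_name` and `radius_mm`.
#' @export
activation_vector <- function(db, roi, radius_mm = 6) {
  stopifnot(radius_mm >= 0)
  if (mask_size(roi) == 0L) stop("ROI mask is empty")
  act <- stats::setNames(logical(length(db$studies)), db$studies)
  if (nrow(db$foci)) {
    fx <- as.matrix(db$foci[, c("x", "y", "z")])
    hit <- foci_hit_mask(fx, roi, radius_mm)
    if (any(hit)) {
      ids <- unique(db$foci$study_id[hit])
      act[ids] <- TRUE
    }
  }
  structure(list(active = act, roi_name = roi$name, radius_mm = radius_mm),
            class = "activation_vector")
}

# logical per-focus: is focus within radius of any ROI voxel centre?
# radius 0: the focus's enclosing voxel is a member.
foci_hit_mask <- function(fx, roi, radius_mm) {
  g <- roi$grid
  co <- world_to_voxel(g, fx)
  if (radius_mm == 0) {
    co <- round(co)
    inside <- co[, 1] >= 1 & co[, 1] <= g$shape[1] &
      co[, 2] >= 1 & co[, 2] <= g$shape[2] &
      co[, 3] >= 1 & co[, 3] <= g$shape[3]
    hit <- logical(nrow(fx))
    if (any(inside)) {
      lin <- co[inside, 1] + (co[inside, 2] - 1) * g$shape[1] +
        (co[inside, 3] - 1) * g$shape[1] * g$shape[2]
      hit[inside] <- roi$members[lin]
    }
    return(hit)
  }
  centers <- mask_voxel_centers(roi)
  # blocked all-pairs squared distances to keep memory bounded
  r2 <- radius_mm^2
  hit <- logical(nrow(fx))
  cs2 <- rowSums(centers^2)
  block <- max(1L, floor(2e6 / nrow(centers)))
  for (start in seq(1L, nrow(fx), by = block)) {
    sel <- start:min(start + block - 1L, nrow(fx))
    f <- fx[sel, , drop = FALSE]
    d2 <- outer(rowSums(f^2), cs2, `+`) - 2 * (f %*% t(centers))
    hit[sel] <- row_mins(d2) <= r2 + 1e-9
  }
  hit
}

row_mins <- function(m) do.call(pmin, as.data.frame(m))

#' Empirical activation likelihoods for one term
#'
#' Proportions of active studies among studies carrying the term and among
#' studies not carrying it. Terms with a degenerate stratum (all or no
#' studies carry the term) are not computable.
#'
#' @param act an `activation_vector`.
#' @param lab a `term_labeling` over the same studies.
#' @param term term name.
#' @return named numeric vector `c(p_act_given_term, p_act_given_notterm)`.
#' @export
condition_probs <- function(act, lab, term) {
  has <- lab$labels[, term]
  n1 <- sum(has); n0 <- sum(!has)
  if (n1 == 0L || n0 == 0L)
    stop(sprintf("term '%s' has a degenerate stratum", term))
  c(p_act_given_term = sum(act$active[has]) / n1,
    p_act_given_notterm = sum(act$active[!has]) / n0)
}

#' Forward inference: marginal activation probability under the prior
#'
#' `P(activation | term, p) = p * P(act|term) + (1 - p) * P(act|not term)`.
#'
#' @param pat `P(activation | term)` in \[0, 1\].
#' @param patn `P(activation | not term)` in \[0, 1\].
#' @param prior prior term probability `p` (default 0.5, which equates the
#'   base rates of all terms).
#' @return probability in \[0, 1\].
#' @export
forward_inference <- function(pat, patn, prior = 0.5) {
  stopifnot(all(pat >= 0 & pat <= 1), all(patn >= 0 & patn <= 1),
            all(prior >= 0 & prior <= 1))
  prior * pat + (1 - prior) * patn
}

#' Reverse inference: posterior term probability given activation
#'
#' `P(term | activation, p) = p * P(act|term) / P(activation | term, p)`.
#' Undefined (rejected) when the forward probability is zero.
#'
#' @inheritParams forward_inference
#' @return posterior probability in \[0, 1\].
#' @export
reverse_inference <- function(pat, patn, prior = 0.5) {
  fwd <- forward_inference(pat, patn, prior)
  if (any(fwd == 0))
    stop("forward probability is zero; posterior undefined")
  prior * pat / fwd
}

#' Chi-square test of activation-term independence
#'
#' Pearson chi-square on the 2x2 activation x term table, df = 1, without
#' continuity correction, upper-tail p. A zero marginal makes the term
#' uninformative: statistic 0, p = 1.
#'
#' @inheritParams condition_probs
#' @param correct apply the Yates continuity correction (default FALSE).
#' @return named numeric vector `c(stat, p_value)`.
#' @export
chi_square_association <- function(act, lab, term, correct = FALSE) {
  has <- lab$labels[, term]
  a <- sum(act$active & has); b <- sum(!act$active & has)
  c_ <- sum(act$active & !has); d <- sum(!act$active & !has)
  res <- chi2_from_counts(a, b, c_, d, correct = correct)
  c(stat = res$stat, p_value = res$p_value)
}

chi2_from_counts <- function(a, b, c_, d, correct = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  c_ <- as.numeric(c_); d <- as.numeric(d)
  n <- a + b + c_ + d
  r1 <- a + b; r2 <- c_ + d; c1 <- a + c_; c2 <- b + d
  num <- abs(a * d - b * c_)
  if (correct) num <- pmax(num - n / 2, 0)
  zero <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  denom <- r1 * r2 * c1 * c2
  denom[zero] <- 1
  stat <- n * num^2 / denom
  stat[zero] <- 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  p[zero] <- 1
  list(stat = stat, p_value = p)
}

#' Benjamini-Hochberg FDR correction
#'
#' Standard step-up procedure; q-values are the BH-adjusted p-values
#' (`min` over larger p of `m * p / rank`, capped at 1). Rejection at
#' `q <= alpha`.
#'
#' @param p_values numeric vector of p-values in \[0, 1\].
#' @param alpha FDR level (default 0.05).
#' @return list with `q_values` and logical `rejected`.
#' @export
fdr_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L)
    return(list(q_values = numeric(0), rejected = logical(0)))
  stopifnot(all(p_values >= 0 & p_values <= 1))
  q <- stats::p.adjust(p_values, method = "BH")
  list(q_values = q, rejected = q <= alpha)
}

#' Decode a region of interest against the database
#'
#' For every computable term: empirical activation likelihoods in the
#' term/non-term strata, forward and reverse (posterior) inference under the
#' prior, a two-way chi-square of activation x term independence, and BH-FDR
#' corrected significance. Terms with a degenerate stratum are excluded.
#'
#' @param db a `coordinate_db`.
#' @param roi nonempty `region_mask`.
#' @param radius_mm activation radius in mm (default 6).
#' @param prior prior term probability (default 0.5).
#' @param f_min term binarization cutoff (default 0.001).
#' @param alpha FDR level for the significance flag (default 0.05).
#' @return An object of class `decoding_result`: a list with `roi_name`,
#'   `prior`, `radius_mm`, `n_active_studies`, `n_studies`, and `rows`, a
#'   data.frame with columns term, p_act_given_term, p_act_given_notterm,
#'   forward, posterior, chi2_stat, p_value, q_value, significant.
#' @export
decode_roi <- function(db, roi, radius_mm = 6, prior = 0.5,
                       f_min = 0.001, alpha = 0.05) {
  if (length(db$studies) < 2L) stop("need at least 2 studies to decode")
  act <- activation_vector(db, roi, radius_mm = radius_mm)
  decode_activation(db, act, prior = prior, f_min = f_min, alpha = alpha,
                    roi_name = roi$name)
}

#' Decode from a precomputed activation vector
#'
#' The workhorse behind [decode_roi()] and the pair decoding: everything
#' after the focus-to-ROI mapping.
#'
#' @param db a `coordinate_db`.
#' @param act an `activation_vector` over the database's studies.
#' @inheritParams decode_roi
#' @param roi_name name recorded on the result.
#' @return a `decoding_result` (see [decode_roi()]).
#' @export
decode_activation <- function(db, act, prior = 0.5, f_min = 0.001,
                              alpha = 0.05, roi_name = act$roi_name) {
  lab <- term_labeling(db, f_min = f_min)
  L <- lab$labels
  active <- act$active
  n <- length(active)
  n1 <- colSums(L)                       # studies carrying each term
  a <- as.vector(crossprod(L, active))   # active & term
  computable <- n1 > 0L & n1 < n
  terms <- db$vocabulary[computable]
  n1 <- n1[computable]; a <- a[computable]
  n_act <- sum(active)
  c_ <- n_act - a                        # active & not term
  b <- n1 - a
  d <- (n - n1) - c_
  pat <- a / n1
  patn <- c_ / (n - n1)
  fwd <- forward_inference(pat, patn, prior)
  ok <- fwd > 0
  terms <- terms[ok]
  pat <- pat[ok]; patn <- patn[ok]; fwd <- fwd[ok]
  a <- a[ok]; b <- b[ok]; c_ <- c_[ok]; d <- d[ok]
  post <- prior * pat / fwd
  chi <- chi2_from_counts(a, b, c_, d)
  fdr <- fdr_correct(chi$p_value, alpha = alpha)
  rows <- data.frame(
    term = terms,
    p_act_given_term = pat,
    p_act_given_notterm = patn,
    forward = fwd,
    posterior = post,
    chi2_stat = chi$stat,
    p_value = chi$p_value,
    q_value = fdr$q_values,
    significant = fdr$rejected,
    stringsAsFactors = FALSE
  )
  structure(list(roi_name = roi_name, prior = prior,
                 radius_mm = act$radius_mm, rows = rows,
                 n_active_studies = n_act, n_studies = n),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> ROI '%s': %d/%d studies active, %d terms, %d significant\n",
              x$roi_name %||% "?", x$n_active_studies, x$n_studies,
              nrow(x$rows), sum(x$rows$significant)))
  invisible(x)
}

#' Select the top decoded terms
#'
#' Default order `rank_then_filter`: take the `k` terms with the highest
#' posterior (ties broken lexicographically), then drop non-significant
#' rows, then keep only allowlisted (psychological-construct) terms.
#' `filter_then_rank` filters first and then ranks, always returning up to
#' `k` surviving terms.
#'
#' @param result a `decoding_result`.
#' @param k maximum number of terms (default 30).
#' @param allowlist character vector of permitted terms; `NULL` or empty
#'   skips the filter with a warning.
#' @param order `"rank_then_filter"` (default) or `"filter_then_rank"`.
#' @return character vector of at most `k` terms, in rank order.
#' @export
select_terms <- function(result, k = 30,
                         allowlist = NULL,
                         order = c("rank_then_filter", "filter_then_rank")) {
  order <- match.arg(order)
  stopifnot(k >= 1)
  rows <- result$rows
  skip_allow <- is.null(allowlist) || length(allowlist) == 0L
  if (skip_allow)
    warning("empty construct allowlist: allowlist filtering skipped")
  rank_rows <- function(r) r[order(-r$posterior, r$term), , drop = FALSE]
  if (order == "rank_then_filter") {
    rows <- utils::head(rank_rows(rows), k)
    rows <- rows[rows$significant, , drop = FALSE]
    if (!skip_allow) rows <- rows[rows$term %in% allowlist, , drop = FALSE]
  } else {
    rows <- rows[rows$significant, , drop = FALSE]
    if (!skip_allow) rows <- rows[rows$term %in% allowlist, , drop = FALSE]
    rows <- utils::head(rank_rows(rows), k)
  }
  rows$term
}

#' Write a decoding result as TSV
#'
#' @param result a `decoding_result`.
#' @param file output path.
#' @export
write_decoding_result <- function(result, file) {
  write_tsv(result$rows, file)
}
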