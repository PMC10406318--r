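# Independent oracles and shared fixtures for the test suite.

# plain-loop trilinear interpolation at one source-voxel coordinate
# (1-based, possibly fractional); out-of-bounds corners contribute 0
oracle_trilinear_at <- function(values, co) {
  s <- dim(values)
  f <- floor(co); w <- co - f
  acc <- 0
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    cx <- f[1] + dx; cy <- f[2] + dy; cz <- f[3] + dz
    wt <- (if (dx) w[1] else 1 - w[1]) *
      (if (dy) w[2] else 1 - w[2]) *
      (if (dz) w[3] else 1 - w[3])
    v <- if (cx >= 1 && cx <= s[1] && cy >= 1 && cy <= s[2] &&
             cz >= 1 && cz <= s[3]) values[cx, cy, cz] else 0
    acc <- acc + wt * v
  }
  acc
}

# closed-form 2x2 chi-square n(ad-bc)^2 / ((a+b)(c+d)(a+c)(b+d))
oracle_chi2 <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

# hand-rolled Benjamini-Hochberg step-up: q_i = min_{j >= i} m p_(j) / j
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  # cummin from the largest p downwards
  q_sorted <- pmin(1, rev(cummin(rev(m * p[o] / seq_len(m)))))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# brute-force Bayes posterior by enumerating a weighted joint table:
# impose prior mass `prior` on the term stratum and split each stratum by
# its activation likelihood, then read P(term | activation) off the table
oracle_bayes_posterior <- function(pat, patn, prior) {
  w_t_act <- prior * pat
  w_t_no <- prior * (1 - pat)
  w_n_act <- (1 - prior) * patn
  w_n_no <- (1 - prior) * (1 - patn)
  stopifnot(abs(w_t_act + w_t_no + w_n_act + w_n_no - 1) < 1e-12)
  w_t_act / (w_t_act + w_n_act)
}

# tiny grid helper
test_grid <- function(shape = c(6, 6, 6), voxel = c(2, 2, 2)) {
  volume_grid(shape, voxel_size = voxel)
}

mask_from_indices <- function(grid, idx, name = "m") {
  m <- array(FALSE, dim = grid$shape)
  m[idx] <- TRUE
  region_mask(grid, m, name = name)
}

# a coordinate database with fully controlled activation: active studies
# get one focus at the first ROI voxel centre, inactive studies one focus
# at `elsewhere` (a voxel index triple far from the ROI)
toy_db <- function(active, term_mat, roi, elsewhere) {
  grid <- roi$grid
  n <- length(active)
  ids <- sprintf("s%03d", seq_len(n))
  rownames(term_mat) <- ids
  roi_center <- voxel_to_world(grid, mask_voxel_indices(roi)[1, , drop = FALSE])
  other <- voxel_to_world(grid, matrix(elsewhere, 1))
  pts <- matrix(NA_real_, n, 3)
  pts[active, ] <- matrix(roi_center, sum(active), 3, byrow = TRUE)
  pts[!active, ] <- matrix(other, sum(!active), 3, byrow = TRUE)
  coordinate_db(data.frame(study_id = ids, x = pts[, 1], y = pts[, 2],
                           z = pts[, 3]), term_mat)
}

# memoised default fixture + pipeline run shared across test files
.sysdecode_memo <- new.env(parent = emptyenv())

default_dataset <- function() {
  if (is.null(.sysdecode_memo$ds))
    .sysdecode_memo$ds <- synthetic_dataset(seed = 1)
  .sysdecode_memo$ds
}

default_pipeline <- function() {
  if (is.null(.sysdecode_memo$pipe))
    .sysdecode_memo$pipe <- run_pipeline(pipeline_config(seed = 1),
                                         data = default_dataset())
  .sysdecode_memo$pipe
}
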