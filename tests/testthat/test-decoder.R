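term_mat <- function(n, terms, fill = 0) {
  matrix(fill, n, length(terms), dimnames = list(NULL, terms))
}

test_that("activation_vector maps foci to studies", {
  g <- test_grid(c(6, 6, 6))
  roi <- mask_from_indices(g, c(1, 2, 7))
  tm <- term_mat(3, "t")
  rownames(tm) <- c("s1", "s2", "s3")
  center <- voxel_to_world(g, mask_voxel_indices(roi)[1, , drop = FALSE])
  far <- voxel_to_world(g, matrix(c(6, 6, 6), 1))
  foci <- data.frame(study_id = c("s1", "s3"),
                     x = c(center[1], far[1]), y = c(center[2], far[2]),
                     z = c(center[3], far[3]))
  db <- coordinate_db(foci, tm)
  act0 <- activation_vector(db, roi, radius_mm = 0)
  expect_equal(unname(act0$active), c(TRUE, FALSE, FALSE))  # s2 has no foci
  expect_error(activation_vector(db, mask_from_indices(g, integer(0))),
               "empty")
})

test_that("radius-based activation equals the all-pairs distance scan", {
  set.seed(31)
  g <- volume_grid(c(10, 10, 10))
  roi <- mask_from_indices(g, sample.int(1000, 30))
  n <- 60
  ids <- sprintf("s%02d", 1:n)
  foci <- do.call(rbind, lapply(seq_len(n), function(i) {
    k <- sample(0:3, 1)
    if (k == 0) return(NULL)
    data.frame(study_id = ids[i],
               x = runif(k, -12, 12), y = runif(k, -12, 12),
               z = runif(k, -12, 12))
  }))
  tm <- term_mat(n, "t"); rownames(tm) <- ids
  db <- coordinate_db(foci, tm)
  act <- activation_vector(db, roi, radius_mm = 6)
  centers <- mask_voxel_centers(roi)
  brute <- vapply(ids, function(id) {
    f <- foci[foci$study_id == id, c("x", "y", "z")]
    if (nrow(f) == 0) return(FALSE)
    any(apply(f, 1, function(p)
      min(sqrt(colSums((t(centers) - as.numeric(p))^2))) <= 6))
  }, logical(1))
  expect_equal(act$active, brute)
})

test_that("condition_probs are stratum proportions", {
  g <- test_grid(c(6, 6, 6))
  roi <- mask_from_indices(g, 1)
  # counts: act&term 30, !act&term 10, act&!term 10, !act&!term 30
  active <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  has <- rep(c(TRUE, FALSE), c(40, 40))
  tm <- term_mat(80, c("t", "all", "none"))
  tm[has, "t"] <- 0.01
  tm[, "all"] <- 0.01
  db <- toy_db(active, tm, roi, c(6, 6, 6))
  act <- activation_vector(db, roi, radius_mm = 0)
  lab <- term_labeling(db)
  expect_equal(unname(condition_probs(act, lab, "t")), c(0.75, 0.25))
  expect_error(condition_probs(act, lab, "all"), "degenerate")
  expect_error(condition_probs(act, lab, "none"), "degenerate")
  # ten term-studies all active
  tm2 <- term_mat(20, "u")
  tm2[1:10, "u"] <- 0.01
  db2 <- toy_db(rep(c(TRUE, FALSE), each = 10), tm2, roi, c(6, 6, 6))
  act2 <- activation_vector(db2, roi, radius_mm = 0)
  expect_equal(condition_probs(act2, term_labeling(db2), "u")[["p_act_given_term"]], 1)
})

test_that("forward and reverse inference evaluate the printed formulas", {
  expect_equal(forward_inference(0.8, 0.2, 0.5), 0.5)
  expect_equal(forward_inference(0.3, 0.3, 0.7), 0.3)   # mixture of equals
  expect_equal(forward_inference(1, 0, 0.5), 0.5)
  expect_equal(reverse_inference(0.8, 0.2, 0.5), 0.8)
  expect_equal(reverse_inference(0.44, 0.44, 0.5), 0.5) # pat = patn -> prior
  expect_equal(reverse_inference(1, 0, 0.5), 1)
  expect_error(reverse_inference(0, 0, 0.5), "zero")
})

test_that("reverse inference matches the joint-count Bayes oracle", {
  set.seed(32)
  for (i in 1:1000) {
    pat <- runif(1, 0.01, 1)
    patn <- runif(1, 0.01, 1)
    prior <- runif(1, 0.05, 0.95)
    expect_equal(reverse_inference(pat, patn, prior),
                 oracle_bayes_posterior(pat, patn, prior),
                 tolerance = 1e-12)
  }
})

test_that("posterior is monotone in the activation likelihoods", {
  pats <- seq(0.05, 0.95, by = 0.1)
  post <- sapply(pats, reverse_inference, patn = 0.3, prior = 0.5)
  expect_true(all(diff(post) > 0))
  post2 <- sapply(pats, function(pn) reverse_inference(0.5, pn, 0.5))
  expect_true(all(diff(post2) < 0))
  expect_true(all(post >= 0 & post <= 1))
})

test_that("chi-square matches the closed form and the stats oracle", {
  g <- test_grid(c(6, 6, 6))
  roi <- mask_from_indices(g, 1)
  active <- rep(c(TRUE, FALSE, TRUE, FALSE), c(30, 10, 10, 30))
  tm <- term_mat(80, "t"); tm[rep(c(TRUE, FALSE), c(40, 40)), "t"] <- 0.01
  db <- toy_db(active, tm, roi, c(6, 6, 6))
  act <- activation_vector(db, roi, radius_mm = 0)
  res <- chi_square_association(act, term_labeling(db), "t")
  expect_equal(unname(res["stat"]), 20)
  # identical rows: exact independence
  tm2 <- term_mat(40, "t"); tm2[c(1:10, 21:30), "t"] <- 0.01
  db2 <- toy_db(rep(c(TRUE, FALSE), each = 20), tm2, roi, c(6, 6, 6))
  res2 <- chi_square_association(activation_vector(db2, roi, 0),
                                 term_labeling(db2), "t")
  expect_equal(unname(res2["stat"]), 0)
  expect_equal(unname(res2["p_value"]), 1)
  # random tables against the closed form and stats::chisq.test
  set.seed(33)
  for (i in 1:200) {
    cts <- as.numeric(rmultinom(1, 400, runif(4, 0.05, 1))[, 1])
    a <- cts[1]; b <- cts[2]; c_ <- cts[3]; d <- cts[4]
    got <- sysdecode:::chi2_from_counts(a, b, c_, d)
    expect_equal(got$stat, oracle_chi2(a, b, c_, d), tolerance = 1e-10)
    if (all(c(a + b, c_ + d, a + c_, b + d) > 0)) {
      ref <- suppressWarnings(
        chisq.test(matrix(c(a, b, c_, d), 2, byrow = TRUE),
                   correct = FALSE))
      expect_equal(got$stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
    }
  }
})

test_that("BH correction reproduces the hand step-up", {
  out <- fdr_correct(c(0.001, 0.01, 0.02, 0.04, 0.2), alpha = 0.05)
  expect_equal(out$rejected, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(fdr_correct(rep(1, 10))$rejected, rep(FALSE, 10))
  expect_true(fdr_correct(0.04, 0.05)$rejected)
  expect_equal(fdr_correct(numeric(0))$q_values, numeric(0))
  set.seed(34)
  p <- runif(50)^2
  expect_equal(fdr_correct(p)$q_values, oracle_bh(p), tolerance = 1e-12)
})

test_that("decode_roi recovers a planted term and nothing under the null", {
  set.seed(35)
  g <- test_grid(c(6, 6, 6))
  roi <- mask_from_indices(g, 1)
  n <- 600
  active <- runif(n) < 0.3
  terms <- sprintf("t%02d", 1:20)
  tm <- term_mat(n, terms)
  for (t in terms) tm[runif(n) < 0.3, t] <- 0.01
  # plant: term t01 present mostly when the ROI is active
  tm[, "t01"] <- 0
  tm[active & runif(n) < 0.8, "t01"] <- 0.01
  tm[!active & runif(n) < 0.05, "t01"] <- 0.01
  db <- toy_db(active, tm, roi, c(6, 6, 6))
  res <- decode_roi(db, roi, radius_mm = 0)
  rows <- res$rows
  expect_equal(rows$term[which.max(rows$posterior)], "t01")
  expect_true(rows$significant[rows$term == "t01"])
  # posterior = prior when pat = patn (constructed exactly)
  tm3 <- term_mat(40, "even")
  tm3[c(1:6, 21:26), "even"] <- 0.01  # 6/20 active in both strata
  db3 <- toy_db(rep(c(TRUE, FALSE), each = 20), tm3, roi, c(6, 6, 6))
  res3 <- decode_roi(db3, roi, radius_mm = 0)
  expect_equal(res3$rows$posterior[res3$rows$term == "even"], 0.5)
})

test_that("decode_roi is invariant to study and vocabulary order", {
  set.seed(36)
  g <- test_grid(c(6, 6, 6))
  roi <- mask_from_indices(g, 1)
  n <- 100
  active <- runif(n) < 0.4
  terms <- c("b", "a", "c")
  tm <- term_mat(n, terms)
  for (t in terms) tm[runif(n) < 0.4, t] <- 0.01
  db <- toy_db(active, tm, roi, c(6, 6, 6))
  res <- decode_roi(db, roi, radius_mm = 0)
  perm <- sample.int(n)
  db2 <- coordinate_db(db$foci, db$term_freq[perm, c("a", "c", "b")])
  res2 <- decode_roi(db2, roi, radius_mm = 0)
  r1 <- res$rows[order(res$rows$term), ]
  r2 <- res2$rows[order(res2$rows$term), ]
  rownames(r1) <- rownames(r2) <- NULL
  expect_equal(r1, r2)
})

test_that("select_terms ranks, filters and truncates as configured", {
  mk_result <- function(n_sig, n_other = 0) {
    rows <- data.frame(
      term = sprintf("term%03d", seq_len(n_sig + n_other)),
      posterior = seq(0.99, 0.5, length.out = n_sig + n_other),
      significant = rep(c(TRUE, FALSE), c(n_sig, n_other)),
      stringsAsFactors = FALSE)
    structure(list(rows = rows, roi_name = "r", prior = 0.5),
              class = "decoding_result")
  }
  res <- mk_result(100)
  out <- select_terms(res, k = 30, allowlist = res$rows$term)
  expect_length(out, 30)
  expect_equal(out, res$rows$term[1:30])  # highest posteriors, rank order
  # supply below k
  res5 <- mk_result(5)
  expect_length(select_terms(res5, k = 30, allowlist = res5$rows$term), 5)
  # ties break lexicographically
  res_tie <- mk_result(4)
  res_tie$rows$posterior <- 0.9
  res_tie$rows$term <- c("delta", "alpha", "charlie", "bravo")
  expect_equal(select_terms(res_tie, k = 2, allowlist = res_tie$rows$term),
               c("alpha", "bravo"))
  # rank_then_filter can return fewer than k when top ranks are filtered
  res_mix <- mk_result(2, 40)
  res_mix$rows$significant <- rep(c(FALSE, TRUE), c(10, 32))
  rtf <- select_terms(res_mix, k = 10, allowlist = res_mix$rows$term)
  ftr <- select_terms(res_mix, k = 10, allowlist = res_mix$rows$term,
                      order = "filter_then_rank")
  expect_lt(length(rtf), 10)
  expect_length(ftr, 10)
  # empty allowlist skips the filter with a warning
  expect_warning(out2 <- select_terms(res, k = 3), "allowlist")
  expect_length(out2, 3)
})
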