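# A hand-built co-activation fixture: activation indicators are drawn
# explicitly per study and realized as foci at region voxel centres, so
# every conditional probability is under direct control (radius 0).
coact_fixture <- function(seed = 101, n = 1500) {
  g <- volume_grid(c(10, 10, 4))
  labels <- array(0L, g$shape)
  labels[1:4, 1:4, 1] <- 1L
  labels[7:10, 7:10, 1] <- 2L
  parc <- parcellation(g, labels, data.frame(
    label = 1:2, name = c("P1", "P2"), hemisphere = c("L", "R"),
    group = "g"))
  m1 <- array(FALSE, g$shape); m1[1, 10, 3] <- TRUE
  m2 <- array(FALSE, g$shape); m2[10, 1, 3] <- TRUE
  seeds <- list(seed1 = region_mask(g, m1, "seed1"),
                seed2 = region_mask(g, m2, "seed2"))
  set.seed(seed)
  terms <- c("wm", "attention", "calc", "noise1", "noise2")
  tm <- matrix(0, n, length(terms), dimnames = list(NULL, terms))
  for (t in terms) tm[runif(n) < 0.2, t] <- 0.01
  act <- matrix(FALSE, n, 4,
                dimnames = list(NULL, c("seed1", "seed2", "p1", "p2")))
  base <- c(seed1 = 0.15, seed2 = 0.15, p1 = 0.3, p2 = 0.3)
  for (i in seq_len(n)) {
    u <- runif(4)
    a <- u < base  # independent background
    if (tm[i, "wm"] > 0) {          # pair-only: seed1 coupled with p1
      a["seed1"] <- u[1] < base["seed1"]
      a["p1"] <- u[1] < base["p1"]
    }
    if (tm[i, "calc"] > 0) {        # pair-only: seed2 coupled with p1 AND p2
      a["seed2"] <- u[2] < base["seed2"]
      a["p1"] <- u[2] < base["p1"]
      a["p2"] <- u[2] < base["p2"]
    }
    if (tm[i, "attention"] > 0 && runif(1) < 0.8) a["p2"] <- TRUE  # region term
    act[i, ] <- a
  }
  ids <- sprintf("s%04d", seq_len(n))
  rownames(tm) <- ids
  spots <- list(seed1 = c(1, 10, 3), seed2 = c(10, 1, 3),
                p1 = c(2, 2, 1), p2 = c(8, 8, 1))
  rows <- list()
  for (i in seq_len(n)) {
    on <- names(which(act[i, ]))
    if (!length(on)) next
    xyz <- voxel_to_world(g, do.call(rbind, spots[on]))
    rows[[length(rows) + 1L]] <- data.frame(study_id = ids[i],
                                            x = xyz[, 1], y = xyz[, 2],
                                            z = xyz[, 3])
  }
  db <- coordinate_db(do.call(rbind, rows), tm)
  list(grid = g, parc = parc, seeds = seeds, db = db,
       allowlist = c("wm", "attention", "calc", "noise1", "noise2"))
}

test_that("pair_activation composes single-ROI activations", {
  fx <- coact_fixture()
  s <- fx$seeds$seed1
  p <- parcel_mask(fx$parc, 1)
  a_s <- activation_vector(fx$db, s, 0)
  a_p <- activation_vector(fx$db, p, 0)
  both <- pair_activation(fx$db, s, p, 0, mode = "both")
  expect_equal(both$active, a_s$active & a_p$active)  # compositional oracle
  uni <- pair_activation(fx$db, s, p, 0, mode = "union")
  expect_equal(uni$active, a_s$active | a_p$active)
  expect_error(pair_activation(fx$db, s, s, 0), "overlap")
})

test_that("a pair-only term is specific and never in the region list", {
  fx <- coact_fixture()
  pd <- decode_pair(fx$db, fx$seeds$seed1, parcel_mask(fx$parc, 1),
                    radius_mm = 0, allowlist = fx$allowlist)
  expect_true("wm" %in% pd$terms_pair)
  expect_true("wm" %in% pd$terms_specific)
  expect_false("wm" %in% pd$terms_region)
  # the region term is found by the region-alone decoding of its parcel
  pd2 <- decode_pair(fx$db, fx$seeds$seed2, parcel_mask(fx$parc, 2),
                     radius_mm = 0, allowlist = fx$allowlist)
  expect_true("attention" %in% pd2$terms_region)
})

test_that("pair decodings partition into specific and shared", {
  fx <- coact_fixture()
  for (s in names(fx$seeds)) for (l in 1:2) {
    pd <- decode_pair(fx$db, fx$seeds[[s]], parcel_mask(fx$parc, l),
                      radius_mm = 0, allowlist = fx$allowlist)
    expect_setequal(union(pd$terms_specific, pd$terms_shared), pd$terms_pair)
    expect_length(intersect(pd$terms_specific, pd$terms_shared), 0)
  }
})

test_that("systems_decode exactly recovers planted pair associations", {
  fx <- coact_fixture()
  connected <- data.frame(seed = rep(c("seed1", "seed2"), each = 2),
                          label = c(1L, 2L, 1L, 2L))
  sys <- systems_decode(fx$db, fx$seeds, connected, fx$parc, radius_mm = 0,
                        allowlist = fx$allowlist)
  sp <- system_entries(sys)
  got <- split(sp$label, paste(sp$seed, sp$term))
  expect_equal(sort(got[["seed1 wm"]]), 1L)
  expect_equal(sort(got[["seed2 calc"]]), c(1L, 2L))
  expect_false("seed2 wm" %in% names(got))
  expect_false("seed1 calc" %in% names(got))
  # iterating order does not matter
  sys2 <- systems_decode(fx$db, rev(fx$seeds), connected[c(3, 1, 4, 2), ],
                         fx$parc, radius_mm = 0, allowlist = fx$allowlist)
  expect_equal(sys2$entries, sys$entries)
})

test_that("group_into_topics unions region sets per topic", {
  sp <- data.frame(seed = "s1", term = c("a", "b", "b", "c"),
                   label = c(1L, 2L, 3L, 9L), stringsAsFactors = FALSE)
  mapping <- topic_mapping(c(a = 1L, b = 1L, d = 2L),
                           c(`1` = "one", `2` = "two"))
  expect_message(tsm <- group_into_topics(sp, mapping), "c")
  expect_equal(tsm$unmapped, "c")
  expect_equal(tsm$regions$label[tsm$regions$topic_id == 1], c(1L, 2L, 3L))
  expect_false(2L %in% tsm$regions$topic_id)  # topic with no terms absent
  # identity mapping reproduces the system map exactly
  idmap <- topic_mapping(stats::setNames(1:3, c("a", "b", "c")))
  tsm2 <- group_into_topics(sp, idmap)
  back <- tsm2$regions
  back$term <- names(idmap$topic_of)[back$topic_id]
  expect_equal(back[order(back$seed, back$term, back$label),
                    c("seed", "term", "label")],
               sp[order(sp$seed, sp$term, sp$label), ],
               ignore_attr = TRUE)
  # random maps equal a brute-force union oracle
  set.seed(41)
  sp3 <- unique(data.frame(
    seed = sample(c("s1", "s2"), 60, TRUE),
    term = sample(letters[1:6], 60, TRUE),
    label = sample(1:8, 60, TRUE), stringsAsFactors = FALSE))
  map3 <- topic_mapping(stats::setNames(sample(1:2, 6, TRUE), letters[1:6]))
  tsm3 <- group_into_topics(sp3, map3)
  for (i in seq_len(nrow(unique(tsm3$regions[, c("seed", "topic_id")])))) {
    key <- unique(tsm3$regions[, c("seed", "topic_id")])[i, ]
    terms <- names(map3$topic_of)[map3$topic_of == key$topic_id]
    brute <- sort(unique(sp3$label[sp3$seed == key$seed &
                                     sp3$term %in% terms]))
    got <- sort(tsm3$regions$label[tsm3$regions$seed == key$seed &
                                     tsm3$regions$topic_id == key$topic_id])
    expect_equal(got, brute)
  }
})

test_that("seed_contribution counts regions and seed multiplicity", {
  g <- test_grid(c(4, 4, 4))
  labels <- array(0L, g$shape)
  labels[1, 1:4, 1] <- 1:4
  parc <- parcellation(g, labels, data.frame(
    label = 1:4, name = paste0("P", 1:4),
    hemisphere = c("L", "L", "L", "L"), group = "g"))
  tsm <- list(regions = data.frame(
    seed = c("s1", "s1", "s1", "s1", "s2"),
    topic_id = 1L, topic_name = "one",
    label = c(1L, 2L, 3L, 4L, 2L)), terms = NULL, unmapped = character(0))
  class(tsm) <- "topic_surface_map"
  out <- seed_contribution(tsm, parc)
  expect_equal(out$counts$n_regions[out$counts$seed == "s1"], 4L)
  expect_equal(out$multiplicity$n_seeds[out$multiplicity$label == 2], 2L)
  expect_equal(out$multiplicity$n_seeds[out$multiplicity$label == 1], 1L)
})
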