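# build a structure set directly from a hand-made mask
ss_from_mask <- function(mask, spacing = c(0.5, 0.1, 0.1),
                         cfg = mel_config()) {
  build_structure_set(mask, spacing, cfg)
}

test_that("overlap matrices count intersecting supports and conserve volume", {
  d <- c(10, 20, 20)
  mask <- array(FALSE, d)
  mask[3:5, 3:6, 3:6] <- TRUE
  s1 <- ss_from_mask(mask)
  s2 <- ss_from_mask(mask)
  V <- compute_overlap_matrix(s1, s2)
  sup_vol <- sum(s1$support == 1)
  expect_equal(V["1", "1"], sup_vol)
  expect_equal(sum(V[-1, -1]) - V["1", "1"], 0) # no off-diagonal overlap
  # disjoint supports across frames
  mask2 <- array(FALSE, d)
  mask2[7:9, 14:17, 14:17] <- TRUE
  V2 <- compute_overlap_matrix(s1, ss_from_mask(mask2))
  expect_equal(V2["1", "1"], 0)
  expect_error(compute_overlap_matrix(s1, ss_from_mask(array(TRUE, c(2, 2, 2)))),
               "different grids")
})

test_that("overlap matches a brute-force triple-loop count on random masks", {
  for (seed in 1:5) {
    d <- c(10, 14, 14)
    s1 <- ss_from_mask(or_random_mask(d, seed, frac = 0.15))
    s2 <- ss_from_mask(or_random_mask(d, seed + 100, frac = 0.15))
    V <- compute_overlap_matrix(s1, s2)
    Vo <- or_overlap(s1$support, s2$support, s1$n_structures, s2$n_structures)
    expect_equal(unclass(V), Vo, ignore_attr = TRUE)
    # conservation in both directions
    expect_equal(unname(rowSums(V)[-1]),
                 tabulate(s1$support, nbins = s1$n_structures))
    expect_equal(unname(colSums(V)[-1]),
                 tabulate(s2$support, nbins = s2$n_structures))
  }
})

test_that("association lists are dual and reflect positive overlap exactly", {
  set.seed(3)
  for (trial in 1:20) {
    n1 <- sample(1:6, 1); n2 <- sample(1:6, 1)
    V <- matrix(stats::rpois((n1 + 1) * (n2 + 1), 0.8), n1 + 1, n2 + 1,
                dimnames = list(0:n1, 0:n2))
    A <- build_associations(V)
    for (x in seq_len(n1)) for (y in seq_len(n2)) {
      expect_equal(y %in% A$forward[[x]], V[x + 1, y + 1] > 0)
      expect_equal(x %in% A$backward[[y]], y %in% A$forward[[x]])
    }
  }
})

test_that("back-and-forth matching reproduces the two-into-one pattern", {
  # two Frame-1 structures both overlapping one Frame-2 structure:
  # V inner = [5; 3] (2 x 1)
  V <- matrix(c(0L, 0L, 0L, 0L, 5L, 3L), 3, 2,
              dimnames = list(0:2, 0:1))
  A <- build_associations(V)
  expect_equal(A$forward, list(1L, 1L))
  expect_equal(A$backward, list(1:2))
  W <- back_and_forth_matching(A)
  expect_equal(W$W1, list(2L, 1L)) # mutual fusion candidates
  expect_equal(W$W2, list(integer(0))) # nothing to split into
})

test_that("one-to-one associations produce no candidates; W lists stay symmetric", {
  set.seed(11)
  # diagonal overlap
  V <- diag(c(0, 5, 7, 2))
  dimnames(V) <- list(0:3, 0:3)
  W <- back_and_forth_matching(build_associations(V))
  expect_true(all(lengths(W$W1) == 0))
  expect_true(all(lengths(W$W2) == 0))
  # random matrices: symmetry of the pair lists
  for (trial in 1:10) {
    n1 <- sample(2:7, 1); n2 <- sample(2:7, 1)
    V <- matrix(stats::rpois((n1 + 1) * (n2 + 1), 0.5), n1 + 1, n2 + 1)
    W <- back_and_forth_matching(build_associations(V))
    for (a in seq_len(n1)) for (b in W$W1[[a]])
      expect_true(a %in% W$W1[[b]])
    for (a in seq_len(n2)) for (b in W$W2[[a]])
      expect_true(a %in% W$W2[[b]])
  }
})

test_that("overlap percentages are relative shares that sum to 100", {
  V <- matrix(0L, 2, 3, dimnames = list(0:1, 0:2))
  V[2, 2] <- 90L; V[2, 3] <- 10L
  A <- build_associations(V)
  P <- compute_overlap_percentages(V, A)
  expect_equal(P$P1[[1]], c(`1` = 90, `2` = 10))
  expect_equal(P$P2[[1]], c(`1` = 100))
  expect_equal(P$P2[[2]], c(`1` = 100))
})

test_that("pair geometry returns the anisotropic minimum and its midpoint", {
  # two voxels one x-step apart at dx = 0.1 um
  a <- matrix(c(3L, 4L, 5L), 1, dimnames = list(NULL, c("z", "y", "x")))
  b <- matrix(c(3L, 4L, 6L), 1, dimnames = list(NULL, c("z", "y", "x")))
  g <- compute_pair_geometry(a, b, c(0.5, 0.1, 0.1))
  expect_equal(g$d_um, 0.1)
  expect_equal(g$p_vox, c(3, 4, 5.5))
  # identical sets: zero distance
  expect_equal(compute_pair_geometry(a, a, c(0.5, 0.1, 0.1))$d_um, 0)
  expect_error(compute_pair_geometry(a[0, , drop = FALSE], b,
                                     c(0.5, 0.1, 0.1)), "empty")
  # z steps cost 5x more than x steps at this spacing
  b2 <- matrix(c(4L, 4L, 5L), 1)
  expect_equal(compute_pair_geometry(a, b2, c(0.5, 0.1, 0.1))$d_um, 0.5)
})

test_that("pair geometry equals the all-pairs brute-force minimum", {
  set.seed(5)
  spacing <- c(0.5, 0.1, 0.1)
  for (trial in 1:8) {
    a <- cbind(sample(1:10, 20, TRUE), sample(1:15, 20, TRUE),
               sample(1:15, 20, TRUE))
    b <- cbind(sample(1:10, 25, TRUE), sample(1:15, 25, TRUE),
               sample(1:15, 25, TRUE))
    storage.mode(a) <- storage.mode(b) <- "integer"
    g <- compute_pair_geometry(a, b, spacing)
    dd <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(i, j) {
      sqrt(((a[i, 1] - b[j, 1]) * spacing[1])^2 +
             ((a[i, 2] - b[j, 2]) * spacing[2])^2 +
             ((a[i, 3] - b[j, 3]) * spacing[3])^2)
    })
    expect_equal(g$d_um, min(dd))
    # the reported midway point lies on the segment joining a minimising pair
    expect_true(any(abs(dd - min(dd)) < 1e-12))
  }
})

test_that("structures with no forward association depolarise at their centroid", {
  d <- c(10, 20, 20)
  m1 <- array(FALSE, d)
  m1[3:5, 3:6, 3:6] <- TRUE      # persists
  m1[6:8, 12:16, 12:16] <- TRUE  # disappears (5x5x3 box)
  m2 <- array(FALSE, d)
  m2[3:5, 3:6, 3:6] <- TRUE
  s1 <- ss_from_mask(m1); s2 <- ss_from_mask(m2)
  A <- build_associations(compute_overlap_matrix(s1, s2))
  ev <- detect_depolarisation(A, s1, frame_index = 4L)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$event_type, "depolarisation")
  expect_equal(ev$frame_index, 4L)
  # unweighted centre of the vanished box, 0-based
  expect_equal(c(ev$z_vox, ev$y_vox, ev$x_vox), c(6, 13, 13))
  # identical frames: nothing depolarises
  A2 <- build_associations(compute_overlap_matrix(s1, s1))
  expect_equal(nrow(detect_depolarisation(A2, s1)), 0L)
})

test_that("candidate filtering enforces distance, percentage and third-structure rules", {
  d <- c(8, 20, 60)
  spacing <- c(0.5, 0.1, 0.1)
  m1 <- array(FALSE, d)
  m1[4:5, 9:11, 5:10] <- TRUE    # a
  m1[4:5, 9:11, 16:21] <- TRUE   # b: gap 5 vox = 0.5 um from a
  m2 <- array(FALSE, d)
  m2[4:5, 9:11, 5:21] <- TRUE    # merged
  s1 <- ss_from_mask(m1, spacing); s2 <- ss_from_mask(m2, spacing)
  V <- compute_overlap_matrix(s1, s2)
  A <- build_associations(V)
  W <- back_and_forth_matching(A)
  P <- compute_overlap_percentages(V, A)
  ev <- filter_and_classify(W, P, A, s1, s2, mel_config(), distance_um = 1)
  expect_equal(ev$event_type, "fusion")
  expect_equal(ev$labels_frame1, "1;2")
  expect_equal(ev$x_vox, 12) # midway across the 5-voxel gap (0-based)
  # the same pair at double distance is removed
  ev2 <- filter_and_classify(W, P, A, s1, s2, mel_config(),
                             distance_um = 0.25)
  expect_equal(nrow(ev2), 0L)
})

test_that("high/low percentage combinations are ignored", {
  # x overlaps y strongly, b overlaps y only marginally: P high/low
  d <- c(8, 20, 40)
  spacing <- c(0.5, 0.1, 0.1)
  m1 <- array(FALSE, d)
  m1[3:6, 5:14, 5:14] <- TRUE    # a, large
  m1[3:6, 5:14, 17:22] <- TRUE   # b, overlaps both y and a second target
  m2 <- array(FALSE, d)
  m2[3:6, 5:14, 5:18] <- TRUE    # y: covers a and the left sliver of b
  m2[3:6, 5:14, 20:22] <- TRUE   # y2: covers most of b
  s1 <- ss_from_mask(m1, spacing); s2 <- ss_from_mask(m2, spacing)
  V <- compute_overlap_matrix(s1, s2)
  A <- build_associations(V)
  W <- back_and_forth_matching(A)
  P <- compute_overlap_percentages(V, A)
  # sanity: b's share on the common target is low
  expect_lt(P$P1[[2]]["1"], 50)
  expect_gt(P$P1[[1]]["1"], 50)
  ev <- filter_and_classify(W, P, A, s1, s2, mel_config(), distance_um = 5)
  expect_false(any(ev$event_type == "fusion" & ev$labels_frame1 == "1;2"))
})

test_that("identical frames yield no events end to end", {
  sc <- make_event_scene(n_fusion = 1, n_fission = 1, n_depol = 0,
                         dim = c(32, 64, 64), radius = 3, gap = 6,
                         noise = "realistic", seed = 21)
  f <- render_scene(sc, seed = 21)$timelapse$frames[[1]]
  res <- detect_events(f, f)
  expect_equal(nrow(res$events), 0L)
  expect_gt(res$n_structures, 0L)
  expect_equal(res$average_volume_vox * res$n_structures,
               res$total_volume_vox)
})

test_that("a planted fusion is found at the gap midpoint and dualises to fission", {
  sc <- make_event_scene(n_fusion = 1, n_fission = 0, n_depol = 0,
                         dim = c(32, 64, 64), radius = 3, gap = 8,
                         noise = "none", seed = 31)
  r <- render_scene(sc, seed = 31)
  f1 <- r$timelapse$frames[[1]]; f2 <- r$timelapse$frames[[2]]
  fwd <- detect_events(f1, f2)
  expect_equal(fwd$events$event_type, "fusion")
  m <- evaluate_detection(fwd$events, r$truth, tol_vox = 3, sc$spacing)
  expect_equal(m$tp[m$kind == "fusion"], 1L)
  # time reversal: same location, same pair, as a fission
  rev <- detect_events(f2, f1)
  expect_equal(rev$events$event_type, "fission")
  expect_equal(rev$events$labels_frame2, fwd$events$labels_frame1)
  expect_equal(c(rev$events$z_vox, rev$events$y_vox, rev$events$x_vox),
               c(fwd$events$z_vox, fwd$events$y_vox, fwd$events$x_vox),
               tolerance = 1e-9)
})
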