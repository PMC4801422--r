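cal1 <- calibration(px_per_um_xy = 1)

test_that("thinning produces stable one-pixel curves and preserves components", {
  bar <- matrix(FALSE, 20, 40); bar[9:11, 5:35] <- TRUE
  sk <- skeletonize(bar)
  expect_true(all(sk[!bar] == FALSE))                    # subset of input
  expect_identical(sk, skeletonize(sk))                  # thinning-stable
  expect_equal(attr(label_components(sk), "n_labels"), 1L)
  # disc collapses to a tiny cluster
  disc <- matrix(disc_mask(40, 40, 20, 20, 9), 40, 40)
  expect_lte(sum(skeletonize(disc)), 4)
  # two disjoint bars stay two components
  two <- matrix(FALSE, 30, 40)
  two[5:7, 5:35] <- TRUE; two[20:22, 5:35] <- TRUE
  expect_equal(attr(label_components(skeletonize(two)), "n_labels"), 2L)
  expect_equal(sum(skeletonize(matrix(FALSE, 5, 5))), 0)
})

test_that("a straight line yields one branch with step-sum length", {
  m <- matrix(FALSE, 20, 80); m[10, 6:75] <- TRUE       # 70 px, 69 steps
  g <- build_skeleton_graph(m, calibration(), spur_prune_um = 0)
  expect_equal(nrow(g$edges), 1L)
  expect_equal(g$edges$length_um, 69 / 6.932, tolerance = 1e-9)
  sf <- skeleton_features(g)
  expect_equal(sf$n_islands, 1L)
  expect_equal(sf$n_branches, 1L)
  expect_equal(sf$n_branching_points, 0L)
  expect_equal(sf$longest_branch_length_um, sf$total_length_um)
})

## A "Y" drawn in exact axial/diagonal strokes: west arm 30 steps, two
## diagonal arms of 25 steps (sqrt(2) each).
make_y <- function() {
  m <- matrix(FALSE, 80, 80)
  m[40, 10:40] <- TRUE
  for (i in 0:25) { m[40 - i, 40 + i] <- TRUE; m[40 + i, 40 + i] <- TRUE }
  m
}

test_that("a Y gives 3 branches, 1 junction, and exact arm lengths", {
  g <- build_skeleton_graph(make_y(), cal1, spur_prune_um = 0)
  sf <- skeleton_features(g)
  expect_equal(sf$n_branches, 3L)
  expect_equal(sf$n_branching_points, 1L)
  expect_equal(sf$n_islands, 1L)
  expect_equal(sf$total_length_um, 30 + 50 * sqrt(2), tolerance = 1e-9)
  expect_equal(sf$longest_branch_length_um, 50 * sqrt(2), tolerance = 1e-9)
})

test_that("an extra island adds branches and islands but not junctions", {
  m <- make_y(); m[70, 5:9] <- TRUE                     # separate 4-step bar
  sf <- skeleton_features(build_skeleton_graph(m, cal1, spur_prune_um = 0))
  expect_equal(sf$n_islands, 2L)
  expect_equal(sf$n_branches, 4L)
  expect_equal(sf$n_branching_points, 1L)
  expect_equal(sf$total_length_um, 30 + 50 * sqrt(2) + 4, tolerance = 1e-9)
  expect_equal(sf$longest_branch_length_um, 50 * sqrt(2), tolerance = 1e-9)
})

test_that("short terminal spurs are pruned and classification recomputed", {
  m <- make_y()
  m[39, 25] <- TRUE; m[38, 25] <- TRUE                  # 2-px spur off the west arm
  g <- build_skeleton_graph(m, cal1, spur_prune_um = 3)
  sf <- skeleton_features(g)
  expect_equal(sf$n_branches, 3L)
  expect_equal(sf$n_branching_points, 1L)
  # without pruning the spur splits the west arm
  g0 <- build_skeleton_graph(m, cal1, spur_prune_um = 0)
  expect_equal(skeleton_features(g0)$n_branches, 5L)
})

test_that("longest path equals brute-force enumeration, including a cycle", {
  # tree case
  g <- build_skeleton_graph(make_y(), cal1, spur_prune_um = 0)
  ends <- g$nodes$id[g$nodes$kind == "end"]
  ed <- data.frame(from = g$edges$from, to = g$edges$to, w = g$edges$length_um)
  expect_equal(skeleton_features(g)$longest_branch_length_um,
               oracle_longest_path(ed, ends), tolerance = 1e-9)
  # cycle: a rectangle ring with two antennae
  m <- matrix(FALSE, 40, 60)
  m[10, 10:40] <- TRUE; m[30, 10:40] <- TRUE
  m[10:30, 10] <- TRUE; m[10:30, 40] <- TRUE
  m[20, 41:55] <- TRUE                                 # east antenna
  m[5:9, 10] <- TRUE                                   # north antenna
  g2 <- build_skeleton_graph(m, cal1, spur_prune_um = 0)
  ends2 <- g2$nodes$id[g2$nodes$kind == "end"]
  ed2 <- data.frame(from = g2$edges$from, to = g2$edges$to, w = g2$edges$length_um)
  expect_gt(nrow(ed2), 3)                              # ring split + antennae
  expect_equal(skeleton_features(g2)$longest_branch_length_um,
               oracle_longest_path(ed2, ends2), tolerance = 1e-9)
})

test_that("features are invariant under translation and 90-degree rotation", {
  topo <- generate_topology(5, 1, c(160, 160), clearance = 12, seed = 31)
  m <- rasterize_tree(topo$edges, c(160, 160), 3)
  feat <- function(mask) {
    sf <- skeleton_features(build_skeleton_graph(skeletonize(mask), cal1, 3.5))
    c(sf$total_length_um, sf$longest_branch_length_um, sf$n_islands,
      sf$n_branches, sf$n_branching_points)
  }
  base <- feat(m)
  shifted <- matrix(FALSE, 200, 200); shifted[21:180, 31:190] <- m
  expect_equal(feat(shifted), base, tolerance = 1e-9)
  # counts exactly invariant; lengths to the chord-resampling phase
  expect_equal(feat(t(m[nrow(m):1, ])), base, tolerance = 3e-3)  # 90 deg rotation
})

test_that("planted topologies are recovered from rasterized masks", {
  combos <- list(c(1, 1), c(3, 1), c(4, 2), c(5, 1), c(6, 2), c(7, 1), c(8, 2))
  for (i in seq_len(10)) {
    kb <- combos[[(i %% length(combos)) + 1]]
    topo <- generate_topology(kb[1], kb[2], c(192, 192), clearance = 12,
                              seed = 300 + i)
    m <- rasterize_tree(topo$edges, c(192, 192), 2)
    sk <- extend_skeleton_tips(skeletonize(m), m)
    sf <- skeleton_features(build_skeleton_graph(sk, cal1, spur_prune_um = 3.5))
    expect_equal(sf$n_islands, topo$n_islands)
    expect_equal(sf$n_branches, topo$n_branches)
    expect_equal(sf$n_branching_points, topo$n_branching_points)
    expect_lt(abs(sf$total_length_um - topo$total_length_px) /
                topo$total_length_px, 0.05)
  }
})

test_that("empty skeletons give zero features with a flag", {
  g <- build_skeleton_graph(matrix(FALSE, 10, 10), cal1)
  sf <- skeleton_features(g)
  expect_equal(sf$total_length_um, 0)
  expect_equal(sf$n_islands, 0L)
  expect_true("empty_skeleton" %in% sf$flags)
})

test_that("marker kind selects the threshold family for the skeleton stage", {
  set.seed(44)
  roi <- matrix(TRUE, 100, 100)
  img <- matrix(10, 100, 100)
  img[disc_mask(100, 100, 50, 50, 18)] <- 600
  dlg <- segment_for_skeleton(img, roi, "dlg1")
  hrp <- segment_for_skeleton(img, roi, "hrp")
  # Li (dlg1) segments at least as wide as Renyi (hrp)
  expect_gte(sum(dlg), sum(hrp))
  expect_true(any(dlg))
  blank <- segment_for_skeleton(matrix(3, 50, 50), matrix(TRUE, 50, 50), "dlg1")
  expect_true(attr(blank, "no_terminal"))
})
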