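test_that("label matching undoes a cyclic renaming and is the identity
           for identical labelings", {
  L <- toy_labeling(k = 4)
  expect_equal(match_labels(L, L), 1:4)
  perm <- c(2, 3, 4, 1)           # label j renamed to perm[j]
  L2 <- relabel(L, perm)
  got <- match_labels(L, L2)      # got[j2] = L1 label for L2 label j2
  expect_equal(got[perm], 1:4)
  expect_error(match_labels(L, toy_labeling(k = 3)), "different k")
})

test_that("label matching agrees with exhaustive permutation search", {
  set.seed(50)
  for (k in 2:4) {
    for (rep in 1:3) {
      lab1 <- array(sample(0:k, 120, replace = TRUE), c(6, 5, 4))
      lab2 <- array(sample(0:k, 120, replace = TRUE), c(6, 5, 4))
      L1 <- new_labeling(lab1, c(1, 1, 1))
      L2 <- new_labeling(lab2, c(1, 1, 1))
      got <- match_labels(L1, L2)
      best <- exhaustive_match(L1, L2)
      overlap <- function(p) sum(vapply(seq_len(k), function(j)
        sum(L1$labels == p[j] & L2$labels == j), numeric(1)))
      expect_equal(overlap(got), overlap(best))
    }
  }
})

test_that("dice handles the standard limiting cases", {
  A <- array(c(TRUE, TRUE, FALSE, FALSE), c(4, 1, 1))
  B <- array(c(TRUE, FALSE, TRUE, FALSE), c(4, 1, 1))
  expect_equal(dice(A, A), 1)
  expect_equal(dice(A, !A), 0)
  expect_equal(dice(A, B), 0.5)   # |A|=|B|=2, one shared voxel
  expect_equal(dice(A & FALSE, B & FALSE), 0)
  expect_equal(dice(A, B), dice(B, A))
})

test_that("modified Hausdorff matches brute force and its axioms", {
  expect_equal(modified_hausdorff(rbind(c(0, 0, 0)), rbind(c(3, 4, 0))), 5)
  A <- matrix(runif(60), 20, 3)
  expect_equal(modified_hausdorff(A, A), 0)
  set.seed(51)
  for (rep in 1:5) {
    A <- matrix(runif(60, 0, 10), 20, 3)
    B <- matrix(runif(60, 0, 10), 20, 3)
    expect_equal(modified_hausdorff(A, B), brute_mhd(A, B),
                 tolerance = 1e-12)
    expect_equal(modified_hausdorff(A, B), modified_hausdorff(B, A))
  }
  expect_error(modified_hausdorff(A[0, ], A), "empty")
})

test_that("centroid distances see a rigid 1-voxel shift as 2 mm", {
  base <- array(0L, c(8, 8, 4))
  base[1:6, 2:4, 2:3] <- rep(1:3, each = 2)  # three x-blocks, clear of
  L <- new_labeling(base, c(2, 2, 2))        # the +y edge
  expect_equal(centroid_distance(L, L), rep(0, 3))
  shifted <- array(0L, dim(base))
  shifted[, 2:8, ] <- base[, 1:7, ]          # rigid 1-voxel shift along y
  L2 <- new_labeling(shifted, c(2, 2, 2))
  d <- centroid_distance(L, L2, match_labels(L, L2))
  expect_equal(d, rep(2, 3), tolerance = 1e-10)
  # hand-computed toy case: cluster of voxels (1,1,1),(2,1,1) vs (1,1,1)
  a <- array(0L, c(3, 3, 3)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(3, 3, 3)); b[1, 1, 1] <- 1L
  La <- new_labeling(a, c(1, 1, 1)); Lb <- new_labeling(b, c(1, 1, 1))
  expect_equal(centroid_distance(La, Lb, 1L), 0.5)
})

test_that("majority voting is idempotent and breaks ties to the lowest
           label", {
  L <- toy_labeling(k = 3)
  expect_identical(majority_vote_map(list(L))$labels, L$labels)
  expect_identical(majority_vote_map(list(L, L, L))$labels, L$labels)
  # constructed tie: first voxel voted 1 by one input, 2 by the other
  mk <- function(v) new_labeling(array(c(v, 1L, 2L), c(3, 1, 1)),
                                 c(1, 1, 1))
  Ls <- list(mk(1L), mk(2L))
  ids <- list(1:2, 1:2)
  expect_message(out <- majority_vote_map(Ls, ids), "tied")
  expect_equal(out$labels[1, 1, 1], 1L)   # lowest tied label wins
  expect_gte(attr(out, "ties"), 1)
})

test_that("normalized volumes tile the mask and match the generator", {
  ph <- fixture_phantom_clean()
  nv <- normalized_volumes(ph$truth, ph$mask)
  expect_equal(sum(nv), 1, tolerance = 1e-12)
  # oracle: region fractions from dense uniform sampling of the ellipsoid
  set.seed(52)
  n <- 2e5
  u <- matrix(runif(3 * n, -1, 1), ncol = 3)
  u <- u[rowSums(u^2) <= 1, ]
  xyz <- sweep(u, 2, ph$spec$semi_axes, "*")
  ang <- atan2(xyz[, 2], xyz[, 1])
  k <- ph$spec$k_regions
  reg <- pmin(k, 1L + floor((ang + pi) / (2 * pi) * k))
  frac <- tabulate(reg, k) / length(reg)
  expect_lt(max(abs(nv - frac)), 0.02)
  # degenerate cases
  one <- new_labeling(array(as.integer(ph$mask$grid), dim(ph$mask$grid)),
                      ph$mask$voxel_size)
  expect_equal(normalized_volumes(one, ph$mask), 1)
})

test_that("centroid border distances read the distance map at the
           centroid", {
  g <- array(FALSE, c(11, 11, 11))
  idx <- which(array(TRUE, c(11, 11, 11)), arr.ind = TRUE)
  inside <- rowSums(sweep(idx, 2, c(6, 6, 6))^2) <= 4.5^2
  g[idx[inside, ]] <- TRUE
  mask <- volume_mask(g, c(1, 1, 1))
  # one centered cluster: distance about the ball radius
  ball <- new_labeling(array(as.integer(g), dim(g)), c(1, 1, 1))
  d <- centroid_border_distance(ball, mask)
  expect_equal(d, 4.5, tolerance = 1)
  # a single-voxel cluster on the boundary: distance about one voxel
  edge <- array(0L, dim(g)); edge[6, 6, 2] <- 1L
  d2 <- centroid_border_distance(new_labeling(edge, c(1, 1, 1)), mask)
  expect_lt(d2, 1.5)
})

test_that("the Pratt signed-rank test behaves across its regimes", {
  # identical pairs: degenerate, p = 1
  r <- symmetry_test(rep(1, 7), rep(1, 7))
  expect_equal(r$p_value, 1)
  expect_equal(r$n_zero, 7)
  # constant unit shift on n = 10: strongly significant
  r2 <- symmetry_test(1:10 + 1, 1:10)
  expect_lt(r2$p_value, 0.01)
  # with no zeros and no ties it equals the normal-approximation
  # Wilcoxon (oracle: stats::wilcox.test)
  set.seed(53)
  x <- rnorm(12); y <- rnorm(12)
  ours <- symmetry_test(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = FALSE)
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(ours$statistic, unname(ref$statistic))
  # mirrored phantom hemispheres: symmetric by construction
  set.seed(54)
  left <- runif(10, 0.1, 0.2)
  right <- left + rnorm(10, 0, 1e-3)
  expect_gt(symmetry_test(left, right)$p_value, 0.05)
})

test_that("metric reports aggregate matched clusters and export cleanly", {
  L <- toy_labeling(k = 3)
  L2 <- relabel(L, c(3, 1, 2))
  m <- cluster_metrics(L, L2)
  expect_equal(nrow(m), 3)
  expect_equal(m$dice, rep(1, 3))
  expect_equal(m$centroid_distance, rep(0, 3))
  expect_equal(m$modified_hausdorff, rep(0, 3))
  tsv <- tempfile(fileext = ".tsv"); js <- tempfile(fileext = ".json")
  write_metrics(m, tsv, js)
  expect_equal(nrow(utils::read.delim(tsv)), 3)
  expect_equal(jsonlite::read_json(js)$mean_dice, 1)
})
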