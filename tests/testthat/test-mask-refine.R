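test_that("single-voxel mask on a 2 mm grid has border distance 2", {
  g <- array(FALSE, c(5, 5, 5)); g[3, 3, 3] <- TRUE
  bd <- border_distance_map(volume_mask(g, c(2, 2, 2)))
  expect_equal(bd[3, 3, 3], 2)
  expect_equal(bd[1, 1, 1], 0)  # background carries 0
})

test_that("a solid cube peaks at its center and respects anisotropy", {
  g <- array(FALSE, c(9, 9, 9)); g[3:7, 3:7, 3:7] <- TRUE
  bd <- border_distance_map(volume_mask(g, c(1, 1, 1)))
  expect_equal(max(bd), bd[5, 5, 5])
  expect_equal(bd[5, 5, 5], 3)
  # anisotropic voxels: distance along z costs 2.5 mm per step
  bdz <- border_distance_map(volume_mask(g, c(1, 1, 2.5)))
  expect_equal(bdz[5, 5, 5], 3)        # x/y border is nearer
  expect_equal(bdz[3, 5, 5], 1)        # one 1-mm step along x
})

test_that("distance transform matches all-pairs brute force exactly", {
  set.seed(21)
  for (rep in 1:5) {
    g <- array(runif(6^3) < 0.45, c(6, 6, 6))
    if (!any(g) || all(g)) next
    vs <- c(1, 1.5, 2)[sample(3)]
    bd <- border_distance_map(volume_mask(g, vs))
    expect_equal(bd, brute_border_distance(g, vs), tolerance = 1e-12)
  }
})

test_that("refinement applies the printed CSF and FA rules", {
  g <- array(FALSE, c(9, 9, 9)); g[2:8, 2:8, 2:8] <- TRUE
  mask <- volume_mask(g, c(1, 1, 1))
  csf <- array(0, dim(g)); fa <- array(0.3, dim(g))
  csf[4, 4, 4] <- 0.06           # over the 0.05 threshold: removed
  fa[2, 5, 5] <- 0.60            # 1 mm from border, FA > 0.55: removed
  fa[5, 5, 5] <- 0.60            # 4 mm deep: retained
  out <- suppressMessages(refine_mask(mask, csf, fa, refine_config()))
  expect_false(out$grid[4, 4, 4])
  expect_false(out$grid[2, 5, 5])
  expect_true(out$grid[5, 5, 5])
  expect_true(all(out$grid <= mask$grid))  # output is a subset
  # csf exactly at the threshold is removed (keep rule is strict <)
  csf2 <- array(0, dim(g)); csf2[4, 4, 4] <- 0.05
  out2 <- suppressMessages(refine_mask(mask, csf2, fa, refine_config()))
  expect_false(out2$grid[4, 4, 4])
  # the FA rule is boundary-inclusive at exactly border_mm
  fa3 <- array(0, dim(g)); fa3[3, 5, 5] <- 0.60  # exactly 2 mm from border
  out3 <- suppressMessages(refine_mask(mask, array(0, dim(g)), fa3,
                                       refine_config()))
  expect_false(out3$grid[3, 5, 5])
})

test_that("refinement that empties the mask is an error", {
  g <- array(FALSE, c(4, 4, 4)); g[2:3, 2:3, 2:3] <- TRUE
  csf <- array(1, dim(g)); fa <- array(0, dim(g))
  expect_error(
    suppressMessages(refine_mask(volume_mask(g, c(1, 1, 1)), csf, fa)),
    "eliminated")
})

test_that("tightening either threshold never adds voxels", {
  set.seed(22)
  g <- array(FALSE, c(8, 8, 8)); g[2:7, 2:7, 2:7] <- TRUE
  mask <- volume_mask(g, c(1, 1, 1))
  csf <- array(runif(8^3, 0, 0.2), dim(g))
  fa <- array(runif(8^3, 0.3, 0.8), dim(g))
  base <- suppressMessages(refine_mask(mask, csf, fa, refine_config()))
  for (cfg in list(refine_config(csf_max = 0.03),
                   refine_config(fa_max = 0.45),
                   refine_config(csf_max = 0.03, fa_max = 0.45))) {
    tight <- tryCatch(
      suppressMessages(refine_mask(mask, csf, fa, cfg)),
      error = function(e) volume_mask(array(FALSE, dim(g)), c(1, 1, 1)))
    expect_true(all(tight$grid <= base$grid))
  }
})

test_that("refinement is idempotent when the retained tissue stays below
           the FA threshold", {
  g <- array(FALSE, c(10, 10, 10)); g[2:9, 2:9, 2:9] <- TRUE
  mask <- volume_mask(g, c(1, 1, 1))
  set.seed(23)
  csf <- array(0.01, dim(g))
  fa <- array(runif(1000, 0.2, 0.4), dim(g))   # thalamus-like interior
  bd <- border_distance_map(mask)
  fa[g & bd <= 2] <- 0.7                        # capsule-like border zone
  csf[g & bd <= 1 & array(runif(1000), dim(g)) < 0.3] <- 0.5
  once <- suppressMessages(refine_mask(mask, csf, fa))
  twice <- suppressMessages(refine_mask(once, csf, fa))
  expect_identical(twice$grid, once$grid)
})

test_that("phantom rims are removed and the deep interior is untouched", {
  ph <- fixture_phantom()
  fa <- fit_tensor_field(ph$dwi, ph$mask)$fa
  out <- suppressMessages(refine_mask(ph$mask, ph$csf_prob, fa))
  removed <- attr(out, "removed")
  expect_gt(removed["csf"], 0)
  expect_gt(removed["fa"], 0)
  # the injected CSF rim is gone
  rim <- ph$mask$grid & ph$csf_prob > 0.5
  expect_false(any(out$grid & rim))
  # voxels deeper than the rim zones survive
  bd <- border_distance_map(ph$mask)
  deep <- ph$mask$grid & bd > max(ph$spec$csf_rim, ph$spec$capsule_rim)
  expect_true(all(out$grid[deep]))
})
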