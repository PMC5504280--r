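test_that("feature assembly scales the ODF block by s_odf", {
  ph <- fixture_phantom_clean()
  field <- fixture_odf_field()
  f55 <- extract_features(field, ph$mask, test_cfg(s_odf = 55))
  f1 <- extract_features(field, ph$mask, test_cfg(s_odf = 1))
  expect_equal(f55$odf, 55 * f1$odf, tolerance = 1e-12)
  expect_equal(ncol(f55$odf), 28)
  expect_equal(nrow(f55$pos), sum(ph$mask$grid))
  # positions are voxel centers in mm
  expect_equal(f55$pos[1, ],
               as.vector(voxel_to_world(f55$index[1, , drop = FALSE] - 1,
                                        ph$mask$affine)))
})

test_that("scaled ODF distances fall inside the spatial distance range", {
  ph <- fixture_phantom_clean()
  f <- extract_features(fixture_odf_field(), ph$mask, test_cfg())
  set.seed(30)
  s <- sample(nrow(f$pos), 300)
  dpos <- as.vector(stats::dist(f$pos[s, ]))
  dodf <- as.vector(stats::dist(f$odf[s, ]))
  expect_gt(stats::median(dodf), min(dpos))
  expect_lt(stats::median(dodf), max(dpos))
})

test_that("k = 1 initialization is the mean position, and seeding makes
           the init deterministic", {
  ph <- fixture_phantom_clean()
  f <- extract_features(fixture_odf_field(), ph$mask, test_cfg())
  cfg1 <- cluster_config(k = 1, n_init_runs = 10, seed = 3)
  init1 <- init_centroids(f, cfg1)
  expect_equal(init1[1, 1:3], colMeans(f$pos), tolerance = 1e-10,
               ignore_attr = TRUE)
  cfg <- test_cfg()
  expect_identical(init_centroids(f, cfg), init_centroids(f, cfg))
  expect_error(init_centroids(f, cluster_config(k = 1e5, seed = 1)),
               "fewer than k")
})

test_that("averaged initialization finds well-separated blob centers", {
  set.seed(33)
  centers <- as.matrix(expand.grid(c(5, 25), c(5, 25), c(5, 25)))[1:7, ]
  pts <- do.call(rbind, lapply(seq_len(7), function(i)
    sweep(matrix(rnorm(60 * 3, sd = 1), ncol = 3), 2, centers[i, ], "+")))
  f <- structure(list(pos = pts, odf = matrix(0, nrow(pts), 1),
                      index = cbind(seq_len(nrow(pts)), 1L, 1L),
                      grid_dim = c(nrow(pts), 1L, 1L),
                      voxel_size = c(1, 1, 1), affine = diag(4)),
                 class = "feature_matrix")
  cfg <- cluster_config(k = 7, n_init_runs = 30, seed = 4)
  init <- init_centroids(f, cfg)
  d <- sqrt(outer(rowSums(init[, 1:3]^2), rowSums(centers^2), "+") -
              2 * init[, 1:3] %*% t(centers))
  # every blob is covered by exactly one init centroid, each far closer
  # to its blob than to any other (blob spacing is 20)
  nearest <- apply(d, 2, which.min)
  expect_setequal(nearest, 1:7)
  expect_lt(max(apply(d, 2, min)), 5)
  # and k-means started from the averaged init recovers the exact blobs
  lab <- kmeans_combined(f, init, cluster_config(k = 7, alpha = 1,
                                                 seed = 4))
  truth <- rep(1:7, each = 60)
  expect_equal(mclust::adjustedRandIndex(lab$labels[cbind(f$index)],
                                         truth), 1)
})

test_that("alpha = 1 reduces the combined k-means to position-only", {
  ph <- fixture_phantom_clean()
  cfg <- test_cfg(alpha = 1)
  f <- extract_features(fixture_odf_field(), ph$mask, cfg)
  init <- init_centroids(f, cfg)
  lab <- kmeans_combined(f, init, cfg)
  km <- stats::kmeans(f$pos, centers = init[, 1:3], iter.max = 200,
                      algorithm = "Lloyd")
  agree <- mclust::adjustedRandIndex(lab$labels[ph$mask$grid], km$cluster)
  expect_equal(agree, 1)
})

test_that("the combined objective is non-increasing and k = 7 clusters
           are all non-empty on the phantom", {
  ph <- fixture_phantom_clean()
  cfg <- test_cfg()
  f <- extract_features(fixture_odf_field(), ph$mask, cfg)
  lab <- kmeans_combined(f, init_centroids(f, cfg), cfg)
  expect_equal(lab$k, 7)
  expect_true(all(tabulate(lab$labels[lab$labels > 0], 7) > 0))
  expect_true(all(diff(lab$objective) <= 1e-9))
  expect_true(lab$converged)
})

test_that("clustering recovers the phantom regions at SNR 30", {
  ph <- fixture_phantom_clean()
  cfg <- test_cfg()
  f <- extract_features(fixture_odf_field(), ph$mask, cfg)
  lab <- kmeans_combined(f, init_centroids(f, cfg), cfg)
  ari <- mclust::adjustedRandIndex(lab$labels[ph$mask$grid],
                                   ph$truth$labels[ph$mask$grid])
  expect_gte(ari, 0.9)
})

test_that("shuffling voxel order leaves the deterministic labeling
           unchanged", {
  ph <- fixture_phantom_clean()
  cfg <- test_cfg()
  f <- extract_features(fixture_odf_field(), ph$mask, cfg)
  init <- init_centroids(f, cfg)
  lab1 <- kmeans_combined(f, init, cfg)
  set.seed(40)
  p <- sample(nrow(f$pos))
  f2 <- f
  f2$pos <- f$pos[p, ]; f2$odf <- f$odf[p, ]; f2$index <- f$index[p, ]
  lab2 <- kmeans_combined(f2, init, cfg)
  expect_identical(lab1$labels, lab2$labels)
})

test_that("the full pipeline is bit-reproducible under one seed", {
  ph <- fixture_phantom_clean()
  cfg <- cluster_config(n_init_runs = 20, seed = NULL)
  a <- parcellate_dwi(ph$dwi, ph$mask, cfg, n_samples = 10, seed = 9)
  b <- parcellate_dwi(ph$dwi, ph$mask, cfg, n_samples = 10, seed = 9)
  expect_identical(a$labels, b$labels)
})

test_that("configs round-trip through YAML", {
  f <- tempfile(fileext = ".yaml")
  write_config(f, refine_config(csf_max = 0.1),
               cluster_config(k = 5, s_odf = 40, seed = 3))
  got <- read_config(f)
  expect_equal(got$refine$csf_max, 0.1)
  expect_equal(got$refine$fa_max, 0.55)
  expect_equal(got$cluster$k, 5L)
  expect_equal(got$cluster$s_odf, 40)
  expect_equal(got$cluster$alpha, 0.5)
})

test_that("angular difference is antipodally symmetric on [0, pi/2]", {
  expect_equal(angular_difference(c(1, 0, 0), c(1, 0, 0)), 0)
  expect_equal(angular_difference(c(1, 0, 0), c(-1, 0, 0)), 0)
  expect_equal(angular_difference(c(1, 0, 0), c(0, 1, 0)), pi / 2)
  expect_equal(angular_difference(c(1, 1, 0), c(1, 0, 0)), pi / 4)
  expect_error(angular_difference(c(0, 0, 0), c(1, 0, 0)), "zero vector")
})

test_that("the dyadic mean of {+v, -v} is +/- v, where the plain mean
           collapses to zero", {
  v <- c(1, 2, -1) / sqrt(6)
  V <- rbind(v, -v, v, -v)
  m <- thalparc:::dyadic_mean_direction(V)
  expect_equal(abs(sum(m * v)), 1, tolerance = 1e-12)
  expect_equal(colMeans(V), c(0, 0, 0))
})

test_that("AD k-means reduces to spatial k-means when all voxels share
           one direction", {
  ph <- fixture_phantom_clean()
  cfg <- test_cfg()
  f <- extract_features(fixture_odf_field(), ph$mask, cfg)
  e1 <- matrix(rep(c(1, 0, 0), nrow(f$pos)), ncol = 3, byrow = TRUE)
  init <- init_centroids(f, cfg)
  lab_ad <- kmeans_ad(f, e1, init, cfg)
  cfg_pos <- test_cfg(alpha = 1)
  lab_pos <- kmeans_combined(f, init, cfg_pos)
  expect_equal(mclust::adjustedRandIndex(lab_ad$labels[ph$mask$grid],
                                         lab_pos$labels[ph$mask$grid]), 1)
})

test_that("orthogonal direction populations split perfectly at alpha = 0", {
  set.seed(44)
  n <- 200
  pos <- matrix(runif(n * 3, 0, 20), ncol = 3)
  grp <- rep(1:2, each = n / 2)
  e1 <- rbind(matrix(rep(c(1, 0, 0), n / 2), ncol = 3, byrow = TRUE),
              matrix(rep(c(0, 0, 1), n / 2), ncol = 3, byrow = TRUE))
  f <- structure(list(pos = pos, odf = matrix(0, n, 1),
                      index = cbind(seq_len(n), 1L, 1L),
                      grid_dim = c(n, 1L, 1L),
                      voxel_size = c(1, 1, 1), affine = diag(4)),
                 class = "feature_matrix")
  cfg <- cluster_config(k = 2, alpha = 0, n_init_runs = 5, seed = 2)
  init <- cbind(pos[c(1, n), , drop = FALSE])
  lab <- kmeans_ad(f, e1, init, cfg)
  expect_equal(mclust::adjustedRandIndex(lab$labels[cbind(f$index)], grp),
               1)
})
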