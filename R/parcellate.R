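#' Clustering configuration
#'
#' All tunable constants of the combined spatial + ODF k-means and of the
#' angular-difference baseline.
#'
#' @param k Number of clusters (default 7).
#' @param alpha Spatial weight in `[0, 1]`; the ODF (or AD) term gets
#'   `1 - alpha`. Default 0.5 (equal contribution).
#' @param s_odf Scaling factor applied to the ODF SH coefficients so that
#'   ODF distances fall inside the range of the spatial distances
#'   (default 55).
#' @param n_init_runs Number of randomly initialized position-only
#'   k-means runs averaged into the data-driven initialization
#'   (default 5000).
#' @param max_iter Maximum Lloyd iterations (default 200).
#' @param tol Unused by the exact-assignment stopping rule; kept for
#'   forward compatibility.
#' @param seed Optional integer seed controlling the random
#'   initializations.
#' @param ad_scale Scaling factor applied to the angular difference (in
#'   radians) in the baseline (default 6).
#' @param distance_mix `"squared"` combines squared distances
#'   (`alpha d_pos^2 + (1-alpha) d_feat^2`, the form under which Lloyd
#'   centroid updates are exact minimizers); `"linear"` combines
#'   unsquared distances.
#' @return Object of class `cluster_config`.
#' @export
cluster_config <- function(k = 7, alpha = 0.5, s_odf = 55,
                           n_init_runs = 5000, max_iter = 200, tol = 0,
                           seed = NULL, ad_scale = 6,
                           distance_mix = c("squared", "linear")) {
  stopifnot(k >= 1, alpha >= 0, alpha <= 1, s_odf > 0, n_init_runs >= 1,
            max_iter >= 1, ad_scale > 0)
  structure(list(k = as.integer(k), alpha = alpha, s_odf = s_odf,
                 n_init_runs = as.integer(n_init_runs),
                 max_iter = as.integer(max_iter), tol = tol, seed = seed,
                 ad_scale = ad_scale,
                 distance_mix = match.arg(distance_mix)),
            class = "cluster_config")
}

#' Read/write a config YAML holding refinement and clustering constants
#' @param path YAML file path.
#' @return For `read_config`, a list with elements `refine`
#'   ([refine_config()]) and `cluster` ([cluster_config()]).
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  list(refine = do.call(refine_config, y$refine %||% list()),
       cluster = do.call(cluster_config, y$cluster %||% list()))
}

#' @rdname read_config
#' @param refine A [refine_config()].
#' @param cluster A [cluster_config()].
#' @export
write_config <- function(path, refine = refine_config(),
                         cluster = cluster_config()) {
  yaml::write_yaml(list(refine = unclass(refine),
                        cluster = unclass(cluster)), path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assemble the clustering feature matrix
#'
#' One row per in-mask voxel: the voxel-center position in mm followed by
#' the `s_odf`-scaled mean ODF SH coefficients.
#'
#' @param odf_field An [fit_odf_field()] result covering the mask.
#' @param mask A [volume_mask()]; must be a subset of the field's mask.
#' @param cfg A [cluster_config()] (supplies `s_odf`).
#' @return Object of class `feature_matrix`: `pos` (`n x 3`, mm), `odf`
#'   (`n x R`, scaled), `index` (`n x 3` voxel indices), `voxel_size`,
#'   `affine`.
#' @export
extract_features <- function(odf_field, mask, cfg = cluster_config()) {
  if (!identical(dim(mask$grid), dim(odf_field$mask$grid)))
    stop("mask grid does not match the ODF field grid")
  d <- dim(mask$grid)
  want <- which(mask$grid)
  have_lin <- odf_field$index[, 1] + (odf_field$index[, 2] - 1L) * d[1] +
    (odf_field$index[, 3] - 1L) * d[1] * d[2]
  pos_in_field <- match(want, have_lin)
  bad <- want[is.na(pos_in_field)]
  coeffs <- odf_field$coeffs[, pos_in_field[!is.na(pos_in_field)],
                             drop = FALSE]
  if (length(bad) || any(!is.finite(coeffs)))
    stop("missing or non-finite ODF coefficients inside the mask at ",
         "voxel(s) ", paste(utils::head(c(
           bad, want[!is.na(pos_in_field)][!apply(
             is.finite(coeffs), 2, all)]), 10), collapse = ", "))
  idx <- which(mask$grid, arr.ind = TRUE)
  structure(list(pos = voxel_to_world(idx - 1, mask$affine),
                 odf = t(coeffs) * cfg$s_odf,
                 index = idx, grid_dim = dim(mask$grid),
                 voxel_size = mask$voxel_size,
                 affine = mask$affine),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("Feature matrix:", nrow(x$pos), "voxels x (3 +", ncol(x$odf),
      ") features\n")
  invisible(x)
}

#' Data-driven k-means initialization
#'
#' Runs `n_init_runs` randomly initialized position-only k-means on the
#' voxel positions, aligns every run's centroids to those of the
#' lowest-objective run by optimal one-to-one assignment on centroid
#' distance, and averages the aligned centroids slot-wise. Using the best
#' run as the alignment reference (rather than an arbitrary one) makes
#' the average insensitive to which random run happens to come first.
#' The ODF slot of each initial centroid is filled with the mean scaled
#' ODF vector of the voxels in the 26-neighborhood of the voxel
#' containing the averaged spatial centroid (falling back to the nearest
#' voxel when the neighborhood is empty).
#'
#' @param features A feature matrix from [extract_features()].
#' @param cfg A [cluster_config()].
#' @return `k x (3 + R)` matrix of initial full-feature centroids, with
#'   attribute `"spread"` recording the mean within-slot centroid
#'   dispersion across runs.
#' @export
init_centroids <- function(features, cfg = cluster_config()) {
  pos <- features$pos
  k <- cfg$k
  if (nrow(unique(pos)) < k)
    stop("fewer than k distinct positions")
  runs <- vector("list", cfg$n_init_runs)
  objs <- numeric(cfg$n_init_runs)
  with_preserved_seed(cfg$seed, {
    for (r in seq_len(cfg$n_init_runs)) {
      km <- kmeans_retry(pos, k)
      runs[[r]] <- km$centers
      objs[r] <- km$tot.withinss
    }
  })
  ref <- runs[[which.min(objs)]]
  acc <- matrix(0, k, 3)
  sq <- matrix(0, k, 3)
  for (r in seq_len(cfg$n_init_runs)) {
    ctr <- runs[[r]]
    d2 <- outer(rowSums(ref^2), rowSums(ctr^2), "+") - 2 * ref %*% t(ctr)
    perm <- as.integer(clue::solve_LSAP(pmax(d2, 0)))
    acc <- acc + ctr[perm, , drop = FALSE]
    sq <- sq + ctr[perm, , drop = FALSE]^2
  }
  avg <- acc / cfg$n_init_runs
  odf0 <- neighborhood_odf(avg, features)
  out <- cbind(avg, odf0)
  attr(out, "spread") <-
    mean(sqrt(pmax(sq / cfg$n_init_runs - avg^2, 0)))
  out
}

kmeans_retry <- function(pos, k, tries = 5) {
  for (t in seq_len(tries)) {
    km <- tryCatch(stats::kmeans(pos, centers = k, iter.max = 100,
                                 nstart = 1),
                   error = function(e) NULL)
    if (!is.null(km)) return(km)
  }
  stop("position-only k-means failed repeatedly")
}

# mean scaled ODF vector over the 26-neighborhood of each centroid's voxel
neighborhood_odf <- function(centers_mm, features) {
  vox <- world_to_voxel(centers_mm, features$affine) + 1  # 1-based, frac
  out <- matrix(0, nrow(centers_mm), ncol(features$odf))
  for (i in seq_len(nrow(centers_mm))) {
    home <- round(vox[i, ])
    cheb <- apply(abs(sweep(features$index, 2, home)), 1, max)
    sel <- cheb <= 1
    if (!any(sel)) {
      d2 <- rowSums(sweep(features$pos, 2, centers_mm[i, ])^2)
      sel <- which.min(d2)
    }
    out[i, ] <- colMeans(features$odf[sel, , drop = FALSE])
  }
  out
}

#' Combined spatial + ODF k-means
#'
#' Lloyd iterations on the decision metric
#' `d^2(v, C) = alpha d_pos^2(v, C) + (1 - alpha) d_ODF^2(v, C)`,
#' where both terms are Euclidean distances (positions in mm, ODF SH
#' coefficients pre-scaled by `s_odf`). With squared mixing this is plain
#' squared-Euclidean k-means on the concatenated weighted feature vector,
#' so the per-block mean is the exact centroid update. Iteration stops at
#' an assignment fixpoint or `max_iter`. An empty cluster is re-seeded at
#' the point farthest from its assigned centroid. Final labels are
#' deterministic: clusters are renumbered by descending size, ties broken
#' by lexicographic centroid order.
#'
#' @param features A feature matrix from [extract_features()].
#' @param init `k x (3 + R)` initial centroids (see [init_centroids()]).
#' @param cfg A [cluster_config()].
#' @return Object of class `labeling`: `labels` (3-D integer array, 0 =
#'   background), `k`, `centroids` (`k x 3` mm), `feature_centroids`,
#'   `voxel_size`, `affine`, `objective` (per-iteration trace),
#'   `iterations`, `converged`.
#' @export
kmeans_combined <- function(features, init, cfg = cluster_config()) {
  if (nrow(init) != cfg$k)
    stop("init has ", nrow(init), " centroids; cfg$k = ", cfg$k)
  run_lloyd(features, pos = features$pos, feat = features$odf,
            init_pos = init[, 1:3, drop = FALSE],
            init_feat = init[, -(1:3), drop = FALSE],
            cfg = cfg, feat_dist = "euclidean")
}

#' Angular-difference baseline k-means
#'
#' Replaces the ODF distance with the antipodally symmetric angular
#' difference between each voxel's principal diffusion direction and the
#' cluster direction, scaled by `ad_scale`:
#' `d^2(v, C) = alpha d_pos^2 + (1 - alpha) (ad_scale * AD(e1_v, dir_C))^2`.
#' The cluster direction is updated as the principal eigenvector of the
#' mean dyadic (outer-product) tensor of the member vectors, which is the
#' sign-invariant mean direction.
#'
#' @param features A feature matrix from [extract_features()] (its ODF block is ignored) or any
#'   object with `pos`, `index`, `voxel_size`, `affine`.
#' @param e1 `n x 3` unit principal eigenvectors, one per voxel.
#' @param init `k x m` initial centroids; only the first 3 (spatial)
#'   columns are used. Initial directions are the dyadic means of the
#'   26-neighborhood around each initial centroid.
#' @param cfg A [cluster_config()].
#' @return A `labeling` (see [kmeans_combined()]).
#' @export
kmeans_ad <- function(features, e1, init, cfg = cluster_config()) {
  if (nrow(init) != cfg$k)
    stop("init has ", nrow(init), " centroids; cfg$k = ", cfg$k)
  nrm <- sqrt(rowSums(e1^2))
  if (any(nrm == 0)) stop("zero principal eigenvector")
  e1 <- e1 / nrm
  init_pos <- init[, 1:3, drop = FALSE]
  init_dir <- t(vapply(seq_len(cfg$k), function(i) {
    home <- round(world_to_voxel(init_pos[i, , drop = FALSE],
                                 features$affine) + 1)
    cheb <- apply(abs(sweep(features$index, 2, as.vector(home))), 1, max)
    sel <- if (any(cheb <= 1)) which(cheb <= 1) else
      which.min(rowSums(sweep(features$pos, 2, init_pos[i, ])^2))
    dyadic_mean_direction(e1[sel, , drop = FALSE])
  }, numeric(3)))
  run_lloyd(features, pos = features$pos, feat = e1,
            init_pos = init_pos, init_feat = init_dir,
            cfg = cfg, feat_dist = "angular")
}

#' Antipodally symmetric angular difference between diffusion axes
#'
#' `AD(v1, v2) = arccos(|v1 . v2|)`, in radians, in `[0, pi/2]`.
#' Diffusion directions are axes, so `v` and `-v` are identical.
#'
#' @param v1,v2 Unit 3-vectors (renormalized; zero vectors are an error).
#' @return Angle in radians.
#' @export
angular_difference <- function(v1, v2) {
  n1 <- sqrt(sum(v1^2)); n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) stop("zero vector has no direction")
  acos(pmin(1, abs(sum(v1 * v2) / (n1 * n2))))
}

# principal eigenvector of the mean outer-product tensor; sign-invariant
# mean of a set of axes ({+v, -v} averages to +/-v, not 0)
dyadic_mean_direction <- function(V) {
  Td <- crossprod(V) / nrow(V)
  eigen(Td, symmetric = TRUE)$vectors[, 1]
}

# shared Lloyd loop for both feature distances
run_lloyd <- function(features, pos, feat, init_pos, init_feat, cfg,
                      feat_dist) {
  k <- cfg$k
  n <- nrow(pos)
  a <- cfg$alpha
  cpos <- init_pos
  cfeat <- init_feat
  assign_old <- rep(0L, n)
  obj_trace <- numeric(0)
  converged <- FALSE
  pos_sq <- rowSums(pos^2)
  sodf_sq <- if (feat_dist == "euclidean") rowSums(feat^2)
  for (it in seq_len(cfg$max_iter)) {
    d2pos <- pmax(outer(pos_sq, rowSums(cpos^2), "+") - 2 * pos %*% t(cpos),
                  0)
    d2feat <- if (feat_dist == "euclidean") {
      pmax(outer(sodf_sq, rowSums(cfeat^2), "+") - 2 * feat %*% t(cfeat), 0)
    } else {
      ad <- acos(pmin(1, abs(feat %*% t(cfeat))))
      (cfg$ad_scale * ad)^2
    }
    comb <- if (cfg$distance_mix == "squared")
      a * d2pos + (1 - a) * d2feat
    else (a * sqrt(d2pos) + (1 - a) * sqrt(d2feat))^2
    assign_new <- max.col(-comb, ties.method = "first")
    obj_trace <- c(obj_trace, sum(comb[cbind(seq_len(n), assign_new)]))
    if (identical(assign_new, assign_old)) { converged <- TRUE; break }
    assign_old <- assign_new
    for (j in seq_len(k)) {
      mem <- assign_new == j
      if (!any(mem)) {
        far <- which.max(comb[cbind(seq_len(n), assign_new)])
        message("empty cluster ", j, " re-seeded at farthest voxel")
        assign_new[far] <- j
        mem <- assign_new == j
      }
      cpos[j, ] <- colMeans(pos[mem, , drop = FALSE])
      cfeat[j, ] <- if (feat_dist == "euclidean")
        colMeans(feat[mem, , drop = FALSE])
      else dyadic_mean_direction(feat[mem, , drop = FALSE])
    }
  }
  # deterministic relabeling: descending size, ties by centroid order
  sizes <- tabulate(assign_old, k)
  cen <- t(vapply(seq_len(k), function(j)
    colMeans(pos[assign_old == j, , drop = FALSE]), numeric(3)))
  ord <- order(-sizes, cen[, 1], cen[, 2], cen[, 3])
  remap <- integer(k); remap[ord] <- seq_len(k)
  lab_vec <- remap[assign_old]
  labels <- array(0L, features$grid_dim)
  labels[features$index] <- lab_vec
  out <- new_labeling(labels, features$voxel_size, features$affine)
  out$feature_centroids <- cfeat[ord, , drop = FALSE]
  out$objective <- obj_trace
  out$iterations <- length(obj_trace)
  out$converged <- converged
  out
}

#' Construct a labeling from an integer label volume
#' @param labels 3-D integer array (0 = background, 1..k).
#' @param voxel_size Length-3 voxel edges (mm).
#' @param affine 4 x 4 voxel-to-world transform.
#' @return Object of class `labeling` with spatial `centroids` (mm).
#' @export
new_labeling <- function(labels, voxel_size,
                         affine = diag(c(voxel_size, 1))) {
  k <- max(labels)
  centroids <- if (k >= 1)
    t(vapply(seq_len(k), function(j) {
      idx <- which(labels == j, arr.ind = TRUE)
      if (nrow(idx) == 0) rep(NA_real_, 3)
      else colMeans(voxel_to_world(idx - 1, affine))
    }, numeric(3)))
  else matrix(numeric(0), 0, 3)
  structure(list(labels = labels, k = as.integer(k), centroids = centroids,
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "labeling")
}

#' @export
print.labeling <- function(x, ...) {
  cat("Labeling:", x$k, "clusters over", sum(x$labels > 0), "voxels; sizes",
      paste(tabulate(x$labels[x$labels > 0], x$k), collapse = ", "), "\n")
  invisible(x)
}
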