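#' Match cluster labels between two labelings
#'
#' Optimal one-to-one assignment maximizing total voxel overlap on the
#' k x k contingency table (Hungarian algorithm).
#'
#' @param L1,L2 `labeling` objects on the same grid with the same `k`.
#' @return Integer vector `p` of length `k`: `p[j]` is the L1 label
#'   matched to L2 label `j`.
#' @export
match_labels <- function(L1, L2) {
  if (L1$k != L2$k)
    stop("labelings have different k (", L1$k, " vs ", L2$k, ")")
  if (!identical(dim(L1$labels), dim(L2$labels)))
    stop("labelings are on different grids")
  k <- L1$k
  tab <- table(factor(L1$labels[L1$labels > 0 | L2$labels > 0],
                      levels = 0:k),
               factor(L2$labels[L1$labels > 0 | L2$labels > 0],
                      levels = 0:k))[-1, -1, drop = FALSE]
  # maximize overlap: Hungarian on the negated counts
  perm <- as.integer(clue::solve_LSAP(matrix(as.numeric(tab), k, k),
                                      maximum = TRUE))
  # perm[i] = L2 label assigned to L1 label i; invert to L2 -> L1
  inv <- integer(k)
  inv[perm] <- seq_len(k)
  inv
}

#' Dice overlap coefficient
#'
#' `2 |A n B| / (|A| + |B|)`; defined as 0 when both sets are empty.
#'
#' @param A,B Voxel sets: logical arrays of equal shape, or vectors of
#'   linear voxel indices.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(A, B) {
  if (is.logical(A) && is.logical(B)) {
    nA <- sum(A); nB <- sum(B); nAB <- sum(A & B)
  } else {
    nA <- length(A); nB <- length(B); nAB <- length(intersect(A, B))
  }
  if (nA + nB == 0) return(0)
  2 * nAB / (nA + nB)
}

#' Modified Hausdorff distance between point sets
#'
#' Dubuisson-Jain distance: the larger of the two directed mean
#' nearest-neighbor distances,
#' `max(mean_a min_b d(a,b), mean_b min_a d(b,a))`. More robust to
#' outliers than the classical Hausdorff maximum.
#'
#' @param A,B Non-empty `n x 3` matrices of points (mm).
#' @return Distance in mm.
#' @export
modified_hausdorff <- function(A, B) {
  A <- matrix(A, ncol = 3); B <- matrix(B, ncol = 3)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty point set")
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
  d <- sqrt(pmax(d2, 0))
  max(mean(apply(d, 1, min)), mean(apply(d, 2, min)))
}

#' Boundary voxels of a cluster as mm points
#'
#' A voxel belongs to the contour when at least one of its 6-connected
#' neighbors lies outside the cluster (grid edges count as outside).
#'
#' @param labels 3-D integer array.
#' @param label Cluster label to extract.
#' @param affine Voxel-to-world transform.
#' @return `n x 3` matrix of boundary voxel centers in mm.
#' @export
cluster_contour <- function(labels, label, affine) {
  inside <- labels == label
  d <- dim(inside)
  pad <- array(FALSE, d + 2)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- inside
  core <- pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] &
    pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  idx <- which(inside & !core, arr.ind = TRUE)
  voxel_to_world(idx - 1, affine)
}

#' Per-cluster scan-rescan similarity metrics
#'
#' Matches the clusters of two labelings and reports, for every matched
#' pair, the Dice coefficient, the Euclidean distance between the spatial
#' centroids (mm) and the modified Hausdorff distance between the cluster
#' contours (mm).
#'
#' @param L1,L2 `labeling` objects on the same grid.
#' @return A data.frame with one row per cluster (`label1`, `label2`,
#'   `dice`, `centroid_distance`, `modified_hausdorff`) and attribute
#'   `"permutation"`.
#' @export
cluster_metrics <- function(L1, L2) {
  perm <- match_labels(L1, L2)
  k <- L1$k
  rows <- lapply(seq_len(k), function(j2) {
    j1 <- perm[j2]
    data.frame(
      label1 = j1, label2 = j2,
      dice = dice(L1$labels == j1, L2$labels == j2),
      centroid_distance = sqrt(sum((L1$centroids[j1, ] -
                                      L2$centroids[j2, ])^2)),
      modified_hausdorff = modified_hausdorff(
        cluster_contour(L1$labels, j1, L1$affine),
        cluster_contour(L2$labels, j2, L2$affine)))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$label1), ]
  rownames(out) <- NULL
  attr(out, "permutation") <- perm
  out
}

#' Per-cluster centroid distances between two matched labelings
#' @param L1,L2 `labeling` objects.
#' @param perm Permutation from [match_labels()] (`perm[j]` = L1 label for
#'   L2 label `j`).
#' @return Numeric vector (mm), one entry per L1 label.
#' @export
centroid_distance <- function(L1, L2, perm = match_labels(L1, L2)) {
  k <- L1$k
  d <- numeric(k)
  for (j2 in seq_len(k)) {
    j1 <- perm[j2]
    d[j1] <- sqrt(sum((L1$centroids[j1, ] - L2$centroids[j2, ])^2))
  }
  d
}

#' Majority-vote consensus labeling
#'
#' Each voxel takes the label held by the majority of the (pre-aligned)
#' input labelings after permutation alignment to the first input. Ties
#' are broken by the lowest label; the number of tied voxels is reported
#' as an attribute and a message.
#'
#' @param labelings List of `labeling` objects on one grid with equal `k`.
#' @param permutations Optional list of permutations mapping each
#'   labeling's labels to the reference (first) labeling; computed with
#'   [match_labels()] when omitted.
#' @return A `labeling` with attribute `"ties"` (tied voxel count).
#' @export
majority_vote_map <- function(labelings, permutations = NULL) {
  m <- length(labelings)
  if (m == 0) stop("no labelings")
  ref <- labelings[[1]]
  k <- ref$k
  if (is.null(permutations))
    permutations <- lapply(labelings, function(L)
      if (identical(L, ref)) seq_len(k) else match_labels(ref, L))
  d <- dim(ref$labels)
  counts <- array(0L, c(prod(d), k + 1L))
  for (i in seq_len(m)) {
    lab <- labelings[[i]]$labels
    aligned <- array(0L, d)
    pos <- lab > 0
    aligned[pos] <- permutations[[i]][lab[pos]]
    counts[cbind(seq_len(prod(d)), as.vector(aligned) + 1L)] <-
      counts[cbind(seq_len(prod(d)), as.vector(aligned) + 1L)] + 1L
  }
  best <- max.col(counts, ties.method = "first") - 1L
  top <- counts[cbind(seq_len(prod(d)), best + 1L)]
  n_tied <- sum(rowSums(counts == top) > 1 & top > 0)
  if (n_tied > 0)
    message("majority_vote_map: ", n_tied, " tied voxels broken to the ",
            "lowest label")
  out <- new_labeling(array(best, d), ref$voxel_size, ref$affine)
  attr(out, "ties") <- n_tied
  out
}

#' Cluster volumes normalized by the thalamus size
#' @param L A `labeling`.
#' @param mask The thalamus [volume_mask()] used for normalization.
#' @return Numeric vector: per-cluster voxel count / mask voxel count.
#' @export
normalized_volumes <- function(L, mask) {
  n <- sum(mask$grid)
  if (n == 0) stop("empty mask")
  tabulate(L$labels[L$labels > 0], L$k) / n
}

#' Distance of cluster centroids to the thalamus border
#'
#' Evaluates the mask border-distance map at each cluster's (generally
#' non-integer) centroid by trilinear interpolation; the map is 0 outside
#' the mask, so centroids at the border score about 0.
#'
#' @param L A `labeling`.
#' @param mask The thalamus [volume_mask()].
#' @return Numeric vector of distances in mm, one per cluster.
#' @export
centroid_border_distance <- function(L, mask) {
  bd <- border_distance_map(mask)
  vapply(seq_len(L$k), function(j)
    trilinear_at(bd, world_to_voxel(L$centroids[j, , drop = FALSE],
                                    mask$affine) + 1),
    numeric(1))
}

# trilinear interpolation at a 1-based (fractional) voxel coordinate
trilinear_at <- function(vol, p) {
  p <- as.numeric(p)
  d <- dim(vol)
  p <- pmin(pmax(p, 1), d)
  f <- pmin(floor(p), d - 1)
  f <- pmax(f, 1)
  w <- p - f
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- prod(ifelse(c(dx, dy, dz) == 1, w, 1 - w))
    if (wt > 0)
      acc <- acc + wt * vol[f[1] + dx, f[2] + dy, f[3] + dz]
  }
  acc
}

#' Wilcoxon signed-rank test with Pratt zero handling
#'
#' Two-sided paired signed-rank test for hemispheric symmetry of
#' per-cluster values (normalized volumes or centroid border distances).
#' Zero differences are ranked with the rest and then discarded from the
#' statistic (Pratt method); the null distribution uses the normal
#' approximation with zero and tie corrections. When every difference is
#' zero the test is degenerate and `p = 1` is returned.
#'
#' @param left_values,right_values Paired numeric vectors (n >= 5).
#' @return List with `statistic` (V, sum of positive ranks), `p_value`,
#'   `n`, `n_zero`.
#' @export
symmetry_test <- function(left_values, right_values) {
  if (length(left_values) != length(right_values))
    stop("paired samples must have equal length")
  n <- length(left_values)
  if (n < 5) stop("need at least 5 pairs")
  d <- left_values - right_values
  r <- rank(abs(d))
  zero <- d == 0
  n0 <- sum(zero)
  V <- sum(r[d > 0])
  if (n0 == n)
    return(list(statistic = 0, p_value = 1, n = n, n_zero = n0))
  mu <- n * (n + 1) / 4 - n0 * (n0 + 1) / 4
  sig2 <- (n * (n + 1) * (2 * n + 1) - n0 * (n0 + 1) * (2 * n0 + 1)) / 24
  ties <- table(r[!zero])
  sig2 <- sig2 - sum(ties^3 - ties) / 48
  if (sig2 <= 0)
    return(list(statistic = V, p_value = 1, n = n, n_zero = n0))
  z <- (V - mu) / sqrt(sig2)
  p <- min(1, 2 * stats::pnorm(-abs(z)))
  list(statistic = V, p_value = p, n = n, n_zero = n0)
}

#' Write per-cluster metrics as TSV and a JSON summary
#' @param metrics Data.frame from [cluster_metrics()].
#' @param tsv_path,json_path Output paths (either may be NULL).
#' @return Invisibly, `metrics`.
#' @export
write_metrics <- function(metrics, tsv_path = NULL, json_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(metrics, tsv_path, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(
      list(mean_dice = mean(metrics$dice),
           mean_centroid_distance = mean(metrics$centroid_distance),
           mean_modified_hausdorff = mean(metrics$modified_hausdorff),
           per_cluster = metrics),
      json_path, auto_unbox = TRUE, digits = NA)
  invisible(metrics)
}
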