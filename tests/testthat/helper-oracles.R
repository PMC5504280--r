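# Independent oracles used to freeze expected values. These deliberately
# use brute-force or quadrature formulations, not the package's code paths.

# numerical constant-solid-angle ODF: analytic Laplace-Beltrami filtering
# (diagonal, eigenvalue -l(l+1)) followed by great-circle quadrature of
# the Funk-Radon transform
oracle_csa_odf <- function(loglog_coeffs, lmax, eval_dirs, n_circle = 256) {
  orders <- unlist(lapply(seq(0, lmax, by = 2), function(l)
    rep(l, 2 * l + 1)))
  c_lb <- -orders * (orders + 1) * loglog_coeffs
  # great-circle points perpendicular to each evaluation direction
  t_ang <- seq(0, 2 * pi, length.out = n_circle + 1)[seq_len(n_circle)]
  pts <- matrix(0, nrow(eval_dirs) * n_circle, 3)
  for (i in seq_len(nrow(eval_dirs))) {
    u <- eval_dirs[i, ]
    a <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    e1 <- a - sum(a * u) * u; e1 <- e1 / sqrt(sum(e1^2))
    e2 <- c(u[2] * e1[3] - u[3] * e1[2],
            u[3] * e1[1] - u[1] * e1[3],
            u[1] * e1[2] - u[2] * e1[1])
    pts[(i - 1) * n_circle + seq_len(n_circle), ] <-
      outer(cos(t_ang), e1) + outer(sin(t_ang), e2)
  }
  g <- sh_eval(c_lb, sh_basis(lmax, pts))
  frt <- rowMeans(matrix(g, nrow(eval_dirs), n_circle, byrow = TRUE)) *
    2 * pi
  1 / (4 * pi) + frt / (16 * pi^2)
}

# all-pairs distance transform: for each in-mask voxel, min distance to
# any out-of-mask voxel center (anisotropic voxels)
brute_border_distance <- function(grid, voxel_size) {
  idx_in <- which(grid, arr.ind = TRUE)
  idx_out <- which(!grid, arr.ind = TRUE)
  out <- array(0, dim(grid))
  pin <- sweep(idx_in - 1, 2, voxel_size, "*")
  pout <- sweep(idx_out - 1, 2, voxel_size, "*")
  for (i in seq_len(nrow(pin))) {
    d2 <- rowSums(sweep(pout, 2, pin[i, ])^2)
    out[idx_in[i, , drop = FALSE]] <- sqrt(min(d2))
  }
  out
}

# explicit double-loop modified Hausdorff
brute_mhd <- function(A, B) {
  dmin_a <- vapply(seq_len(nrow(A)), function(i)
    min(vapply(seq_len(nrow(B)), function(j)
      sqrt(sum((A[i, ] - B[j, ])^2)), numeric(1))), numeric(1))
  dmin_b <- vapply(seq_len(nrow(B)), function(j)
    min(vapply(seq_len(nrow(A)), function(i)
      sqrt(sum((A[i, ] - B[j, ])^2)), numeric(1))), numeric(1))
  max(mean(dmin_a), mean(dmin_b))
}

# exhaustive search over all k! label permutations, maximizing overlap
exhaustive_match <- function(L1, L2) {
  k <- L1$k
  perms <- pracma::perms(seq_len(k))
  best <- -Inf; best_p <- NULL
  for (r in seq_len(nrow(perms))) {
    p <- perms[r, ]  # p[j] = L1 label for L2 label j
    ov <- sum(vapply(seq_len(k), function(j)
      sum(L1$labels == p[j] & L2$labels == j), numeric(1)))
    if (ov > best) { best <- ov; best_p <- p }
  }
  best_p
}

# rotation matrix about an arbitrary axis
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

# signal of a single diffusion tensor at the scheme's weighted directions
tensor_signal <- function(scheme, D, s0 = 100) {
  g <- scheme$bvecs[!scheme$b0, , drop = FALSE]
  b <- scheme$bvals[!scheme$b0]
  s0 * exp(-b * rowSums((g %*% D) * g))
}

random_spd_tensor <- function(scale = 1e-3) {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A)
  S / max(eigen(S)$values) * scale
}
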