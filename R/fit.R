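#' Fit the double-log signal in the SH basis
#'
#' Solves the linear least-squares problem
#' `ln(-ln S(u)/S(0)) = sum_j c_j Y_j(u)` for the SH coefficients `c_j`,
#' optionally with Laplace-Beltrami ridge regularization
#' (penalty `lambda * (l(l+1))^2` per coefficient). The signal ratio
#' `S/S0` is clipped to `[delta_clip, 1 - delta_clip]` before the double
#' log, as the estimator requires `0 < S/S0 < 1`.
#'
#' @param signal Per-direction signal values: a vector (one voxel) or an
#'   `n_dir x n_vox` matrix, rows matching the rows of `basis$design`.
#' @param s0 Unweighted signal, scalar or length `n_vox`; must be > 0.
#' @param basis [sh_basis()] evaluated at the diffusion-weighted
#'   directions.
#' @param lambda_reg Laplace-Beltrami regularization weight (default
#'   0.006, standard for order-6 fits with 64 directions; 0 allowed when
#'   the system is overdetermined).
#' @param delta_clip Two-sided clipping bound on `S/S0` (default 1e-3).
#' @return An [sh_coeffs()] in the `"loglog_signal"` domain (matrix of
#'   one column per voxel when `signal` is a matrix).
#' @export
fit_loglog_sh <- function(signal, s0, basis, lambda_reg = 0.006,
                          delta_clip = 1e-3) {
  y <- loglog_signal(signal, s0, delta_clip)
  one <- !is.matrix(signal)
  if (is.null(dim(y))) y <- cbind(y)
  if (nrow(y) != nrow(basis$design))
    stop("signal has ", nrow(y), " directions; basis expects ",
         nrow(basis$design))
  M <- loglog_solver(basis, lambda_reg)
  coeffs <- M %*% y
  sh_coeffs(if (one) drop(coeffs) else coeffs, basis$lmax, "loglog_signal")
}

loglog_signal <- function(signal, s0, delta_clip) {
  if (any(s0 <= 0)) stop("s0 must be strictly positive")
  ratio <- if (is.matrix(signal)) sweep(signal, 2, s0, "/") else signal / s0
  ratio <- pmin(pmax(ratio, delta_clip), 1 - delta_clip)
  log(-log(ratio))
}

# normal-equation solve matrix (R x n_dir) for the regularized fit
loglog_solver <- function(basis, lambda_reg) {
  B <- basis$design
  if (lambda_reg == 0 && nrow(B) < basis$R)
    stop("underdetermined fit: ", nrow(B), " directions for ", basis$R,
         " coefficients and no regularization")
  L <- (basis$orders * (basis$orders + 1))^2
  solve(crossprod(B) + lambda_reg * diag(L, basis$R), t(B))
}

#' Residual-bootstrap mean CSA ODF
#'
#' Fits the double-log signal once, resamples the per-direction fit
#' residuals with replacement, refits `n_samples` times, applies the CSA
#' transform to every replicate and returns the coefficient-wise mean ODF
#' — the per-voxel input to the clustering stage.
#'
#' @inheritParams fit_loglog_sh
#' @param transform A [csa_transform()] matching `basis`.
#' @param n_samples Number of bootstrap replicates (default 50).
#' @param seed Optional integer seed; the same seed reproduces the result
#'   exactly. The caller's RNG state is left untouched.
#' @param return_samples Also return the `R x n_vox x n_samples` replicate
#'   array (for diagnostics).
#' @return An [sh_coeffs()] in the `"odf"` domain; with
#'   `return_samples = TRUE`, a list `(mean, samples)`.
#' @export
bootstrap_mean_odf <- function(signal, s0, basis, transform,
                               n_samples = 50, seed = NULL,
                               lambda_reg = 0.006, delta_clip = 1e-3,
                               return_samples = FALSE) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  one <- !is.matrix(signal)
  y <- loglog_signal(if (one) cbind(signal) else signal, s0, delta_clip)
  M <- loglog_solver(basis, lambda_reg)
  B <- basis$design
  C <- M %*% y
  yhat <- B %*% C
  res <- y - yhat
  nd <- nrow(y); nv <- ncol(y)
  mult <- transform$multipliers
  mult[transform$orders == 0] <- 0
  acc <- matrix(0, basis$R, nv)
  samples <- if (return_samples) array(NA_real_, c(basis$R, nv, n_samples))
  with_preserved_seed(seed, {
    for (s in seq_len(n_samples)) {
      idx <- sample.int(nd, nd * nv, replace = TRUE) +
        rep((seq_len(nv) - 1L) * nd, each = nd)
      ystar <- yhat + matrix(res[idx], nd, nv)
      cs <- (M %*% ystar) * mult
      cs[transform$orders == 0, ] <- transform$c0
      acc <- acc + cs
      if (return_samples) samples[, , s] <- cs
    }
  })
  mean_odf <- sh_coeffs(if (one) drop(acc / n_samples) else acc / n_samples,
                        basis$lmax, "odf")
  if (return_samples) list(mean = mean_odf, samples = samples) else mean_odf
}

# evaluate expr with a locally set seed, restoring the caller's RNG state
with_preserved_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv())
    on.exit({
      if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

#' Log-linear diffusion tensor fit
#'
#' Fits `ln(S/S0) = -b g' D g` by least squares, eigendecomposes `D`,
#' clamps negative eigenvalues at zero and computes fractional anisotropy
#' from the clamped eigenvalues.
#'
#' @param signal Per-volume signal values for one voxel (length of the
#'   full scheme, or of its diffusion-weighted subset).
#' @param s0 Unweighted signal, > 0.
#' @param scheme A [gradient_scheme()].
#' @param delta_clip Lower clipping bound on `S/S0` (default 1e-6).
#' @return Object of class `tensor_fit`: `D` (3 x 3, mm^2/s),
#'   `eigenvalues` (descending), `e1` (unit principal eigenvector), `fa`,
#'   and `clamped` (TRUE when a negative eigenvalue was clamped).
#' @export
fit_tensor <- function(signal, s0, scheme, delta_clip = 1e-6) {
  dw <- !scheme$b0
  sig <- if (length(signal) == length(scheme$bvals)) signal[dw] else signal
  if (length(sig) != sum(dw))
    stop("signal length matches neither the scheme nor its weighted subset")
  G <- tensor_design(scheme)
  if (qr(G)$rank < 6)
    stop("rank-deficient tensor design: need >= 6 non-collinear directions")
  d <- solve(crossprod(G), crossprod(G, -log(pmax(sig / s0, delta_clip))))
  tensor_fit_from_d(drop(d))
}

tensor_design <- function(scheme) {
  g <- scheme$bvecs[!scheme$b0, , drop = FALSE]
  b <- scheme$bvals[!scheme$b0]
  b * cbind(g[, 1]^2, g[, 2]^2, g[, 3]^2,
            2 * g[, 1] * g[, 2], 2 * g[, 1] * g[, 3], 2 * g[, 2] * g[, 3])
}

tensor_fit_from_d <- function(d) {
  D <- matrix(c(d[1], d[4], d[5],
                d[4], d[2], d[6],
                d[5], d[6], d[3]), 3, 3)
  e <- eigen(D, symmetric = TRUE)
  ev <- e$values
  clamped <- any(ev < 0)
  ev <- pmax(ev, 0)
  structure(list(D = D, eigenvalues = ev, e1 = e$vectors[, 1],
                 fa = fa_from_eigenvalues(ev), clamped = clamped),
            class = "tensor_fit")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' Normalized eigenvalue variance:
#' `FA = sqrt(3/2 * sum((lambda - mean)^2) / sum(lambda^2))`,
#' 0 for an isotropic tensor and 1 in the single-stick limit.
#'
#' @param ev Numeric vector of 3 (non-negative) eigenvalues.
#' @return FA in `[0, 1]`.
#' @export
fa_from_eigenvalues <- function(ev) {
  ss <- sum(ev^2)
  if (ss == 0) return(0)
  min(1, sqrt(1.5 * sum((ev - mean(ev))^2) / ss))
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat("Tensor fit: eigenvalues", paste(signif(x$eigenvalues, 4),
      collapse = ", "), "mm^2/s, FA =", round(x$fa, 4), "\n")
  invisible(x)
}

#' Voxel-wise tensor metrics over a mask
#'
#' Vectorized log-linear tensor fit for every in-mask voxel; returns FA
#' and principal-eigenvector maps (used for mask refinement and for the
#' angular-difference baseline features).
#'
#' @param dwi A [dwi_volume()].
#' @param mask A [volume_mask()] on the same grid.
#' @param delta_clip Lower clipping bound on `S/S0`.
#' @return List with `fa` (3-D array, NA outside the mask), `e1`
#'   (`n_vox x 3` unit vectors), `eigenvalues` (`n_vox x 3`), `index`
#'   (in-mask voxel indices, 1-based) and `n_clamped`.
#' @export
fit_tensor_field <- function(dwi, mask, delta_clip = 1e-6) {
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  sig <- dwi_signal_matrix(dwi, idx)
  s0 <- dwi$s0[idx]
  if (any(s0 <= 0)) stop("s0 must be strictly positive inside the mask")
  G <- tensor_design(dwi$scheme)
  Y <- -log(pmax(sweep(sig, 2, s0, "/"), delta_clip))
  Dhat <- solve(crossprod(G), crossprod(G, Y))  # 6 x n_vox
  n <- ncol(Dhat)
  fa_vals <- numeric(n)
  e1 <- matrix(0, n, 3)
  evs <- matrix(0, n, 3)
  n_clamped <- 0L
  for (i in seq_len(n)) {
    tf <- tensor_fit_from_d(Dhat[, i])
    fa_vals[i] <- tf$fa
    e1[i, ] <- tf$e1
    evs[i, ] <- tf$eigenvalues
    n_clamped <- n_clamped + tf$clamped
  }
  fa <- array(NA_real_, dim(mask$grid))
  fa[idx] <- fa_vals
  list(fa = fa, e1 = e1, eigenvalues = evs, index = idx,
       n_clamped = n_clamped)
}

# n_dir x n_vox matrix of diffusion-weighted signal at given voxel indices
dwi_signal_matrix <- function(dwi, idx) {
  d <- dim(dwi$data)
  flat <- matrix(dwi$data, prod(d[1:3]), d[4])
  lin <- idx[, 1] + (idx[, 2] - 1L) * d[1] + (idx[, 3] - 1L) * d[1] * d[2]
  t(flat[lin, !dwi$scheme$b0, drop = FALSE])
}

#' Bootstrap-mean ODF field over a mask
#'
#' Runs the full per-voxel ODF reconstruction — order-`lmax` double-log
#' SH fit, residual bootstrap, CSA transform, replicate mean — for every
#' in-mask voxel.
#'
#' @param dwi A [dwi_volume()].
#' @param mask A [volume_mask()] on the same grid.
#' @param lmax Maximum SH order (default 6 giving 28 coefficients).
#' @param n_samples Bootstrap replicates (default 50).
#' @param seed Optional seed for the bootstrap resampling.
#' @param lambda_reg,delta_clip Passed to [fit_loglog_sh()].
#' @return Object of class `odf_field`: `coeffs` (`R x n_vox`, `"odf"`
#'   domain), `lmax`, `index` (in-mask voxel indices), `mask`,
#'   `n_samples`, `seed`.
#' @export
fit_odf_field <- function(dwi, mask, lmax = 6, n_samples = 50, seed = NULL,
                          lambda_reg = 0.006, delta_clip = 1e-3) {
  idx <- which(mask$grid, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  sig <- dwi_signal_matrix(dwi, idx)
  s0 <- dwi$s0[idx]
  if (any(s0 <= 0)) stop("s0 must be strictly positive inside the mask")
  basis <- sh_basis(lmax, dwi$scheme$bvecs[!dwi$scheme$b0, , drop = FALSE])
  tr <- csa_transform(lmax)
  mean_odf <- bootstrap_mean_odf(sig, s0, basis, tr, n_samples = n_samples,
                                 seed = seed, lambda_reg = lambda_reg,
                                 delta_clip = delta_clip)
  structure(list(coeffs = mean_odf$coeffs, lmax = lmax, index = idx,
                 mask = mask, n_samples = n_samples, seed = seed),
            class = "odf_field")
}

#' @export
print.odf_field <- function(x, ...) {
  cat("ODF field: lmax =", x$lmax, ",", ncol(x$coeffs), "voxels,",
      x$n_samples, "bootstrap samples\n")
  invisible(x)
}

#' Write an ODF field as 4-D NIfTI plus JSON sidecar
#'
#' The coefficient index runs along the 4th dimension; the sidecar
#' records the SH order, basis convention, normalization and seed.
#'
#' @param field An [fit_odf_field()] result.
#' @param path Output NIfTI path; the sidecar is written next to it with
#'   extension `.json`.
#' @return Invisibly, `path`.
#' @export
write_odf_field <- function(field, path) {
  d <- dim(field$mask$grid)
  R <- nrow(field$coeffs)
  arr <- array(0, c(d, R))
  lin <- field$index[, 1] + (field$index[, 2] - 1L) * d[1] +
    (field$index[, 3] - 1L) * d[1] * d[2]
  for (j in seq_len(R)) {
    vol <- array(0, d)
    vol[lin] <- field$coeffs[j, ]
    arr[, , , j] <- vol
  }
  RNifti::writeNifti(nifti_with_affine(arr, field$mask$voxel_size,
                                       field$mask$affine), path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(lmax = field$lmax,
         convention = "real symmetric SH, l ascending, m ascending",
         normalization = "ODF integrates to 1 over the sphere",
         n_samples = field$n_samples,
         seed = field$seed),
    sidecar, auto_unbox = TRUE, null = "null")
  invisible(path)
}
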