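#' Diffusion-weighted volume
#'
#' Container for a 4-D diffusion-weighted dataset: the signal grid
#' `S(u)`, the mean unweighted image `S(0)` and the voxel geometry.
#'
#' @param data 4-D numeric array (x, y, z, volume).
#' @param scheme [gradient_scheme()] matching the 4th dimension.
#' @param voxel_size Length-3 numeric, voxel edges in mm.
#' @param affine 4 x 4 voxel-to-world transform (0-based voxel indices to
#'   mm). Defaults to a scaling by `voxel_size`.
#' @return Object of class `dwi_volume` with elements `data`, `s0`
#'   (mean of the b=0 volumes), `scheme`, `voxel_size`, `affine`.
#' @export
dwi_volume <- function(data, scheme, voxel_size,
                       affine = diag(c(voxel_size, 1))) {
  if (length(dim(data)) != 4)
    stop("data must be a 4-D array")
  if (dim(data)[4] != length(scheme$bvals))
    stop("image has ", dim(data)[4], " volumes but the gradient scheme ",
         "describes ", length(scheme$bvals))
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3 || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (mm)")
  b0_idx <- which(scheme$b0)
  s0 <- apply(data[, , , b0_idx, drop = FALSE], 1:3, mean)
  structure(list(data = data, s0 = s0, scheme = scheme,
                 voxel_size = voxel_size, affine = affine),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat("DWI volume:", paste(d[1:3], collapse = " x "), "voxels,",
      d[4], "volumes, voxel", paste(x$voxel_size, collapse = " x "), "mm\n")
  invisible(x)
}

#' Read a 4-D DWI dataset with its gradient scheme
#'
#' Reads a NIfTI-1 image together with FSL-dialect bvals/bvecs files,
#' renormalizes gradient directions and computes the mean b=0 image.
#'
#' @param dwi_path Path to the 4-D NIfTI image.
#' @param bvals_path,bvecs_path Paths to the gradient table files.
#' @param b0_threshold b-values below this count as b = 0 (s/mm^2).
#' @return A [dwi_volume()].
#' @export
read_dwi <- function(dwi_path, bvals_path, bvecs_path, b0_threshold = 50) {
  img <- RNifti::readNifti(dwi_path)
  arr <- as.array(img)
  if (length(dim(arr)) != 4)
    stop("expected a 4-D image, got ", length(dim(arr)), "-D")
  scheme <- read_gradient_scheme(bvals_path, bvecs_path, b0_threshold)
  if (dim(arr)[4] != length(scheme$bvals))
    stop("image has ", dim(arr)[4], " volumes but the gradient scheme ",
         "describes ", length(scheme$bvals))
  dwi_volume(arr, scheme,
             voxel_size = RNifti::pixdim(img)[1:3],
             affine = unclass_affine(RNifti::xform(img)))
}

unclass_affine <- function(a) {
  a <- unclass(a)
  attributes(a) <- list(dim = c(4L, 4L))
  a
}

nifti_with_affine <- function(arr, voxel_size, affine) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(voxel_size,
                           rep(1, max(0, length(dim(arr)) - 3L)))
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::qform(img) <- structure(affine, code = 2L)
  img
}

#' Write a DWI volume (with bvals/bvecs) to disk
#' @param dwi A [dwi_volume()].
#' @param dwi_path Output NIfTI path (.nii or .nii.gz).
#' @param bvals_path,bvecs_path Optional gradient table output paths.
#' @return Invisibly, `dwi_path`.
#' @export
write_dwi <- function(dwi, dwi_path, bvals_path = NULL, bvecs_path = NULL) {
  RNifti::writeNifti(nifti_with_affine(dwi$data, dwi$voxel_size, dwi$affine),
                     dwi_path)
  if (!is.null(bvals_path))
    write_gradient_scheme(dwi$scheme, bvals_path, bvecs_path)
  invisible(dwi_path)
}

#' Binary volume mask
#' @param grid 3-D logical (or 0/1) array.
#' @param voxel_size Length-3 voxel edges in mm.
#' @param affine 4 x 4 voxel-to-world transform.
#' @return Object of class `volume_mask`.
#' @export
volume_mask <- function(grid, voxel_size, affine = diag(c(voxel_size, 1))) {
  if (length(dim(grid)) != 3) stop("mask grid must be 3-D")
  structure(list(grid = array(as.logical(grid), dim(grid)),
                 voxel_size = as.numeric(voxel_size), affine = affine),
            class = "volume_mask")
}

#' Read a binary mask from NIfTI
#' @param path NIfTI path; non-zero voxels are in-mask.
#' @return A [volume_mask()].
#' @export
read_mask <- function(path) {
  img <- RNifti::readNifti(path)
  volume_mask(as.array(img) != 0, RNifti::pixdim(img)[1:3],
              unclass_affine(RNifti::xform(img)))
}

#' Write a binary mask to NIfTI
#' @param mask A [volume_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  RNifti::writeNifti(
    nifti_with_affine(array(as.integer(mask$grid), dim(mask$grid)),
                      mask$voxel_size, mask$affine),
    path, datatype = "uint8")
  invisible(path)
}

#' Smooth a DWI volume with an isotropic Gaussian kernel
#'
#' Each 3-D volume (weighted and unweighted alike) is convolved
#' independently with a separable Gaussian whose standard deviation is
#' `sigma_mm` millimetres per axis, converted to voxel units through the
#' voxel size. Boundaries use reflect padding, which conserves total image
#' mass for interior-supported images.
#'
#' @param dwi A [dwi_volume()].
#' @param sigma_mm Kernel standard deviation in mm (default 0.8).
#' @return A smoothed [dwi_volume()] (s0 recomputed).
#' @export
smooth_dwi <- function(dwi, sigma_mm = 0.8) {
  if (sigma_mm < 0) stop("sigma_mm must be non-negative")
  if (sigma_mm == 0) return(dwi)
  out <- dwi$data
  sig_vox <- sigma_mm / dwi$voxel_size
  for (v in seq_len(dim(out)[4]))
    out[, , , v] <- gaussian_smooth_3d(out[, , , v], sig_vox)
  dwi_volume(out, dwi$scheme, dwi$voxel_size, dwi$affine)
}

#' Separable Gaussian smoothing of a 3-D array
#' @param vol 3-D numeric array.
#' @param sigma_vox Per-axis standard deviation in voxel units (length 3).
#' @return Smoothed array of the same dimension.
#' @export
gaussian_smooth_3d <- function(vol, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(4 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2))
    k <- k / sum(k)
    vol <- convolve_axis_reflect(vol, k, ax)
  }
  vol
}

# 1-D convolution along `ax` with reflect padding, applied to every line.
convolve_axis_reflect <- function(vol, k, ax) {
  d <- dim(vol)
  perm <- c(ax, setdiff(1:3, ax))
  m <- aperm(vol, perm)
  dm <- dim(m)
  m <- matrix(m, nrow = dm[1])
  n <- nrow(m)
  r <- (length(k) - 1L) / 2L
  # reflect (mirror without repeating the edge sample); fall back to edge
  # clamping when the kernel radius exceeds the axis length
  pre <- pmax(1L, pmin(n, (r + 1L):2L))
  post <- pmax(1L, pmin(n, (n - 1L):(n - r)))
  mp <- rbind(m[pre, , drop = FALSE], m, m[post, , drop = FALSE])
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k))
    out <- out + k[j] * mp[(j - 1L) + seq_len(n), , drop = FALSE]
  aperm(array(out, dm), order(perm))
}

#' Write a labeling to NIfTI
#' @param labeling A `labeling` object (see [kmeans_combined()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_labeling <- function(labeling, path) {
  RNifti::writeNifti(
    nifti_with_affine(array(as.integer(labeling$labels),
                            dim(labeling$labels)),
                      labeling$voxel_size, labeling$affine),
    path, datatype = "int16")
  invisible(path)
}

#' Read an integer label volume from NIfTI
#'
#' Float-typed files are accepted when every voxel holds an integral
#' value; anything else is a format error. Centroids are recomputed from
#' the voxel data.
#'
#' @param path NIfTI path.
#' @return A `labeling` object (labels, centroids in mm, k).
#' @export
read_labeling <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (max(abs(arr - round(arr))) > 1e-6)
    stop("label image contains non-integer voxel values")
  arr <- array(as.integer(round(arr)), dim(arr))
  if (all(arr == 0L))
    warning("empty labeling: all voxels are background")
  new_labeling(arr, RNifti::pixdim(img)[1:3],
               unclass_affine(RNifti::xform(img)))
}

#' Map 0-based voxel indices to world mm through an affine
#' @param idx0 `n x 3` matrix of 0-based voxel indices (may be fractional).
#' @param affine 4 x 4 transform.
#' @return `n x 3` matrix of mm coordinates.
#' @export
voxel_to_world <- function(idx0, affine) {
  idx0 <- matrix(idx0, ncol = 3)
  t(affine %*% rbind(t(idx0), 1))[, 1:3, drop = FALSE]
}

# world mm -> 0-based voxel indices
world_to_voxel <- function(xyz, affine) {
  xyz <- matrix(xyz, ncol = 3)
  t(solve(affine) %*% rbind(t(xyz), 1))[, 1:3, drop = FALSE]
}

#' Positions (mm) of in-mask voxel centers
#' @param mask A [volume_mask()].
#' @return `n x 3` matrix of mm coordinates plus attribute `"index"`
#'   holding the corresponding `n x 3` 1-based voxel indices.
#' @export
mask_positions <- function(mask) {
  idx <- which(mask$grid, arr.ind = TRUE)
  pos <- voxel_to_world(idx - 1, mask$affine)
  attr(pos, "index") <- idx
  pos
}
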