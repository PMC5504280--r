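#' Specification of a synthetic multi-tensor diffusion phantom
#'
#' Describes an ellipsoidal "thalamus" partitioned into `k_regions`
#' spatially compact angular wedges, each with its own single- or
#' two-fiber multi-tensor model, surrounded by contamination rims that
#' emulate the real sources the mask refinement targets: a
#' high-CSF-probability rim (isotropic, fast diffusion) on the inferior
#' border and a high-FA shell (internal-capsule-like) on the superior
#' border. The default acquisition emulates a clinical single-shell
#' protocol: 64 gradient directions at b = 1000 s/mm^2 plus one b = 0
#' volume, 2 x 2 x 2.5 mm voxels.
#'
#' @param grid_dim Grid size in voxels (default `c(24, 24, 18)`).
#' @param voxel_size Voxel edges in mm (default `c(2, 2, 2.5)`).
#' @param semi_axes Ellipsoid semi-axes in mm (default `c(22, 17, 11)`,
#'   about 1700 in-mask voxels; the flattened shape keeps the angular
#'   wedge regions spatially compact, as the clustering assumes).
#' @param k_regions Number of wedge regions (default 7).
#' @param orientations `k_regions`-element list; each element is a matrix
#'   with one unit fiber direction per row (1 or 2 rows). The default
#'   gives every region a distinct pair of crossing fibers, which keeps
#'   the tensor-fit FA at thalamus-like values (about 0.45-0.55) while
#'   the ODFs remain strongly orientation-distinct.
#' @param fractions List of per-region volume fraction vectors summing
#'   to 1 (default `c(0.6, 0.4)` per region).
#' @param lambdas Per-fiber tensor eigenvalues (mm^2/s), axially
#'   symmetric `(parallel, perpendicular, perpendicular)`; default
#'   `c(1.7, 0.3, 0.3) * 1e-3`, the canonical simulation values for a
#'   coherent fiber population.
#' @param capsule_lambdas Eigenvalues of the high-FA rim tensor (default
#'   `c(1.9, 0.2, 0.2) * 1e-3`, FA about 0.89).
#' @param csf_diffusivity Isotropic diffusivity of the CSF rim (default
#'   3e-3 mm^2/s).
#' @param scheme A [gradient_scheme()]; default 64 hemisphere directions
#'   at b = 1000 plus one leading b = 0.
#' @param snr Rician signal-to-noise ratio referenced to S0 (default 30);
#'   `Inf` disables noise.
#' @param s0 Unweighted signal level (arbitrary units, default 100).
#' @param csf_rim,capsule_rim Rim thicknesses in mm (default 2 each).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(24, 24, 18),
                         voxel_size = c(2, 2, 2.5),
                         semi_axes = c(22, 17, 11),
                         k_regions = 7,
                         orientations = default_orientations(k_regions),
                         fractions = lapply(orientations,
                                            function(o) if (nrow(o) == 2)
                                              c(0.6, 0.4)
                                            else rep(1 / nrow(o), nrow(o))),
                         lambdas = c(1.7, 0.3, 0.3) * 1e-3,
                         capsule_lambdas = c(1.9, 0.2, 0.2) * 1e-3,
                         csf_diffusivity = 3e-3,
                         scheme = default_scheme(),
                         snr = 30, s0 = 100,
                         csf_rim = 2, capsule_rim = 2) {
  stopifnot(length(grid_dim) == 3, length(voxel_size) == 3,
            k_regions >= 1, length(orientations) == k_regions,
            length(fractions) == k_regions)
  for (i in seq_len(k_regions)) {
    o <- orientations[[i]]
    stopifnot(is.matrix(o), ncol(o) == 3,
              abs(sum(fractions[[i]]) - 1) < 1e-8,
              nrow(o) == length(fractions[[i]]))
    orientations[[i]] <- o / sqrt(rowSums(o^2))
  }
  if (snr <= 0) stop("snr must be positive (use Inf for noise-free)")
  structure(list(grid_dim = as.integer(grid_dim),
                 voxel_size = as.numeric(voxel_size),
                 semi_axes = semi_axes, k_regions = as.integer(k_regions),
                 orientations = orientations, fractions = fractions,
                 lambdas = lambdas, capsule_lambdas = capsule_lambdas,
                 csf_diffusivity = csf_diffusivity, scheme = scheme,
                 snr = snr, s0 = s0, csf_rim = csf_rim,
                 capsule_rim = capsule_rim),
            class = "phantom_spec")
}

#' Default 64-direction b=1000 scheme with one leading b=0
#' @param n_dir Number of diffusion directions.
#' @param bval Shell b-value (s/mm^2).
#' @return A [gradient_scheme()].
#' @export
default_scheme <- function(n_dir = 64, bval = 1000) {
  gradient_scheme(c(0, rep(bval, n_dir)),
                  rbind(c(0, 0, 0), sphere_points(n_dir, hemisphere = TRUE)))
}

# one distinct crossing-fiber pair per region, drawn from 2k
# quasi-uniform hemisphere directions (pair i = directions i and i + k)
default_orientations <- function(k) {
  pts <- sphere_points(2 * k, hemisphere = TRUE)
  lapply(seq_len(k), function(i) pts[c(i, i + k), , drop = FALSE])
}

# multi-tensor attenuation for one voxel model at the scheme directions
multi_tensor_signal <- function(dirs, bvals, orientations, fractions,
                                lambdas) {
  att <- numeric(length(bvals))
  for (f in seq_along(fractions)) {
    v <- orientations[f, ]
    # D = (l1 - l23) v v' + l23 I  =>  u'Du = l23 + (l1 - l23) (u.v)^2
    udv <- lambdas[2] + (lambdas[1] - lambdas[2]) * (dirs %*% v)^2
    att <- att + fractions[f] * exp(-bvals * udv)
  }
  att
}

#' Generate a synthetic DWI phantom
#'
#' Builds the noiseless multi-tensor signal
#' `S(u) = S0 sum_i f_i exp(-b u' D_i u)` voxel-wise, applies Rician
#' noise (magnitude of the complex signal with two independent Gaussian
#' channels of standard deviation `S0 / snr`; b = 0 volumes are noised
#' identically), and returns everything the segmentation pipeline
#' consumes: the DWI volume, the thalamus mask, a CSF probability map
#' (high only in the inferior rim) and the ground-truth wedge labeling.
#'
#' @param spec A [phantom_spec()].
#' @param seed Integer seed for the noise (ignored when `snr = Inf`).
#' @return List with `dwi` ([dwi_volume()]), `mask` ([volume_mask()]),
#'   `csf_prob` (3-D array), `truth` (`labeling`), and `spec`.
#' @export
generate_phantom <- function(spec = phantom_spec(), seed = NULL) {
  noiseless <- phantom_noiseless(spec)
  data <- noiseless$signal
  if (is.finite(spec$snr)) {
    sigma <- spec$s0 / spec$snr
    with_preserved_seed(seed, {
      data <- sqrt((data + array(stats::rnorm(length(data), 0, sigma),
                                 dim(data)))^2 +
                     array(stats::rnorm(length(data), 0, sigma),
                           dim(data))^2)
    })
  }
  dwi <- dwi_volume(data, spec$scheme, spec$voxel_size, noiseless$affine)
  list(dwi = dwi, mask = noiseless$mask, csf_prob = noiseless$csf_prob,
       truth = noiseless$truth, spec = spec)
}

# deterministic noiseless phantom: signal, mask, csf map, truth labels
phantom_noiseless <- function(spec) {
  d <- spec$grid_dim
  vs <- spec$voxel_size
  affine <- diag(c(vs, 1))
  center <- (d - 1) / 2 * vs
  idx <- as.matrix(expand.grid(i = seq_len(d[1]), j = seq_len(d[2]),
                               k = seq_len(d[3])))
  xyz <- sweep(voxel_to_world(idx - 1, affine), 2, center)
  inside <- rowSums(sweep(xyz, 2, spec$semi_axes, "/")^2) <= 1
  grid <- array(FALSE, d)
  grid[idx[inside, , drop = FALSE]] <- TRUE
  mask <- volume_mask(grid, vs, affine)

  # wedge partition: equal angular sectors in the axial plane
  ang <- atan2(xyz[inside, 2], xyz[inside, 1])
  region <- pmin(spec$k_regions,
                 1L + as.integer(floor((ang + pi) / (2 * pi) *
                                         spec$k_regions)))
  labels <- array(0L, d)
  labels[idx[inside, , drop = FALSE]] <- region
  truth <- new_labeling(labels, vs, affine)

  # rims: border distance inside the mask, split by z about the center
  bd <- border_distance_map(mask)
  zrel <- array(0, d)
  zrel[idx] <- xyz[, 3]
  in_csf_rim <- grid & bd <= spec$csf_rim & zrel < 0
  in_capsule <- grid & bd <= spec$capsule_rim & zrel >= 0
  csf_prob <- array(0.01, d)
  csf_prob[in_csf_rim] <- 0.9

  dirs <- spec$scheme$bvecs
  bv <- spec$scheme$bvals
  n_vol <- length(bv)
  sig <- array(0, c(d, n_vol))
  flat <- matrix(0, prod(d), n_vol)
  lin_all <- which(grid)
  reg_of <- array(0L, d); reg_of[idx[inside, , drop = FALSE]] <- region
  for (r in seq_len(spec$k_regions)) {
    att <- multi_tensor_signal(dirs, bv, spec$orientations[[r]],
                               spec$fractions[[r]], spec$lambdas)
    sel <- lin_all[reg_of[lin_all] == r & !in_csf_rim[lin_all] &
                     !in_capsule[lin_all]]
    if (length(sel))
      flat[sel, ] <- matrix(spec$s0 * att, length(sel), n_vol, byrow = TRUE)
    # capsule voxels keep their wedge's primary orientation but are
    # single-fiber and highly anisotropic, emulating internal-capsule
    # partial volume
    att_cap <- multi_tensor_signal(dirs, bv,
                                   spec$orientations[[r]][1, , drop = FALSE],
                                   1, spec$capsule_lambdas)
    sel_cap <- lin_all[reg_of[lin_all] == r & in_capsule[lin_all]]
    if (length(sel_cap))
      flat[sel_cap, ] <- matrix(spec$s0 * att_cap, length(sel_cap), n_vol,
                                byrow = TRUE)
  }
  att_csf <- exp(-bv * spec$csf_diffusivity)
  sel_csf <- lin_all[in_csf_rim[lin_all]]
  if (length(sel_csf))
    flat[sel_csf, ] <- matrix(spec$s0 * att_csf, length(sel_csf), n_vol,
                              byrow = TRUE)
  sig <- array(flat, c(d, n_vol))
  list(signal = sig, mask = mask, csf_prob = csf_prob, truth = truth,
       affine = affine)
}

#' Simulate a scan-rescan pair
#'
#' Two acquisitions of the identical noiseless phantom with independent
#' Rician noise realizations, sharing one ground-truth labeling — the
#' synthetic analog of two same-day scans of one subject.
#'
#' @param spec A [phantom_spec()].
#' @param seed_a,seed_b Noise seeds for the two acquisitions.
#' @return List with `scan_a`, `scan_b` (each as [generate_phantom()]
#'   output), sharing `mask`, `csf_prob` and `truth`.
#' @export
simulate_scan_rescan <- function(spec = phantom_spec(), seed_a, seed_b) {
  a <- generate_phantom(spec, seed = seed_a)
  b <- generate_phantom(spec, seed = seed_b)
  list(scan_a = a$dwi, scan_b = b$dwi, mask = a$mask,
       csf_prob = a$csf_prob, truth = a$truth, spec = spec)
}

#' Write phantom outputs to a directory
#' @param phantom Output of [generate_phantom()].
#' @param out_dir Directory (created if missing).
#' @return Invisibly, `out_dir`.
#' @export
write_phantom <- function(phantom, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_dwi(phantom$dwi, file.path(out_dir, "dwi.nii.gz"),
            file.path(out_dir, "bvals"), file.path(out_dir, "bvecs"))
  write_mask(phantom$mask, file.path(out_dir, "mask.nii.gz"))
  RNifti::writeNifti(nifti_with_affine(phantom$csf_prob,
                                       phantom$mask$voxel_size,
                                       phantom$mask$affine),
                     file.path(out_dir, "csf.nii.gz"))
  write_labeling(phantom$truth, file.path(out_dir, "truth.nii.gz"))
  invisible(out_dir)
}
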