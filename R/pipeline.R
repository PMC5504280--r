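#' Full thalamic parcellation pipeline
#'
#' Runs the complete segmentation on one DWI dataset: optional Gaussian
#' pre-smoothing, optional CSF/FA mask refinement, per-voxel
#' bootstrap-mean CSA ODF reconstruction (or tensor fit for the
#' angular-difference baseline), feature assembly, data-driven k-means
#' initialization and the combined spatial + feature k-means.
#'
#' @param dwi A [dwi_volume()].
#' @param mask A [volume_mask()] of the thalamus.
#' @param cfg A [cluster_config()].
#' @param feature `"odf"` (combined spatial + ODF clustering) or `"ad"`
#'   (angular-difference baseline on tensor principal eigenvectors).
#' @param smooth_sigma Pre-smoothing kernel std in mm (0 disables;
#'   the acquisition default is 0.8).
#' @param refine Optional list with `csf_prob` (3-D array) and optionally
#'   `config` (a [refine_config()]); when given, the mask is refined
#'   with the CSF rule and an FA map fitted from the data before
#'   clustering.
#' @param lmax SH order for the ODF reconstruction (default 6).
#' @param n_samples Bootstrap replicates (default 50).
#' @param seed Integer seed driving both the bootstrap and the k-means
#'   initializations (sub-seeds are derived deterministically).
#' @return A `labeling` (see [kmeans_combined()]) with attribute
#'   `"mask_used"` holding the (possibly refined) mask.
#' @examples
#' \donttest{
#' ph <- generate_phantom(phantom_spec(snr = 30), seed = 1)
#' cfg <- cluster_config(n_init_runs = 50, seed = 2)
#' lab <- parcellate_dwi(ph$dwi, ph$mask, cfg, seed = 3)
#' table(lab$labels[lab$labels > 0])
#' }
#' @export
parcellate_dwi <- function(dwi, mask, cfg = cluster_config(),
                           feature = c("odf", "ad"), smooth_sigma = 0,
                           refine = NULL, lmax = 6, n_samples = 50,
                           seed = NULL) {
  feature <- match.arg(feature)
  if (smooth_sigma > 0) dwi <- smooth_dwi(dwi, smooth_sigma)
  if (!is.null(refine)) {
    fa <- fit_tensor_field(dwi, mask)$fa
    mask <- refine_mask(mask, refine$csf_prob, fa,
                        refine$config %||% refine_config())
  }
  boot_seed <- if (!is.null(seed)) seed else NULL
  if (is.null(cfg$seed) && !is.null(seed)) cfg$seed <- seed + 1L
  field <- fit_odf_field(dwi, mask, lmax = lmax, n_samples = n_samples,
                         seed = boot_seed)
  features <- extract_features(field, mask, cfg)
  init <- init_centroids(features, cfg)
  lab <- if (feature == "odf") {
    kmeans_combined(features, init, cfg)
  } else {
    tf <- fit_tensor_field(dwi, mask)
    kmeans_ad(features, tf$e1, init, cfg)
  }
  attr(lab, "mask_used") <- mask
  lab
}

#' Scan-rescan reproducibility of the pipeline
#'
#' Runs [parcellate_dwi()] independently on the two acquisitions of a
#' scan-rescan pair and reports the matched per-cluster similarity
#' metrics.
#'
#' @param pair Output of [simulate_scan_rescan()] (or a list with
#'   `scan_a`, `scan_b`, `mask`).
#' @param cfg A [cluster_config()].
#' @param feature `"odf"` or `"ad"`.
#' @param seed Base seed; the two runs use `seed` and `seed + 100`.
#' @param ... Passed to [parcellate_dwi()].
#' @return List with `metrics` (see [cluster_metrics()]), `mean_dice`,
#'   `labeling_a`, `labeling_b`.
#' @export
scan_rescan_metrics <- function(pair, cfg = cluster_config(),
                                feature = "odf", seed = NULL, ...) {
  la <- parcellate_dwi(pair$scan_a, pair$mask, cfg, feature = feature,
                       seed = seed, ...)
  lb <- parcellate_dwi(pair$scan_b, pair$mask, cfg, feature = feature,
                       seed = if (!is.null(seed)) seed + 100L, ...)
  m <- cluster_metrics(la, lb)
  list(metrics = m, mean_dice = mean(m$dice), labeling_a = la,
       labeling_b = lb)
}
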