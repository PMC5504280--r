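#' Refinement thresholds for the thalamus mask
#'
#' @param csf_max Voxels with CSF probability at or above this are removed
#'   (keep rule is strictly `< csf_max`; default 0.05).
#' @param fa_max Border-zone voxels with FA strictly greater than this are
#'   removed (default 0.55), excluding partial-volume contamination from
#'   the internal capsule.
#' @param border_mm Width of the border zone in mm, boundary-inclusive
#'   (default 2).
#' @return Object of class `refine_config`.
#' @export
refine_config <- function(csf_max = 0.05, fa_max = 0.55, border_mm = 2.0) {
  stopifnot(csf_max >= 0, csf_max <= 1, fa_max >= 0, fa_max <= 1,
            border_mm >= 0)
  structure(list(csf_max = csf_max, fa_max = fa_max, border_mm = border_mm),
            class = "refine_config")
}

#' Distance from in-mask voxels to the mask border
#'
#' Exact Euclidean distance transform (separable lower-envelope
#' algorithm) from each in-mask voxel center to the nearest out-of-mask
#' voxel center, honouring anisotropic voxel sizes. Out-of-mask voxels
#' get distance 0.
#'
#' @param mask A [volume_mask()], non-empty.
#' @return 3-D array of distances in mm (0 outside the mask).
#' @export
border_distance_map <- function(mask) {
  if (!any(mask$grid)) stop("empty mask")
  d2 <- array(ifelse(mask$grid, Inf, 0), dim(mask$grid))
  for (ax in 1:3)
    d2 <- edt_pass(d2, ax, mask$voxel_size[ax])
  sqrt(d2)
}

# one separable squared-EDT pass along axis `ax` with sample spacing `s`
edt_pass <- function(d2, ax, s) {
  dm <- dim(d2)
  perm <- c(ax, setdiff(1:3, ax))
  m <- matrix(aperm(d2, perm), nrow = dm[ax])
  for (j in seq_len(ncol(m)))
    m[, j] <- edt_1d(m[, j], s)
  aperm(array(m, dm[perm]), order(perm))
}

# 1-D squared distance transform (Felzenszwalb & Huttenlocher lower
# envelope of parabolas), positions x_i = s*i
edt_1d <- function(f, s) {
  n <- length(f)
  if (all(is.infinite(f)) || all(f == 0)) return(f)
  x <- s * seq_len(n)
  v <- integer(n); z <- numeric(n + 1)
  k <- 0L
  for (q in seq_len(n)) {
    if (is.infinite(f[q])) next
    while (k > 0L) {
      p <- v[k]
      sect <- ((f[q] + x[q]^2) - (f[p] + x[p]^2)) / (2 * (x[q] - x[p]))
      if (sect <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- if (k == 1L) -Inf else sect
    z[k + 1L] <- Inf
  }
  d <- numeric(n)
  j <- 1L
  for (q in seq_len(n)) {
    while (z[j + 1L] < x[q]) j <- j + 1L
    p <- v[j]
    d[q] <- (x[q] - x[p])^2 + f[p]
  }
  d
}

#' Refine a thalamus mask with CSF probability and FA maps
#'
#' Removes, in a single pass over the input mask, (a) voxels whose CSF
#' probability is `>= csf_max` (partial-volume contamination from
#' cerebrospinal fluid) and (b) voxels lying within `border_mm` of the
#' mask border (boundary-inclusive, measured on the input mask) whose FA
#' exceeds `fa_max` (partial-volume contamination from the internal
#' capsule). The output is always a subset of the input.
#'
#' @param mask A [volume_mask()].
#' @param csf_prob 3-D array of CSF probabilities in `[0, 1]`.
#' @param fa 3-D array of FA values (NA allowed outside the mask).
#' @param cfg A [refine_config()].
#' @return The refined [volume_mask()], with attribute `"removed"` giving
#'   the per-rule removal counts.
#' @export
refine_mask <- function(mask, csf_prob, fa, cfg = refine_config()) {
  if (!identical(dim(csf_prob), dim(mask$grid)) ||
      !identical(dim(fa), dim(mask$grid)))
    stop("csf_prob and fa must share the mask grid dimensions")
  if (any(csf_prob < 0 | csf_prob > 1, na.rm = TRUE))
    stop("csf_prob must lie in [0, 1]")
  g <- mask$grid
  rm_csf <- g & !is.na(csf_prob) & csf_prob >= cfg$csf_max
  bd <- border_distance_map(mask)
  rm_fa <- g & bd <= cfg$border_mm & !is.na(fa) & fa > cfg$fa_max
  out <- g & !rm_csf & !rm_fa
  if (!any(out)) stop("mask eliminated by refinement")
  message("refine_mask: removed ", sum(rm_csf), " CSF-rule and ",
          sum(rm_fa & !rm_csf), " FA-rule voxels of ", sum(g))
  res <- volume_mask(out, mask$voxel_size, mask$affine)
  attr(res, "removed") <- c(csf = sum(rm_csf), fa = sum(rm_fa & !rm_csf))
  res
}
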