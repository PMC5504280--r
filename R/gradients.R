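#' Diffusion gradient scheme
#'
#' Bundles the per-volume b-values and unit gradient directions of a
#' single-shell diffusion acquisition. Volumes with a b-value below
#' `b0_threshold` are treated as unweighted (b = 0) reference volumes;
#' their direction vectors are irrelevant and may be zero. Directions of
#' diffusion-weighted volumes are renormalized to unit length.
#'
#' @param bvals Numeric vector of b-values (s/mm^2), one per volume.
#' @param bvecs Numeric matrix of gradient directions, either `n x 3` or
#'   `3 x n` (FSL layout); transposed automatically.
#' @param b0_threshold b-values below this are treated as b = 0 (s/mm^2).
#'   Robust to scanner-reported near-zero b-values.
#' @return An object of class `gradient_scheme`: a list with elements
#'   `bvals`, `bvecs` (`n x 3`, unit rows for weighted volumes), `b0`
#'   (logical mask of unweighted volumes) and `n_b0`.
#' @examples
#' dirs <- sphere_points(64, hemisphere = TRUE)
#' sch <- gradient_scheme(c(0, rep(1000, 64)), rbind(0, dirs))
#' sch$n_b0
#' @export
gradient_scheme <- function(bvals, bvecs, b0_threshold = 50) {
  bvals <- unname(as.numeric(bvals))
  bvecs <- unname(as.matrix(bvecs))
  if (ncol(bvecs) != 3 && nrow(bvecs) == 3) bvecs <- t(bvecs)
  if (ncol(bvecs) != 3)
    stop("bvecs must be an n x 3 (or 3 x n) matrix")
  if (nrow(bvecs) != length(bvals))
    stop("bvals and bvecs describe different numbers of volumes (",
         length(bvals), " vs ", nrow(bvecs), ")")
  b0 <- bvals < b0_threshold
  if (!any(b0))
    stop("gradient scheme has no b=0 volume")
  if (all(b0))
    stop("no diffusion-weighted volumes")
  nrm <- sqrt(rowSums(bvecs^2))
  if (any(nrm[!b0] == 0))
    stop("zero direction vector at a diffusion-weighted volume")
  bvecs[!b0, ] <- bvecs[!b0, , drop = FALSE] / nrm[!b0]
  bvecs[b0, ] <- 0
  structure(list(bvals = bvals, bvecs = bvecs, b0 = b0, n_b0 = sum(b0)),
            class = "gradient_scheme")
}

#' Read an FSL-style bvals/bvecs pair
#'
#' `bvals` is whitespace-separated numbers (one row or one column);
#' `bvecs` is three rows by n columns (or the transpose).
#'
#' @param bvals_path,bvecs_path Paths to the two text files.
#' @param b0_threshold Passed to [gradient_scheme()].
#' @return A [gradient_scheme()].
#' @export
read_gradient_scheme <- function(bvals_path, bvecs_path, b0_threshold = 50) {
  bvals <- scan(bvals_path, quiet = TRUE)
  vec <- scan(bvecs_path, quiet = TRUE)
  if (length(vec) != 3 * length(bvals))
    stop("bvecs file holds ", length(vec), " numbers; expected 3 x ",
         length(bvals))
  # FSL files are 3 rows x n columns, read row-wise
  bvecs <- matrix(vec, nrow = 3, byrow = TRUE)
  gradient_scheme(bvals, bvecs, b0_threshold = b0_threshold)
}

#' Write a gradient scheme as FSL bvals/bvecs
#' @param scheme A [gradient_scheme()].
#' @param bvals_path,bvecs_path Output paths.
#' @return Invisibly, `scheme`.
#' @export
write_gradient_scheme <- function(scheme, bvals_path, bvecs_path) {
  writeLines(paste(format(scheme$bvals, trim = TRUE), collapse = " "),
             bvals_path)
  writeLines(apply(t(scheme$bvecs), 1, function(r)
    paste(format(r, trim = TRUE, digits = 12), collapse = " ")), bvecs_path)
  invisible(scheme)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat("Gradient scheme:", length(x$bvals), "volumes (", x$n_b0,
      "b=0,", sum(!x$b0), "weighted ), b =",
      paste(unique(round(x$bvals[!x$b0])), collapse = "/"), "s/mm^2\n")
  invisible(x)
}

#' Quasi-uniform points on the sphere or hemisphere
#'
#' Fibonacci spiral sampling; with `hemisphere = TRUE` the `n` points cover
#' the upper hemisphere (z >= 0), the natural domain for antipodally
#' symmetric diffusion sampling schemes.
#'
#' @param n Number of points.
#' @param hemisphere Restrict to z >= 0.
#' @return `n x 3` matrix of unit vectors.
#' @export
sphere_points <- function(n, hemisphere = FALSE) {
  m <- if (hemisphere) 2L * n else n
  i <- seq_len(m) - 1
  ga <- pi * (3 - sqrt(5))
  z <- 1 - 2 * (i + 0.5) / m
  r <- sqrt(pmax(0, 1 - z^2))
  th <- ga * i
  pts <- unname(cbind(r * cos(th), r * sin(th), z))
  if (hemisphere) pts <- pts[z >= 0, , drop = FALSE][seq_len(n), , drop = FALSE]
  pts
}
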