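#' Real symmetric spherical-harmonic basis
#'
#' Builds the modified real symmetric SH basis (even orders only) used to
#' represent antipodally symmetric spherical functions such as diffusion
#' ODFs. Coefficients are ordered by order `l` ascending and degree `m`
#' ascending within each order (`m = -l..l`), giving
#' `R = (lmax+1)(lmax+2)/2` basis functions. For `m < 0` the basis
#' function is `sqrt(2) N_l^|m| P_l^|m|(cos theta) cos(|m| phi)`, for
#' `m = 0` it is `N_l^0 P_l^0(cos theta)` and for `m > 0`
#' `sqrt(2) N_l^m P_l^m(cos theta) sin(m phi)`, with `N_l^m` the full
#' orthonormalization constant. The basis is orthonormal under the
#' spherical measure.
#'
#' @param lmax Maximum (even) SH order; `lmax = 6` gives 28 coefficients.
#' @param dirs `n x 3` matrix of unit direction vectors at which the basis
#'   is evaluated.
#' @return Object of class `sh_basis`: list with `lmax`, `R`, `orders`
#'   (per-coefficient `l`), `degrees` (per-coefficient `m`), `design`
#'   (`n x R` matrix of basis values) and `dirs`.
#' @examples
#' b <- sh_basis(6, sphere_points(64, hemisphere = TRUE))
#' b$R  # 28
#' @export
sh_basis <- function(lmax, dirs) {
  if (lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be an even non-negative integer")
  dirs <- matrix(dirs, ncol = 3)
  if (nrow(dirs) == 0) stop("dirs must be non-empty")
  R <- (lmax + 1) * (lmax + 2) / 2
  theta <- acos(pmin(pmax(dirs[, 3], -1), 1))
  phi <- atan2(dirs[, 2], dirs[, 1])
  ct <- cos(theta)
  design <- matrix(0, nrow(dirs), R)
  orders <- integer(R)
  degrees <- integer(R)
  j <- 0L
  for (l in seq(0, lmax, by = 2)) {
    # associated Legendre P_l^m(cos theta), MATLAB/Condon-Shortley
    # convention; row m+1 of pracma::legendre holds P_l^m
    P <- t(pracma::legendre(l, ct))
    if (l == 0) P <- matrix(P, ncol = 1)
    for (m in -l:l) {
      j <- j + 1L
      am <- abs(m)
      N <- sqrt((2 * l + 1) / (4 * pi) *
                  exp(lgamma(l - am + 1) - lgamma(l + am + 1)))
      design[, j] <-
        if (m < 0) sqrt(2) * N * P[, am + 1] * cos(am * phi)
        else if (m == 0) N * P[, 1]
        else sqrt(2) * N * P[, am + 1] * sin(m * phi)
      orders[j] <- l
      degrees[j] <- m
    }
  }
  structure(list(lmax = lmax, R = R, orders = orders, degrees = degrees,
                 design = design, dirs = dirs),
            class = "sh_basis")
}

#' @export
print.sh_basis <- function(x, ...) {
  cat("Real symmetric SH basis: lmax =", x$lmax, ", R =", x$R,
      "coefficients,", nrow(x$design), "directions\n")
  invisible(x)
}

#' Evaluate an SH coefficient vector on the sphere
#' @param coeffs Length-R coefficient vector (or `R x n` matrix, one
#'   column per voxel).
#' @param basis An [sh_basis()] evaluated at the desired directions, or an
#'   `n x 3` matrix of unit directions (a basis of the same `lmax` as
#'   `coeffs` is then built on the fly).
#' @param lmax Required when `basis` is a direction matrix and `coeffs` is
#'   a bare vector.
#' @return Function values, one row per direction.
#' @export
sh_eval <- function(coeffs, basis, lmax = NULL) {
  if (!inherits(basis, "sh_basis")) {
    R <- if (is.matrix(coeffs)) nrow(coeffs) else length(coeffs)
    if (is.null(lmax)) lmax <- lmax_for_R(R)
    basis <- sh_basis(lmax, basis)
  }
  basis$design %*% if (is.matrix(coeffs)) coeffs else cbind(coeffs)
}

lmax_for_R <- function(R) {
  l <- (-3 + sqrt(1 + 8 * R)) / 2
  if (abs(l - round(l)) > 1e-9)
    stop("no even SH order has ", R, " coefficients")
  as.integer(round(l))
}

#' SH coefficient vector with a domain tag
#'
#' Thin wrapper distinguishing coefficients of the log-log signal fit from
#' coefficients of a reconstructed ODF, so that the CSA transform cannot
#' be applied twice by mistake.
#'
#' @param coeffs Numeric vector (length R) or `R x n` matrix.
#' @param lmax SH order of the generating basis.
#' @param domain `"loglog_signal"` or `"odf"`.
#' @return Object of class `sh_coeffs`.
#' @export
sh_coeffs <- function(coeffs, lmax, domain = c("loglog_signal", "odf")) {
  domain <- match.arg(domain)
  R <- (lmax + 1) * (lmax + 2) / 2
  n <- if (is.matrix(coeffs)) nrow(coeffs) else length(coeffs)
  if (n != R)
    stop("coefficient length ", n, " does not match lmax ", lmax,
         " (R = ", R, ")")
  if (!all(is.finite(coeffs)))
    stop("non-finite SH coefficients")
  structure(list(coeffs = coeffs, lmax = lmax, domain = domain),
            class = "sh_coeffs")
}

#' @export
print.sh_coeffs <- function(x, ...) {
  n <- if (is.matrix(x$coeffs)) ncol(x$coeffs) else 1L
  cat("SH coefficients (", x$domain, "): lmax =", x$lmax, ",", n,
      if (n == 1) "voxel\n" else "voxels\n")
  invisible(x)
}

# per-coefficient order vector for a given lmax, same ordering as sh_basis
sh_orders <- function(lmax) {
  unlist(lapply(seq(0, lmax, by = 2), function(l) rep(l, 2 * l + 1)))
}
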