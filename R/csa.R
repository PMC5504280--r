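#' Constant-solid-angle ODF transform
#'
#' The CSA q-ball estimator reconstructs the ODF from the double-log
#' transformed signal `f(u) = ln(-ln S(u)/S(0))` as
#' `ODF(u) = 1/(4 pi) + 1/(16 pi^2) * FRT{ LB f }(u)`,
#' where `LB` is the Laplace-Beltrami operator and `FRT` the Funk-Radon
#' transform. Both operators are diagonal in the SH basis — `LB` with
#' eigenvalue `-l(l+1)` and `FRT` with eigenvalue `2 pi P_l(0)` — so the
#' whole transform reduces to one multiplier per SH order:
#' `m_l = -l(l+1) P_l(0) / (8 pi)` for `l > 0`, while the constant term is
#' fixed at `1/(2 sqrt(pi))` so that the ODF integrates to exactly 1 over
#' the sphere.
#'
#' @param lmax Maximum even SH order.
#' @return Object of class `csa_transform`: list with `lmax`, `orders`,
#'   `multipliers` (length R; entry for l = 0 is NA because the constant
#'   is replaced, not scaled) and `c0` (the fixed constant coefficient).
#' @export
csa_transform <- function(lmax) {
  if (lmax < 0 || lmax %% 2 != 0)
    stop("lmax must be an even non-negative integer")
  orders <- sh_orders(lmax)
  mult <- -orders * (orders + 1) * legendre_p0(orders) / (8 * pi)
  mult[orders == 0] <- NA_real_
  structure(list(lmax = lmax, orders = orders, multipliers = mult,
                 c0 = 1 / (2 * sqrt(pi))),
            class = "csa_transform")
}

# Legendre polynomial at zero: P_l(0) = (-1)^(l/2) (l-1)!! / l!! for even l
legendre_p0 <- function(l) {
  p <- numeric(length(l))
  for (i in seq_along(l)) {
    li <- l[i]
    if (li %% 2 == 1) { p[i] <- 0; next }
    if (li == 0) { p[i] <- 1; next }
    k <- li / 2
    p[i] <- (-1)^k * exp(lgamma(li + 1) - 2 * k * log(2) - 2 * lgamma(k + 1))
  }
  p
}

#' @export
print.csa_transform <- function(x, ...) {
  cat("CSA transform: lmax =", x$lmax, ", per-order multipliers",
      paste(signif(unique(stats::na.omit(x$multipliers)), 4), collapse = ", "),
      "\n")
  invisible(x)
}

#' Apply the CSA transform to log-log signal coefficients
#'
#' Maps SH coefficients of `ln(-ln S/S0)` to SH coefficients of the
#' constant-solid-angle ODF. The constant term is set so the ODF
#' integrates to 1; higher orders are scaled by the analytic
#' Laplace-Beltrami and Funk-Radon eigenvalues.
#'
#' @param c An [sh_coeffs()] in the `"loglog_signal"` domain.
#' @param t A [csa_transform()] of matching order.
#' @return An [sh_coeffs()] in the `"odf"` domain.
#' @export
csa_odf <- function(c, t) {
  if (!inherits(c, "sh_coeffs"))
    stop("c must be an sh_coeffs object")
  if (c$domain == "odf")
    stop("coefficients are already in the odf domain")
  if (c$lmax != t$lmax)
    stop("transform order ", t$lmax, " does not match coefficients (",
         c$lmax, ")")
  mult <- t$multipliers
  mult[t$orders == 0] <- 0
  out <- if (is.matrix(c$coeffs)) c$coeffs * mult else c$coeffs * mult
  if (is.matrix(out)) out[t$orders == 0, ] <- t$c0
  else out[t$orders == 0] <- t$c0
  sh_coeffs(out, c$lmax, "odf")
}
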