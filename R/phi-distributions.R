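#' Attraction-factor distribution families on [-1, 1]
#'
#' Symmetric densities phi(q) on [-1, 1] under which the positive-part mean
#' \code{q+ = integral_0^1 q phi(q) dq} equals 1/4, the quarter law's
#' predicted typical amplitude:
#' \describe{
#'   \item{uniform}{phi(q) = 1/2 (the no-prior-information null).}
#'   \item{beta}{phi(q) = Gamma(2a) / (2 Gamma(a)^2) |q|^(a-1) (1-|q|)^(a-1),
#'     shape a > 0.}
#'   \item{quadratic}{phi(q) = 6 (|q| - 1/2)^2.}
#'   \item{triangular}{phi(q) = 2|q| for |q| <= 1/2, 2(1 - |q|) for
#'     1/2 < |q| <= 1.}
#' }
#' All are symmetric (mean of q is 0, as the alternation conditions require)
#' and give q+ = 1/4 for every admissible shape.
#'
#' @param family one of \code{"uniform"}, \code{"beta"}, \code{"quadratic"},
#'   \code{"triangular"}.
#' @param shape beta-family shape a > 0 (ignored by the other families).
#' @return Object of class \code{phi_dist}.
#' @examples
#' d <- phi_dist("triangular")
#' dphi(0.25, d)     # 0.5
#' qplus(d)          # 0.25
#' @export
phi_dist <- function(family = c("uniform", "beta", "quadratic", "triangular"),
                     shape = 1) {
  family <- match.arg(family)
  if (family == "beta" && (!is.numeric(shape) || shape <= 0)) {
    stop("beta family needs shape > 0", call. = FALSE)
  }
  structure(list(family = family, shape = shape), class = "phi_dist")
}

#' @export
print.phi_dist <- function(x, ...) {
  cat("Attraction-factor distribution:", x$family,
      if (x$family == "beta") sprintf("(shape %g)", x$shape) else "", "\n")
  invisible(x)
}

#' Density of an attraction-factor distribution
#'
#' @param q numeric vector in [-1, 1].
#' @param dist a \code{\link{phi_dist}}.
#' @return phi(q), non-negative.
#' @export
dphi <- function(q, dist) {
  stopifnot(inherits(dist, "phi_dist"))
  if (any(abs(q) > 1)) stop("|q| > 1 is outside the support", call. = FALSE)
  m <- abs(q)
  switch(dist$family,
    uniform = rep(0.5, length(q)),
    beta = {
      a <- dist$shape
      cst <- gamma(2 * a) / (2 * gamma(a)^2)
      cst * m^(a - 1) * (1 - m)^(a - 1)
    },
    quadratic = 6 * (m - 0.5)^2,
    triangular = ifelse(m <= 0.5, 2 * m, 2 * (1 - m))
  )
}

#' Positive-part mean q+ of an attraction-factor distribution
#'
#' \code{q+ = integral_0^1 q phi(q) dq}; by symmetry q- = -q+. Every family
#' in the package has q+ = 1/4 in closed form (for the beta family via
#' B(a+1, a) / B(a, a) * 1/2 = a / (4a) ... = 1/4), which the numeric method
#' verifies by adaptive quadrature split at the non-smooth points 0 and 1/2.
#'
#' @param dist a \code{\link{phi_dist}}.
#' @param method \code{"analytic"} (closed form) or \code{"numeric"}
#'   (quadrature).
#' @return Scalar q+.
#' @export
qplus <- function(dist, method = c("analytic", "numeric")) {
  stopifnot(inherits(dist, "phi_dist"))
  method <- match.arg(method)
  if (method == "analytic") {
    # all four families integrate to exactly 1/4 on the positive half-line
    return(0.25)
  }
  integrand <- function(q) q * dphi(q, dist)
  quad <- function(lo, hi) {
    stats::integrate(integrand, lo, hi, rel.tol = 1e-12,
                     abs.tol = 1e-12, subdivisions = 500L)$value
  }
  quad(0, 0.5) + quad(0.5, 1)
}

#' Mean absolute attraction factor of a distribution
#'
#' \code{E|q| = 2 q+ = 1/2} for every family here; reported as a companion
#' quantity because the empirical analysis compares the mean |q| over
#' aggregates with 0.25 while the raw densities have E|q| = 0.5 (see the
#' methods vignette for the discussion of this tension).
#'
#' @inheritParams qplus
#' @return Scalar E|q|.
#' @export
mean_abs <- function(dist, method = c("analytic", "numeric")) {
  2 * qplus(dist, method)
}

#' Sample attraction factors
#'
#' Rejection-free sampling: the magnitude |q| is drawn by inverse CDF
#' (uniform, quadratic, triangular families) or from a standard Beta(a, a)
#' (beta family), and an independent fair sign is applied.
#'
#' @param n number of draws.
#' @param dist a \code{\link{phi_dist}}.
#' @param seed optional integer seed (set before drawing when given).
#' @return Numeric vector of n draws in [-1, 1].
#' @export
rphi <- function(n, dist, seed = NULL) {
  stopifnot(inherits(dist, "phi_dist"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- rphi_magnitude(n, dist)
  s <- sample(c(-1, 1), n, replace = TRUE)
  m * s
}

# |q| law: density 2 phi(m) on [0, 1]
rphi_magnitude <- function(n, dist) {
  u <- stats::runif(n)
  switch(dist$family,
    uniform = u,
    beta = stats::rbeta(n, dist$shape, dist$shape),
    # CDF of 12 (m - 1/2)^2 is 4 (m - 1/2)^3 + 1/2
    quadratic = 0.5 + sign(u - 0.5) * (abs(u - 0.5) / 4)^(1 / 3),
    # triangular magnitude peaks at 1/2
    triangular = ifelse(u <= 0.5, sqrt(u / 2), 1 - sqrt((1 - u) / 2))
  )
}
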