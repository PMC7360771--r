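#' @include grid.R
NULL

## Radial basis: zetaRaw_n(r) = (1/N) r^2 (rO - r)^(n+2) on [0, rO), zero
## beyond the cutoff and at the origin. Polynomials of degree n + 4, so
## Gauss-Legendre quadrature evaluates every overlap exactly.

#' Raw (pre-orthogonalization) radial basis function
#'
#' Evaluates `(1/N) r^2 (rO - r)^(n+2)` for `r < rO` and 0 otherwise. The
#' function is continuous everywhere and vanishes at both `r = 0` and the
#' outer cutoff `r = rO`; the inner cutoff radius is fixed at zero.
#'
#' @param n integer radial index, >= 1.
#' @param r numeric vector of radii, Bohr, >= 0.
#' @param rO outer cutoff radius, Bohr, > 0.
#' @param normalization scalar N dividing the polynomial; see
#'   [radialNormalization()].
#' @return numeric vector of the same length as `r`.
#' @examples
#' radialRaw(2, 1, rO = 2)  # = 1 * (2 - 1)^4 = 1 (N = 1)
#' @export
radialRaw <- function(n, r, rO, normalization = 1) {
  if (n < 1) .stopf("radial index n must be >= 1")
  if (rO <= 0) .stopf("outer cutoff rO must be positive")
  if (any(r < 0)) .stopf("radii must be non-negative")
  out <- numeric(length(r))
  inside <- r < rO
  out[inside] <- r[inside]^2 * (rO - r[inside])^(n + 2) / normalization
  out
}

## Gauss-Legendre rule on [0, rO] resolving the radial polynomials exactly:
## integrands have degree <= 2 nMax + 10 (with the r^2 measure), so
## nMax + 6 nodes suffice; we default to a comfortable margin.
.radialRule <- function(nMax, rO, nQuad = NULL) {
  if (is.null(nQuad)) nQuad <- max(32L, nMax + 8L)
  pracma::gaussLegendre(nQuad, 0, rO)
}

#' Unit-norm constant of a raw radial function
#'
#' Returns `N` such that `radialRaw(n, r, rO, N)` has unit L2 norm under the
#' measure `r^2 dr` on `[0, rO]`, i.e. the 3-D norm of the corresponding
#' spherically symmetric function. Evaluated by Gauss--Legendre quadrature,
#' which is exact for these polynomials.
#'
#' @inheritParams radialRaw
#' @param quadrature optional list with nodes `x` and weights `w` on
#'   `[0, rO]`; defaults to an exact rule.
#' @return scalar N.
#' @export
radialNormalization <- function(n, rO, quadrature = NULL) {
  q <- if (is.null(quadrature)) .radialRule(n, rO) else quadrature
  f <- radialRaw(n, q$x, rO, normalization = 1)
  sqrt(sum(q$w * f^2 * q$x^2))
}

#' Loewdin-orthogonalize the radial basis
#'
#' Computes, per species, the symmetric (Loewdin) orthogonalization matrix
#' `M = S^(-1/2)` of the unit-normalized raw radial functions, so that
#' `zeta_n = sum_k M[n, k] zetaRaw_k` satisfies
#' `integral zeta_n zeta_n' r^2 dr = delta_nn'`. Symmetric orthogonalization
#' is basis-order independent and deterministic for a given spec.
#'
#' @param spec a [BasisSpec-class].
#' @param quadrature optional list with `x`, `w` (nodes and weights on
#'   `[0, rO]`), recycled per species, or an integer node count. The rule
#'   must resolve polynomials of the raw-overlap degree; the default does.
#' @return named list per species with elements `M` (nMax x nMax),
#'   `normalization` (vector of N_n) and `rO`.
#' @export
orthogonalizeRadial <- function(spec, quadrature = NULL) {
  stopifnot(is(spec, "BasisSpec"))
  out <- vector("list", length(spec@species))
  names(out) <- spec@species
  for (s in seq_along(spec@species)) {
    nMax <- spec@nMax[s]; rO <- spec@rO[s]
    q <- if (is.null(quadrature)) .radialRule(nMax, rO)
         else if (is.numeric(quadrature) && length(quadrature) == 1L)
           .radialRule(nMax, rO, as.integer(quadrature))
         else quadrature
    N <- vapply(seq_len(nMax), radialNormalization, numeric(1),
                rO = rO, quadrature = q)
    F <- vapply(seq_len(nMax),
                function(n) radialRaw(n, q$x, rO, N[n]), numeric(length(q$x)))
    S <- crossprod(F * sqrt(q$w * q$x^2))
    e <- eigen((S + t(S)) / 2, symmetric = TRUE)
    cond <- max(e$values) / min(e$values)
    if (min(e$values) <= 0 || cond > 1e14)
      .stopf("raw radial overlap numerically singular (condition number %.3g)",
             cond, class = "nxcrConditioningError")
    M <- e$vectors %*% diag(1 / sqrt(e$values), nMax) %*% t(e$vectors)
    out[[s]] <- list(M = M, normalization = N, rO = rO)
  }
  out
}

#' Evaluate orthonormal radial functions
#'
#' @param ortho one species' entry of [orthogonalizeRadial()] output.
#' @param r numeric radii, Bohr.
#' @return matrix length(r) x nMax of zeta_n(r).
#' @export
radialOrtho <- function(ortho, r) {
  nMax <- nrow(ortho$M)
  raw <- vapply(seq_len(nMax),
                function(n) radialRaw(n, r, ortho$rO, ortho$normalization[n]),
                numeric(length(r)))
  if (length(r) == 1L) raw <- matrix(raw, nrow = 1L)
  raw %*% t(ortho$M)
}
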