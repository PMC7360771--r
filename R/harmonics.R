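#' @include constants.R
NULL

## Real spherical harmonics, orthonormal on the unit sphere, without the
## Condon-Shortley phase, m ordered -l..l. The convention is fixed because
## serialized c_nlm coefficients depend on it (the d_nl invariants do not).

#' Real spherical harmonics for a block of directions
#'
#' Evaluates all real spherical harmonics up to `lMax` at the given unit
#' directions. Columns are ordered (l ascending; within l, m from -l to l):
#' for m < 0 the sin(|m| phi) combination, m = 0 the zonal harmonic, m > 0
#' the cos(m phi) combination, each normalized to unit L2 norm on the sphere.
#'
#' @param lMax integer maximum angular momentum.
#' @param dirs numeric n x 3 matrix of unit vectors.
#' @return numeric n x (lMax + 1)^2 matrix.
#' @export
sphericalHarmonics <- function(lMax, dirs) {
  dirs <- rbind(dirs)
  n <- nrow(dirs)
  ct <- pmin(1, pmax(-1, dirs[, 3L]))
  phi <- atan2(dirs[, 2L], dirs[, 1L])
  out <- matrix(0, n, (lMax + 1L)^2)
  col <- 0L
  for (l in 0:lMax) {
    ## associated Legendre P_l^m, m = 0..l; strip the Condon-Shortley phase
    P <- if (l == 0L) matrix(1, 1L, n) else pracma::legendre(l, ct)
    if (l > 0L) P <- P * (-1)^(0:l)
    norm0 <- sqrt((2 * l + 1) / (4 * pi))
    for (m in (-l):l) {
      col <- col + 1L
      am <- abs(m)
      Nlm <- norm0 * exp(0.5 * (lgamma(l - am + 1) - lgamma(l + am + 1)))
      out[, col] <-
        if (m < 0L)      sqrt(2) * Nlm * P[am + 1L, ] * sin(am * phi)
        else if (m == 0L) norm0 * P[1L, ]
        else             sqrt(2) * Nlm * P[am + 1L, ] * cos(am * phi)
    }
  }
  out
}

#' Single real spherical harmonic
#'
#' @param l integer, angular momentum, >= 0.
#' @param m integer, |m| <= l.
#' @param direction numeric length-3 unit vector, or n x 3 matrix.
#' @return numeric value(s) of Y_lm.
#' @examples
#' realSphericalHarmonic(0, 0, c(0, 0, 1))  # 1 / sqrt(4 pi)
#' @export
realSphericalHarmonic <- function(l, m, direction) {
  if (abs(m) > l) .stopf("|m| must not exceed l")
  Y <- sphericalHarmonics(l, rbind(direction))
  Y[, l^2 + l + m + 1L]
}
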