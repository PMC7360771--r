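#' @include model.R
NULL

#' Moments of a charge distribution
#'
#' Dipole and traceless quadrupole of the combined charge distribution:
#' point nuclear charges (species valence charge, +Z at R_I) minus the
#' electron density. The scalar quadrupole summary `qT` is half the
#' difference between the largest and smallest eigenvalue of the traceless
#' quadrupole tensor and is invariant to rotations. The spread `r2` is the
#' charge-weighted second radial moment of the valence electron density
#' about the origin (negative, electron charge being -e).
#'
#' For a non-neutral system the dipole depends on the origin; a warning is
#' emitted and the origin is recorded in the result.
#'
#' @param density a [DensityField-class] (valence electron density, e/Bohr^3).
#' @param system an [AtomicSystem-class] supplying nuclear point charges via
#'   `valenceCharges`.
#' @param origin numeric length-3 reference point, Bohr.
#' @return list with `dipole` (length-3, Debye), `dipoleNorm` (Debye),
#'   `quadrupole` (3 x 3 traceless tensor, Debye x Angstrom), `qT`
#'   (Debye x Angstrom), `r2` (Debye x Angstrom), `origin` (Bohr).
#' @export
densityMoments <- function(density, system, origin = c(0, 0, 0)) {
  origin <- as.numeric(origin)
  w <- density@grid@weights
  rho <- density@values
  pts <- sweep(density@grid@points, 2L, origin)
  Z <- system@valenceCharges[system@species]
  if (anyNA(Z))
    .stopf("no valence charge configured for some species",
           class = "nxcrConfigError")
  Rp <- sweep(system@positions, 2L, origin)
  nEl <- sum(w * rho)
  if (abs(sum(Z) - nEl) > 1e-4 * max(1, sum(Z)))
    warning(sprintf(
      "system is non-neutral (nuclear %.6f vs electronic %.6f); dipole is origin-dependent",
      sum(Z), nEl))
  ## dipole, e * Bohr -> Debye
  mu <- colSums(Rp * Z) - colSums(pts * (w * rho))
  ## traceless quadrupole, Buckingham convention, e * Bohr^2
  quadOf <- function(X, q) {
    r2 <- rowSums(X^2)
    M <- matrix(0, 3, 3)
    for (i in 1:3) for (j in 1:3)
      M[i, j] <- sum(q * (3 * X[, i] * X[, j] - (i == j) * r2)) / 2
    M
  }
  theta <- quadOf(Rp, Z) - quadOf(pts, w * rho)
  ev <- eigen((theta + t(theta)) / 2, symmetric = TRUE,
              only.values = TRUE)$values
  dipD <- mu * nxcrUnits[["debyePerEBohr"]]
  list(dipole = dipD,
       dipoleNorm = sqrt(sum(dipD^2)),
       quadrupole = theta * .debyeAngstromPerEBohr2,
       qT = (max(ev) - min(ev)) / 2 * .debyeAngstromPerEBohr2,
       r2 = -sum(w * rho * rowSums(pts^2)) * .debyeAngstromPerEBohr2,
       origin = origin)
}
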