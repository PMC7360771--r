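#' @include radial.R harmonics.R system.R
NULL

.sameGrid <- function(a, b) {
  nrow(a@points) == nrow(b@points) &&
    isTRUE(all.equal(a@points, b@points, tolerance = 1e-12,
                     check.attributes = FALSE))
}

## canonical (n, l, m) table for one atom: n ascending, l ascending, m -l..l
.nlmTable <- function(nMax, lMax) {
  rows <- list()
  for (n in seq_len(nMax))
    for (l in 0:lMax)
      for (m in (-l):l)
        rows[[length(rows) + 1L]] <- c(n, l, m)
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("n", "l", "m")
  tab
}

.nlmNames <- function(tab)
  sprintf("n%d.l%d.m%s%d", tab[, "n"], tab[, "l"],
          ifelse(tab[, "m"] < 0, "-", "+"), abs(tab[, "m"]))

#' Tabulate the atom-centered basis on a grid
#'
#' Orthogonalizes the radial basis per species and tabulates every basis
#' function `psi_nlm(r - R_I) = Y_lm zeta_n` at the grid points inside each
#' atom's cutoff sphere. For periodic grids displacements follow the
#' minimum-image convention, and an error is raised when a cutoff diameter
#' exceeds the shortest cell vector (the sphere would wrap onto itself).
#'
#' @param system an [AtomicSystem-class].
#' @param spec a [BasisSpec-class] covering every species present.
#' @param grid a [Grid-class]; must cover every atom's cutoff sphere.
#' @return a [ProjectionOperator-class].
#' @export
buildProjector <- function(system, spec, grid) {
  stopifnot(is(system, "AtomicSystem"), is(spec, "BasisSpec"), is(grid, "Grid"))
  bas <- basisFor(spec, system@species)
  if (grid@periodic) {
    minCell <- sqrt(min(rowSums(grid@cell^2)))
    if (any(2 * bas$rO > minCell))
      .stopf("cutoff diameter %.3f exceeds shortest cell vector %.3f",
             max(2 * bas$rO), minCell, class = "nxcrAmbiguityError")
  } else if (identical(grid@meta$backend, "uniform")) {
    ax <- grid@meta$axes
    if (all(abs(ax[upper.tri(ax) | lower.tri(ax)]) < 1e-12)) {
      lo <- grid@meta$origin - diag(ax) / 2
      hi <- lo + grid@meta$dims * diag(ax)
      for (a in seq_len(nAtoms(system))) {
        R <- system@positions[a, ]
        if (any(R - bas$rO[a] < lo - 1e-9) || any(R + bas$rO[a] > hi + 1e-9))
          .stopf("grid does not cover the cutoff sphere of atom %d", a)
      }
    }
  }
  ortho <- orthogonalizeRadial(spec)
  atoms <- vector("list", nAtoms(system))
  maps <- vector("list", nAtoms(system))
  beta0 <- 0L
  for (a in seq_len(nAtoms(system))) {
    s <- system@species[a]
    nMax <- bas$nMax[a]; lMax <- bas$lMax[a]; rO <- bas$rO[a]
    disp <- .displacements(grid, system@positions[a, ])
    r <- sqrt(rowSums(disp^2))
    idx <- which(r < rO)
    tab <- .nlmTable(nMax, lMax)
    nb <- nrow(tab)
    if (length(idx)) {
      rr <- r[idx]
      dirs <- disp[idx, , drop = FALSE] / pmax(rr, 1e-300)
      dirs[rr == 0, ] <- rep(c(0, 0, 1), each = sum(rr == 0))
      Z <- radialOrtho(ortho[[s]], rr)
      Y <- sphericalHarmonics(lMax, dirs)
      psi <- Z[, tab[, "n"], drop = FALSE] *
        Y[, tab[, "l"]^2 + tab[, "l"] + tab[, "m"] + 1L, drop = FALSE]
    } else {
      psi <- matrix(0, 0L, nb)
    }
    colnames(psi) <- .nlmNames(tab)
    atoms[[a]] <- list(idx = idx, psi = psi,
                       beta = seq.int(beta0 + 1L, beta0 + nb))
    maps[[a]] <- data.frame(beta = seq.int(beta0 + 1L, beta0 + nb),
                            atom = a, species = s,
                            n = tab[, "n"], l = tab[, "l"], m = tab[, "m"])
    beta0 <- beta0 + nb
  }
  new("ProjectionOperator", system = system, spec = spec, grid = grid,
      orthoCoeffs = ortho, atoms = atoms,
      betaMap = do.call(rbind, maps), basisHash = basisHash(spec))
}

#' @describeIn buildProjector total number of basis functions.
#' @param projector a [ProjectionOperator-class].
#' @export
nBasis <- function(projector) nrow(projector@betaMap)

#' Per-atom Gram matrix of the tabulated basis
#'
#' Quadrature Gram matrix `<psi_beta | psi_beta'>` restricted to one atom's
#' functions; identity within the grid backend's quadrature tolerance.
#'
#' @param projector a [ProjectionOperator-class].
#' @param atom integer atom index.
#' @return square numeric matrix.
#' @export
atomGram <- function(projector, atom) {
  at <- projector@atoms[[atom]]
  w <- projector@grid@weights[at$idx]
  crossprod(at$psi * sqrt(w))
}

#' @describeIn projectDensity quadrature projection of a density field.
#' @export
setMethod("projectDensity", signature("ProjectionOperator", "DensityField"),
  function(projector, density) {
    if (!.sameGrid(projector@grid, density@grid))
      .stopf("projector and density live on different grids",
             class = "nxcrShapeError")
    wv <- density@grid@weights * density@values
    coef <- lapply(projector@atoms, function(at)
      drop(crossprod(at$psi, wv[at$idx])))
    new("DescriptorSet", coefficients = coef, invariants = list(),
        species = projector@system@species, betaMap = projector@betaMap,
        basisHash = projector@basisHash)
  })

#' Atomic reference density
#'
#' Superposition of spherically symmetric atom-centered profiles, one per
#' atom, the (non-negative) first raw radial basis function scaled so that
#' it carries the species' valence charge. The scale is fixed on the
#' target grid's own quadrature, so the neutrality contract of the
#' difference density holds to machine precision on any grid backend (the
#' continuum normalization is recovered as the grid refines).
#' Subtracting this field from a full density yields the neutral difference
#' density used by models with the delta-density option.
#'
#' @param system an [AtomicSystem-class] with `valenceCharges` set.
#' @param spec a [BasisSpec-class].
#' @param grid a [Grid-class] to tabulate on.
#' @return a [DensityField-class] of kind `"atomic"`.
#' @export
atomicReferenceDensity <- function(system, spec, grid) {
  bas <- basisFor(spec, system@species)
  miss <- setdiff(unique(system@species), names(system@valenceCharges))
  if (length(miss))
    .stopf("no valence charge configured for species: %s",
           paste(miss, collapse = ", "), class = "nxcrConfigError")
  vals <- numeric(nGridPoints(grid))
  for (a in seq_len(nAtoms(system))) {
    rO <- bas$rO[a]
    v <- system@valenceCharges[[system@species[a]]]
    disp <- .displacements(grid, system@positions[a, ])
    r <- sqrt(rowSums(disp^2))
    idx <- which(r < rO)
    if (!length(idx)) next
    prof <- radialRaw(1L, r[idx], rO, radialNormalization(1L, rO))
    discrete <- sum(grid@weights[idx] * prof)
    if (discrete <= 0) .stopf("grid cannot resolve the atomic profile of atom %d", a)
    vals[idx] <- vals[idx] + (v / discrete) * prof
  }
  new("DensityField", grid = grid, values = vals, kind = "atomic",
      meta = list(source = "atomicReferenceDensity"))
}

#' Neutral difference density
#'
#' Pointwise difference between a full density and the atomic reference
#' density. When the full density integrates to the system's valence
#' electron count, the difference integrates to zero.
#'
#' @param rho a [DensityField-class] of kind `"full"`.
#' @param rhoAtm a [DensityField-class] of kind `"atomic"` on the same grid.
#' @return a [DensityField-class] of kind `"neutral"`.
#' @export
deltaDensity <- function(rho, rhoAtm) {
  if (rho@kind != "full" || rhoAtm@kind != "atomic")
    .stopf("expected kinds full and atomic", class = "nxcrShapeError")
  if (!.sameGrid(rho@grid, rhoAtm@grid))
    .stopf("density fields live on different grids", class = "nxcrShapeError")
  new("DensityField", grid = rho@grid, values = rho@values - rhoAtm@values,
      kind = "neutral", meta = list(source = "deltaDensity"))
}
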