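#' @include model.R
NULL

## 3-D single-particle solver on a uniform box grid (hard-wall boundary):
## H = -1/2 Laplacian (7-point stencil) + Gaussian external wells + a local
## density-power mean-field term. Lowest eigenstates are found with ARPACK;
## orbitals are occupied one electron each (spinless). Small by design, but
## the projector/potential code paths it exercises are the real 3-D ones.

#' Construct a toy model system
#'
#' @param species character vector, one label per well ("atom").
#' @param positions n x 3 matrix of well centers, Bohr.
#' @param depth numeric, well depths (Hartree, > 0).
#' @param width numeric, Gaussian well widths (Bohr).
#' @param nElectrons integer electron count (spinless occupancy).
#' @param boxLength numeric box edge, Bohr.
#' @param nGrid integer voxels per edge (<= 64).
#' @param baselineCoeff coefficient of the baseline functional
#'   `E = coeff * integral rho^(4/3)` (Hartree Bohr^(4) units); its analytic
#'   functional derivative `(4/3) coeff rho^(1/3)` enters the potential.
#' @param valences named valence charges per species (for projection and
#'   moments).
#' @param boxCenter optional box center, Bohr; defaults to the centroid of
#'   the well positions. Fixing it lets different systems share an
#'   identical grid (e.g. for separability comparisons).
#' @return a [ToySystem-class].
#' @export
toySystem <- function(species, positions, depth, width, nElectrons = 1L,
                      boxLength = 12, nGrid = 16L, baselineCoeff = 0.05,
                      valences = NULL, boxCenter = NULL) {
  positions <- as.matrix(positions)
  nA <- nrow(positions)
  if (is.null(valences))
    valences <- stats::setNames(rep(1, length(unique(species))),
                                unique(species))
  sys <- atomicSystem(species, positions, valences)
  grid <- boxGrid(boxCenter %||% colMeans(positions), boxLength,
                  as.integer(nGrid))
  new("ToySystem", system = sys,
      depth = rep_len(as.numeric(depth), nA),
      width = rep_len(as.numeric(width), nA),
      nElectrons = as.integer(nElectrons), grid = grid,
      baselineCoeff = baselineCoeff)
}

## external potential of the Gaussian wells on the grid
.externalPotential <- function(ts) {
  v <- numeric(nGridPoints(ts@grid))
  for (a in seq_len(nAtoms(ts@system))) {
    d2 <- rowSums(sweep(ts@grid@points, 2L, ts@system@positions[a, ])^2)
    v <- v - ts@depth[a] * exp(-d2 / (2 * ts@width[a]^2))
  }
  v
}

## baseline local functional and its derivative
.baselineEnergy <- function(ts, rho)
  ts@baselineCoeff * sum(ts@grid@weights * rho^(4 / 3))
.baselinePotential <- function(ts, rho)
  (4 / 3) * ts@baselineCoeff * rho^(1 / 3)

## run expr under a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## lowest nev eigenpairs of -1/2 lap + v by ARPACK; ARPACK's random starting
## vector is drawn from the R RNG, so a fixed per-call seed makes every
## diagonalization (and hence the whole mixing path) bitwise reproducible
.lowestStates <- function(v, dims, h, nev, seedTag = 0L) {
  n1 <- dims[1L]; n2 <- dims[2L]; n3 <- dims[3L]
  N <- n1 * n2 * n3
  ih2 <- 1 / h^2
  matvec <- function(x, extra = NULL) {
    a <- array(x, dim = c(n3, n2, n1))  # third grid axis varies fastest
    lap <- -6 * a
    lap[-1, , ] <- lap[-1, , ] + a[-n3, , ]
    lap[-n3, , ] <- lap[-n3, , ] + a[-1, , ]
    lap[, -1, ] <- lap[, -1, ] + a[, -n2, ]
    lap[, -n2, ] <- lap[, -n2, ] + a[, -1, ]
    lap[, , -1] <- lap[, , -1] + a[, , -n1]
    lap[, , -n1] <- lap[, , -n1] + a[, , -1]
    -0.5 * ih2 * as.vector(lap) + v * x
  }
  res <- .withSeed(90001L + seedTag, igraph::arpack(
    matvec, sym = TRUE,
    options = list(n = N, nev = nev,
                   ncv = min(N, max(4L * nev + 12L, 20L)),
                   which = "SA", maxiter = 3000, tol = 1e-9)))
  vec <- matrix(res$vectors, ncol = nev)
  ord <- order(res$values)
  list(values = res$values[ord], vectors = vec[, ord, drop = FALSE])
}

## the shared SCF loop; `correction(rho)` returns list(energy, potential) of
## an extra density functional (learned or analytic target), or NULL
.solveSCF <- function(ts, correction = NULL, mix = 0.3, tol = 1e-8,
                      maxCycles = 200L, onFail = c("error", "flag"),
                      rho0 = NULL) {
  onFail <- match.arg(onFail)
  g <- ts@grid
  w <- g@weights
  h <- g@meta$axes[1, 1]
  dims <- g@meta$dims
  vExt <- .externalPotential(ts)
  nev <- ts@nElectrons

  densityOf <- function(states) {
    phi <- states$vectors / sqrt(w[1L])  # normalize to integral 1 per orbital
    rowSums(phi[, seq_len(nev), drop = FALSE]^2)
  }
  if (is.null(rho0)) {
    ## initial guess: external potential only
    states <- .lowestStates(vExt, dims, h, nev, seedTag = 0L)
    rho <- densityOf(states)
  } else {
    rho <- rho0
  }
  residuals <- numeric(0)
  corr <- NULL
  rhoPrev <- NULL
  fPrev <- NULL
  for (cyc in seq_len(maxCycles)) {
    corr <- if (is.null(correction)) NULL else
      correction(new("DensityField", grid = g, values = rho, kind = "full",
                     meta = list()))
    vEff <- vExt + .baselinePotential(ts, rho) +
      (if (is.null(corr)) 0 else corr$potential)
    states <- .lowestStates(vEff, dims, h, nev, seedTag = cyc)
    rhoNew <- densityOf(states)
    f <- rhoNew - rho
    res <- sum(w * abs(f))
    residuals <- c(residuals, res)
    if (res < tol) { rho <- rhoNew; break }
    ## damped linear mixing accelerated by one step of Anderson
    ## extrapolation (deterministic; falls back to plain mixing when the
    ## residual difference is degenerate)
    if (!is.null(fPrev)) {
      df <- f - fPrev
      den2 <- sum(w * df * df)
      gam <- if (den2 > 1e-30) sum(w * f * df) / den2 else 0
      gam <- max(min(gam, 30), -30)
      rhoBar <- rho - gam * (rho - rhoPrev)
      fBar <- f - gam * df
      rhoPrev <- rho; fPrev <- f
      rho <- pmax(rhoBar + mix * fBar, 0)
    } else {
      rhoPrev <- rho; fPrev <- f
      rho <- rho + mix * f
    }
  }
  ok <- length(residuals) > 0 && residuals[length(residuals)] < tol
  ## re-evaluate the correction at the converged density for a consistent
  ## energy report (identical to the in-loop value within the SCF tolerance)
  if (!is.null(correction))
    corr <- correction(new("DensityField", grid = g, values = rho,
                           kind = "full", meta = list()))
  if (!ok && onFail == "error")
    .stopf(paste0("SCF did not converge in %d cycles (last residual %.3g);",
                  " a smaller mixing coefficient usually helps"),
           maxCycles, residuals[length(residuals)],
           class = "nxcrConvergenceError")
  eps <- states$values[seq_len(nev)]
  vCorr <- if (is.null(corr)) 0 else corr$potential
  eBase <- sum(eps) -
    sum(w * (.baselinePotential(ts, rho) + vCorr) * rho) +
    .baselineEnergy(ts, rho)
  energy <- eBase + (if (is.null(corr)) 0 else corr$energy)
  list(density = new("DensityField", grid = g, values = rho, kind = "full",
                     meta = list(source = "toyScf")),
       energy = energy, eBase = eBase,
       eigenvalues = eps, residuals = residuals, ok = ok,
       cycles = length(residuals))
}

#' Baseline self-consistent solve
#'
#' Occupies the lowest eigenstates of the single-particle Hamiltonian
#' (finite-difference kinetic term, Gaussian wells, baseline mean-field
#' term) under linear density mixing until the density residual
#' `integral |rho_out - rho_in|` drops below `tol` electrons.
#'
#' @param ts a [ToySystem-class].
#' @param mix linear mixing coefficient in (0, 1].
#' @param tol density residual tolerance, electrons.
#' @param maxCycles iteration cap.
#' @param onFail `"error"` to raise a convergence error carrying the
#'   residual history, `"flag"` to return with `ok = FALSE`.
#' @return list with `density` ([DensityField-class]), `energy` (Hartree),
#'   `eigenvalues`, `residuals`, `cycles`, `ok`.
#' @export
solveBaseline <- function(ts, mix = 0.3, tol = 1e-8, maxCycles = 200L,
                          onFail = "error") {
  .solveSCF(ts, NULL, mix = mix, tol = tol, maxCycles = maxCycles,
            onFail = onFail)
}

#' Self-consistent solve with a learned correction
#'
#' Runs the same SCF loop with the corrected potential: at every cycle the
#' current density is projected, the learned potential is re-assembled from
#' the model's coefficient derivatives, and added to the baseline potential.
#' On convergence the density is a fixed point of the combined potential and
#' the energy is the additive baseline + learned total. A `NULL` model
#' reproduces [solveBaseline()] exactly.
#'
#' @param ts a [ToySystem-class].
#' @param model an [EnergyModel-class] or NULL.
#' @param spec the [BasisSpec-class] the model was trained with.
#' @param rho0 optional starting density values (warm start from a previous
#'   self-consistent solve); NULL starts from the external-potential ground
#'   state.
#' @inheritParams solveBaseline
#' @return as [solveBaseline()], with `energy` the corrected total.
#' @export
solveNxc <- function(ts, model, spec, mix = 0.3, tol = 1e-8,
                     maxCycles = 200L, onFail = "error", rho0 = NULL) {
  if (is.null(model))
    return(solveBaseline(ts, mix = mix, tol = tol, maxCycles = maxCycles,
                         onFail = onFail))
  proj <- buildProjector(ts@system, spec, ts@grid)
  if (nzchar(model@basisHash) && !identical(model@basisHash, proj@basisHash))
    .stopf("model basis hash does not match the system's basis",
           class = "nxcrIntegrityError")
  correction <- function(den) {
    ev <- evaluateFunctional(model, proj, den)
    list(energy = ev$energy, potential = ev$potential@values)
  }
  .solveSCF(ts, correction, mix = mix, tol = tol, maxCycles = maxCycles,
            onFail = onFail, rho0 = rho0)
}

#' Self-consistent solve with the analytic target functional
#'
#' Adds the synthetic benchmark's analytic target functional (local density
#' power plus atom-centered squared smoothed overlaps, see
#' [targetFunctional()]) and its exact functional derivative to the
#' baseline, yielding the reference energies and densities the learned
#' correction is supposed to recover.
#'
#' @param ts a [ToySystem-class].
#' @param targetParams list as in [SyntheticSpec-class] (`aLocal`, `p`,
#'   `aNonlocal`, `sigmaNonlocal`); weight centers are the system's atoms.
#' @inheritParams solveBaseline
#' @return as [solveBaseline()].
#' @export
solveTarget <- function(ts, targetParams, mix = 0.3, tol = 1e-8,
                        maxCycles = 200L, onFail = "error") {
  centers <- ts@system@positions
  gWeights <- vapply(seq_len(nrow(centers)), function(a)
    exp(-rowSums(sweep(ts@grid@points, 2L, centers[a, ])^2) /
        (2 * targetParams$sigmaNonlocal^2)),
    numeric(nGridPoints(ts@grid)))
  correction <- function(den) {
    rho <- den@values
    w <- den@grid@weights
    ov <- drop(crossprod(gWeights, w * rho))
    eLoc <- sum(vapply(seq_along(targetParams$p), function(j)
      targetParams$aLocal[j] * sum(w * rho^targetParams$p[j]), numeric(1)))
    vLoc <- Reduce(`+`, lapply(seq_along(targetParams$p), function(j)
      targetParams$aLocal[j] * targetParams$p[j] *
        rho^(targetParams$p[j] - 1)))
    list(energy = eLoc + targetParams$aNonlocal * sum(ov^2),
         potential = vLoc + 2 * targetParams$aNonlocal *
           drop(gWeights %*% ov))
  }
  .solveSCF(ts, correction, mix = mix, tol = tol, maxCycles = maxCycles,
            onFail = onFail)
}

#' Self-consistent driver for iterative training
#'
#' Wraps a list of toy systems into the driver interface expected by
#' [iterativeTrain()]: given a model (or NULL for the baseline) it returns
#' the self-consistent density and corrected energy per system, flagging
#' non-converged solves instead of failing.
#'
#' @param toySystems list of [ToySystem-class], aligned with the training
#'   samples.
#' @param spec the [BasisSpec-class].
#' @param mix,tol,maxCycles SCF settings, see [solveBaseline()].
#' @return function(model, samples) -> list of per-sample results.
#' @export
makeToyScfDriver <- function(toySystems, spec, mix = 0.3, tol = 1e-8,
                             maxCycles = 200L) {
  force(toySystems); force(spec)
  function(model, samples) {
    lapply(seq_along(samples), function(i) {
      ts <- toySystems[[i]]
      den <- samples[[i]]@density
      rho0 <- if (length(den@values) == nGridPoints(ts@grid)) den@values
              else NULL
      solveNxc(ts, model, spec, mix = mix, tol = tol,
               maxCycles = maxCycles, onFail = "flag", rho0 = rho0)
    })
  }
}
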