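#' @include training.R scf.R
NULL

## Deterministic synthetic benchmark: seeded geometries, closed-form
## anisotropic-Gaussian valence densities, a baseline energy from the toy
## solver's local functional, and reference energies from a known analytic
## target functional. Plays the role of an external reference dataset so
## that training, cross-validation and iterative training run end to end
## with no downloads. It emulates smooth valence densities responding to
## geometric deformation -- not core cusps, shell structure or any published
## dataset's distribution.

#' Synthetic benchmark specification
#'
#' The default conditions: a three-well "molecule" (one heavy, two light
#' centers) with seeded geometric deformation, per-atom anisotropic Gaussian
#' densities normalized to the species' valence charges, a clean (noise-free)
#' reference, and a target functional mixing a local density power with a
#' squared smoothed-overlap term. The nonlocal term makes the target
#' deliberately not linear in the power-spectrum invariants, so nonzero
#' network depth is required to recover it.
#'
#' @param seed integer master seed.
#' @param speciesPattern character vector of species labels.
#' @param basePositions matrix of undeformed positions, Bohr. Defaults keep
#'   every pair of cutoff spheres disjoint under the default deformation.
#' @param valences named valence charges.
#' @param deformAmplitude per-coordinate deformation s.d., Bohr.
#' @param widthRange range of base Gaussian widths, Bohr.
#' @param anisotropyRange range of per-axis width scaling factors.
#' @param targetParams list: `aLocal`, `p`, `aNonlocal`, `sigmaNonlocal`.
#' @param noiseSd reference-energy noise s.d., Hartree (0 = clean recovery;
#'   a small positive value exercises regularization and gamma selection).
#' @return a [SyntheticSpec-class].
#' @export
syntheticSpec <- function(seed = 1L,
                          speciesPattern = c("O", "H", "H"),
                          basePositions = rbind(c(0, 0, 0),
                                                c(5.6, 0, 0),
                                                c(-2.8, 4.85, 0)),
                          valences = c(O = 6, H = 1),
                          deformAmplitude = 0.15,
                          widthRange = c(0.5, 1.1),
                          anisotropyRange = c(0.75, 1.3),
                          targetParams = list(aLocal = c(0.05, 0.02),
                                              p = c(4 / 3, 3),
                                              aNonlocal = 0.25,
                                              sigmaNonlocal = 1.1),
                          noiseSd = 0) {
  new("SyntheticSpec", speciesPattern = speciesPattern,
      basePositions = as.matrix(basePositions), valences = valences,
      deformAmplitude = deformAmplitude, widthRange = widthRange,
      anisotropyRange = anisotropyRange, targetParams = targetParams,
      noiseSd = noiseSd, seed = as.integer(seed))
}

## per-(seed, index, stream) deterministic seeding, kept below 2^31
.subSeed <- function(seed, index, stream)
  (as.numeric(seed) * 48271 + index * 9973 + stream * 127) %% 2147483629

#' Hash of a synthetic specification
#' @param spec a [SyntheticSpec-class].
#' @return character md5 digest.
#' @export
syntheticHash <- function(spec) {
  .hashString(paste(
    paste(spec@speciesPattern, collapse = ","),
    paste(format(spec@basePositions, digits = 17), collapse = ","),
    paste(names(spec@valences), spec@valences, collapse = ","),
    format(c(spec@deformAmplitude, spec@widthRange, spec@anisotropyRange,
             unlist(spec@targetParams), spec@noiseSd), digits = 17),
    spec@seed, sep = "|"))
}

#' Generate the index-th geometry
#'
#' Base geometry plus a seeded Gaussian deformation of every coordinate;
#' identical (seed, index) pairs give bitwise-identical systems.
#'
#' @param spec a [SyntheticSpec-class].
#' @param index positive integer sample index.
#' @return an [AtomicSystem-class].
#' @export
generateSystem <- function(spec, index) {
  set.seed(.subSeed(spec@seed, index, 1L))
  nA <- length(spec@speciesPattern)
  pos <- spec@basePositions +
    spec@deformAmplitude * matrix(stats::rnorm(3 * nA), nA, 3)
  atomicSystem(spec@speciesPattern, pos, spec@valences)
}

## closed-form anisotropic Gaussian mixture evaluation
.gaussianMixture <- function(points, gs) {
  v <- numeric(nrow(points))
  for (g in gs) {
    d <- sweep(points, 2L, g$center)
    q <- rowSums((d %*% g$precision) * d)
    v <- v + g$norm * exp(-0.5 * q)
  }
  v
}

#' Seeded density parameters for a system
#'
#' One anisotropic Gaussian per atom: base width drawn from `widthRange`,
#' per-axis scalings from `anisotropyRange`, a random orientation, and a
#' normalization fixing the atom's integral to its valence charge.
#'
#' @param system an [AtomicSystem-class].
#' @param spec a [SyntheticSpec-class].
#' @param index sample index (same substream as the density draw).
#' @return list of per-atom Gaussian parameters (`center`, `precision`,
#'   `norm`, `valence`, `sigmas`, `axes`).
#' @export
densityParams <- function(system, spec, index) {
  set.seed(.subSeed(spec@seed, index, 2L))
  lapply(seq_len(nAtoms(system)), function(a) {
    v <- spec@valences[[system@species[a]]]
    sig <- stats::runif(1, spec@widthRange[1], spec@widthRange[2]) *
      stats::runif(3, spec@anisotropyRange[1], spec@anisotropyRange[2])
    R <- randomRotation()
    prec <- R %*% diag(1 / sig^2) %*% t(R)
    list(center = system@positions[a, ], precision = prec,
         norm = v / ((2 * pi)^1.5 * prod(sig)), valence = v,
         sigmas = sig, axes = R)
  })
}

#' Rigidly transform density parameters
#'
#' Rotates/reflects and shifts a Gaussian-mixture density covariantly with
#' its geometry (centers move, precision matrices conjugate).
#'
#' @param gs list from [densityParams()].
#' @param rotation 3 x 3 orthogonal matrix.
#' @param shift numeric length-3, Bohr.
#' @return transformed parameter list.
#' @export
transformDensityParams <- function(gs, rotation = diag(3),
                                   shift = c(0, 0, 0)) {
  lapply(gs, function(g) {
    g$center <- drop(rotation %*% g$center) + as.numeric(shift)
    g$precision <- rotation %*% g$precision %*% t(rotation)
    if (!is.null(g$axes)) g$axes <- rotation %*% g$axes
    g
  })
}

#' Generate the index-th density field
#'
#' Evaluates the seeded Gaussian-mixture density on a grid. The analytic
#' parameters travel in the field's `meta$gaussians`, so descriptor
#' computation can re-evaluate the closed form on tighter quadratures.
#'
#' @param system the matching [AtomicSystem-class] from [generateSystem()].
#' @param spec a [SyntheticSpec-class].
#' @param index sample index.
#' @param grid a [Grid-class] to tabulate on.
#' @return a [DensityField-class] of kind `"full"`.
#' @export
generateDensity <- function(system, spec, index, grid) {
  gs <- densityParams(system, spec, index)
  den <- evaluateOnGrid(function(p) .gaussianMixture(p, gs), grid,
                        kind = "full",
                        meta = list(gaussians = gs, index = index))
  if (any(den@values < 0)) .stopf("negative synthetic density",
                                  class = "nxcrSpecError")
  den
}

#' Analytic target functional
#'
#' The known nonlinear functional the synthetic reference energies derive
#' from: a mixture of local density powers plus atom-centered squared
#' smoothed overlaps,
#' `sum_j aLocal_j integral rho^p_j + aNonlocal * sum_a (integral rho g_a)^2`,
#' where `g_a` is a Gaussian weight of width `sigmaNonlocal` centered at
#' atom a (`params$centers`). Both terms decompose over atoms (so an
#' additive per-atom model can represent them), but the squared overlaps
#' are quadratic in the projection coefficients with cross-radial products,
#' hence not expressible as a linear function of the power-spectrum
#' invariants: network depth is required.
#'
#' @param density a [DensityField-class] on a grid covering the density.
#' @param params list with `aLocal`, `p`, `aNonlocal`, `sigmaNonlocal` and
#'   `centers` (matrix of weight centers; a single `center` is accepted).
#' @return scalar reference-energy contribution, Hartree.
#' @export
targetFunctional <- function(density, params) {
  w <- density@grid@weights
  rho <- density@values
  centers <- params$centers %||% rbind(params$center %||% c(0, 0, 0))
  eNl <- 0
  for (a in seq_len(nrow(centers))) {
    gw <- exp(-rowSums(sweep(density@grid@points, 2L, centers[a, ])^2) /
              (2 * params$sigmaNonlocal^2))
    eNl <- eNl + sum(w * rho * gw)^2
  }
  eLoc <- sum(vapply(seq_along(params$p), function(j)
    params$aLocal[j] * sum(w * pmax(rho, 0)^params$p[j]), numeric(1)))
  eLoc + params$aNonlocal * eNl
}

#' Generate a synthetic delta-learning dataset
#'
#' For each index: seeded geometry, seeded Gaussian density on a shared box
#' grid, baseline energy from the toy solver's local baseline functional
#' evaluated on that density, and reference energy
#' `eRef = eBase + target + noise`. A manifest (seed, spec hash, n, grid
#' settings) is attached as an attribute. Regeneration from the same spec is
#' bitwise identical.
#'
#' @param spec a [SyntheticSpec-class].
#' @param n number of samples (0 gives an empty dataset with a manifest).
#' @param boxLength,nGrid shared integration grid settings; the defaults
#'   cover the deformed geometries to beyond four Gaussian widths at a
#'   spacing resolving the narrowest density width.
#' @param baselineCoeff coefficient of the baseline local functional.
#' @param keepDensity logical; `FALSE` replaces the stored field by a
#'   one-point stub (the analytic parameters remain in `meta`), saving
#'   memory for large n.
#' @return list of [TrainingSample-class] with a `manifest` attribute.
#' @export
generateDataset <- function(spec, n, boxLength = 22, nGrid = 52L,
                            baselineCoeff = 0.05, keepDensity = TRUE) {
  center0 <- colMeans(spec@basePositions)
  grid <- boxGrid(center0, boxLength, nGrid)
  stubGrid <- boxGrid(center0, boxLength, 1L)
  samples <- vector("list", n)
  for (i in seq_len(n)) {
    sys <- generateSystem(spec, i)
    den <- generateDensity(sys, spec, i, grid)
    eBase <- baselineCoeff * sum(grid@weights * den@values^(4 / 3))
    tp <- spec@targetParams
    tp$centers <- sys@positions
    eT <- targetFunctional(den, tp)
    set.seed(.subSeed(spec@seed, i, 3L))
    noise <- if (spec@noiseSd > 0) stats::rnorm(1, sd = spec@noiseSd) else 0
    stored <- if (keepDensity) den else
      new("DensityField", grid = stubGrid,
          values = den@values[1L], kind = "full", meta = den@meta)
    samples[[i]] <- trainingSample(sys, stored, eBase, eBase + eT + noise)
  }
  attr(samples, "manifest") <- list(
    seed = spec@seed, specHash = syntheticHash(spec), n = n,
    boxLength = boxLength, nGrid = as.integer(nGrid),
    baselineCoeff = baselineCoeff, noiseSd = spec@noiseSd)
  samples
}

#' Toy self-consistency benchmark
#'
#' Seeded two-well systems for the iterative-training loop: baseline
#' densities and energies from [solveBaseline()], reference energies from
#' [solveTarget()] (the analytic target functional solved self-consistently,
#' so the reference densities genuinely differ from the baseline ones).
#'
#' @param n number of systems.
#' @param seed integer seed.
#' @param targetParams analytic target settings (see [solveTarget()]).
#' @param nGrid,boxLength solver grid settings.
#' @param mix,tol SCF settings.
#' @return list with `samples` (baseline [TrainingSample-class] list),
#'   `toySystems`, `targetParams`, `eTrue` (reference SCF energies).
#' @export
makeToyBenchmark <- function(n, seed = 1L,
                             targetParams = list(aLocal = 0.1, p = 4 / 3,
                                                 aNonlocal = 0.04,
                                                 sigmaNonlocal = 1.5),
                             nGrid = 16L, boxLength = 12, mix = 0.6,
                             tol = 1e-8) {
  systems <- vector("list", n)
  samples <- vector("list", n)
  eTrue <- numeric(n)
  for (i in seq_len(n)) {
    set.seed(.subSeed(seed, i, 4L))
    sep <- stats::runif(1, 3.2, 4.4)
    depth <- stats::runif(2, 1.0, 1.6)
    width <- stats::runif(2, 0.9, 1.2)
    off <- stats::rnorm(3, sd = 0.15)
    pos <- rbind(c(-sep / 2, 0, 0), c(sep / 2, 0, 0))
    pos <- sweep(pos, 2L, -off)
    ts <- toySystem(c("A", "A"), pos, depth, width, nElectrons = 2L,
                    boxLength = boxLength, nGrid = nGrid)
    base <- solveBaseline(ts, mix = mix, tol = tol)
    ref <- solveTarget(ts, targetParams, mix = mix, tol = tol)
    systems[[i]] <- ts
    eTrue[i] <- ref$energy
    samples[[i]] <- trainingSample(ts@system, base$density,
                                   eBase = base$energy, eRef = ref$energy)
  }
  list(samples = samples, toySystems = systems,
       targetParams = targetParams, eTrue = eTrue)
}
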