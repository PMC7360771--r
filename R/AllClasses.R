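## Central S4 containers. Structural invariants live in validity() methods;
## quantitative contracts that depend on grid coverage (electron counts,
## neutrality of difference densities) are enforced by exported checks so that
## fields restricted to partial grids remain representable.

#' @import methods
NULL

#' Quadrature grid in real space
#'
#' Holds quadrature nodes and weights for three-dimensional integration,
#' either a uniform voxel grid (cube-file style) or an atom-centered
#' Gauss--Legendre x spherical product rule. Integrals of a field `f` are
#' evaluated as `sum(weights * f)`.
#'
#' @slot points numeric matrix (n x 3), node coordinates in Bohr.
#' @slot weights numeric vector of positive quadrature weights in Bohr^3.
#' @slot periodic logical flag; `TRUE` for periodic cells.
#' @slot cell 3 x 3 matrix of lattice vectors (rows), Bohr; used when periodic.
#' @slot meta list of backend metadata (voxel shape, origin, axes, per-atom
#'   point ranges for atom-centered rules).
#' @export
setClass("Grid", representation(
  points   = "matrix",
  weights  = "numeric",
  periodic = "logical",
  cell     = "matrix",
  meta     = "list"
))

setValidity("Grid", function(object) {
  if (ncol(object@points) != 3L) return("points must be an n x 3 matrix")
  if (nrow(object@points) != length(object@weights))
    return("points and weights disagree in length")
  if (any(!is.finite(object@points))) return("non-finite grid points")
  if (any(object@weights <= 0)) return("all quadrature weights must be > 0")
  if (object@periodic && !all(dim(object@cell) == c(3L, 3L)))
    return("periodic grids require a 3 x 3 cell matrix")
  TRUE
})

#' Molecular geometry with species labels
#'
#' @slot species character vector of element labels, one per atom.
#' @slot positions numeric matrix (n x 3) of nuclear positions in Bohr.
#' @slot valenceCharges named numeric vector mapping species to the number of
#'   valence electrons used for reference densities and nuclear moments.
#' @export
setClass("AtomicSystem", representation(
  species        = "character",
  positions      = "matrix",
  valenceCharges = "numeric"
))

setValidity("AtomicSystem", function(object) {
  if (nrow(object@positions) != length(object@species))
    return("species list and position list must have the same length")
  if (ncol(object@positions) != 3L) return("positions must be n x 3")
  if (any(!is.finite(object@positions))) return("positions must be finite")
  TRUE
})

#' Atom-centered basis specification
#'
#' Per-species parameters of the radial x spherical-harmonic projection basis:
#' number of radial functions `nMax`, maximum angular momentum `lMax`, and the
#' outer cutoff radius `rO` (Bohr) beyond which every basis function vanishes.
#' The inner cutoff radius is fixed to zero.
#'
#' @slot species character vector of species covered by the basis.
#' @slot nMax integer vector, radial functions per species (>= 1).
#' @slot lMax integer vector, maximum angular momentum per species (>= 0).
#' @slot rO numeric vector, outer cutoff radii in Bohr (> 0).
#' @export
setClass("BasisSpec", representation(
  species = "character",
  nMax    = "integer",
  lMax    = "integer",
  rO      = "numeric"
))

setValidity("BasisSpec", function(object) {
  k <- length(object@species)
  if (length(object@nMax) != k || length(object@lMax) != k ||
      length(object@rO) != k)
    return("per-species fields must be parallel to species")
  if (anyDuplicated(object@species)) return("duplicate species in basis spec")
  if (any(object@nMax < 1L)) return("nMax must be >= 1")
  if (any(object@lMax < 0L)) return("lMax must be >= 0")
  if (any(object@rO <= 0)) return("rO must be > 0")
  TRUE
})

#' Electron density (or density difference) on a grid
#'
#' @slot grid a [Grid-class] carrying the quadrature.
#' @slot values numeric vector of density values, electrons / Bohr^3.
#' @slot kind one of `"full"` (electron density), `"neutral"` (difference
#'   density integrating to zero), `"atomic"` (superposed atomic reference).
#' @slot meta list; analytic parameters when the field was generated from a
#'   closed-form model, provenance otherwise.
#' @export
setClass("DensityField", representation(
  grid   = "Grid",
  values = "numeric",
  kind   = "character",
  meta   = "list"
))

setValidity("DensityField", function(object) {
  if (length(object@values) != nrow(object@grid@points))
    return("values must align with grid points")
  if (!object@kind %in% c("full", "neutral", "atomic"))
    return("kind must be one of 'full', 'neutral', 'atomic'")
  if (any(!is.finite(object@values))) return("non-finite density values")
  TRUE
})

#' Tabulated atom-centered projection basis
#'
#' Orthonormal basis functions psi_nlm(r - R_I) = Y_lm(theta, phi) zeta_n(r)
#' tabulated on a grid, with the composite index beta running over
#' (atom, n, l, m) in canonical order (atom index, n ascending, l ascending,
#' m from -l to l). Shared by density projection and potential assembly.
#'
#' @slot system the [AtomicSystem-class] the basis is centered on.
#' @slot spec the [BasisSpec-class].
#' @slot grid the [Grid-class] the basis is tabulated on.
#' @slot orthoCoeffs named list (per species) of Loewdin orthogonalization
#'   matrices mapping raw radial functions to orthonormal ones.
#' @slot atoms list, one entry per atom: `idx` (grid-point indices inside the
#'   cutoff sphere) and `psi` (matrix, length(idx) x basis functions of that
#'   atom) plus that atom's beta range.
#' @slot betaMap data.frame with columns beta, atom, species, n, l, m.
#' @slot basisHash character digest identifying (system species set, spec).
#' @export
setClass("ProjectionOperator", representation(
  system      = "AtomicSystem",
  spec        = "BasisSpec",
  grid        = "Grid",
  orthoCoeffs = "list",
  atoms       = "list",
  betaMap     = "data.frame",
  basisHash   = "character"
))

#' Per-atom density descriptors
#'
#' Projection coefficients `c_nlm` per atom and their rotation/reflection
#' invariant power spectrum `d_nl = sum_m c_nlm^2`.
#'
#' @slot coefficients list, per atom, of named numeric vectors c_nlm.
#' @slot invariants list, per atom, of named numeric vectors d_nl (may be
#'   empty until [symmetrize()] is called).
#' @slot species character vector, one label per atom.
#' @slot betaMap data.frame as in [ProjectionOperator-class].
#' @slot basisHash character digest for integrity checks against a model.
#' @export
setClass("DescriptorSet", representation(
  coefficients = "list",
  invariants   = "list",
  species      = "character",
  betaMap      = "data.frame",
  basisHash    = "character"
))

setValidity("DescriptorSet", function(object) {
  if (length(object@coefficients) != length(object@species))
    return("one coefficient block per atom required")
  if (length(object@invariants) &&
      length(object@invariants) != length(object@species))
    return("invariants, when present, must align with atoms")
  TRUE
})

#' Machine-learned energy functional
#'
#' Per-species preprocessing pipeline (variance mask, shift/scale,
#' principal-axis rotation with explained-variance truncation) followed by a
#' per-species feed-forward atomic network with sigmoid hidden layers and a
#' linear output. The total energy is the sum of atomic outputs, which makes
#' it invariant under permutations of same-species atoms by construction.
#'
#' @slot species character vector of species the model covers.
#' @slot pipelines named list per species: `mask`, `center`, `scale`,
#'   `rotation` (columns are retained principal axes), `inputDim`.
#' @slot networks named list per species: list of layers, each with `W`, `b`,
#'   `activation` ("sigmoid" or "linear") and `frozen` flag.
#' @slot useDelta logical; `TRUE` when the model expects descriptors of the
#'   neutral difference density rather than the full density.
#' @slot basisHash character digest of the basis the model was trained with.
#' @slot meta list (training history, config hash, seeds).
#' @export
setClass("EnergyModel", representation(
  species   = "character",
  pipelines = "list",
  networks  = "list",
  useDelta  = "logical",
  basisHash = "character",
  meta      = "list"
))

setValidity("EnergyModel", function(object) {
  if (!all(object@species %in% names(object@networks)))
    return("every species needs an atomic network")
  if (!all(object@species %in% names(object@pipelines)))
    return("every species needs a preprocessing pipeline")
  TRUE
})

#' Functional-derivative potential on a grid
#'
#' The learned potential is a linear combination of the projection basis,
#' `V(r) = sum_beta w_beta psi_beta(r)`; both the coefficient vector and the
#' tabulated values are stored.
#'
#' @slot grid the [Grid-class].
#' @slot values numeric vector, Hartree per (electron / Bohr^3).
#' @slot coefficients numeric vector w_beta over the projector's beta index.
#' @slot betaMap data.frame as in [ProjectionOperator-class].
#' @export
setClass("PotentialField", representation(
  grid         = "Grid",
  values       = "numeric",
  coefficients = "numeric",
  betaMap      = "data.frame"
))

#' Model system for the toy self-consistent solver
#'
#' A few Gaussian external potential wells in a hard-wall box, with a local
#' density-power baseline functional. Serves as a stand-in host code so that
#' the potential pathway and iterative training can be exercised end to end.
#'
#' @slot system an [AtomicSystem-class] giving well centers and species.
#' @slot depth numeric vector, well depths (Hartree, > 0) per atom.
#' @slot width numeric vector, Gaussian well widths (Bohr) per atom.
#' @slot nElectrons integer, number of (spinless) electrons.
#' @slot grid uniform [Grid-class] the solver works on.
#' @slot baselineCoeff numeric, coefficient of the baseline density-power
#'   functional `E = coeff * integral rho^(4/3)`.
#' @export
setClass("ToySystem", representation(
  system        = "AtomicSystem",
  depth         = "numeric",
  width         = "numeric",
  nElectrons    = "integer",
  grid          = "Grid",
  baselineCoeff = "numeric"
))

setValidity("ToySystem", function(object) {
  nA <- length(object@system@species)
  if (length(object@depth) != nA || length(object@width) != nA)
    return("depth and width must have one entry per atom")
  if (object@nElectrons < 1L) return("electron count must be positive")
  if (any(object@depth <= 0) || any(object@width <= 0))
    return("well depths and widths must be positive")
  TRUE
})

#' Delta-learning training sample
#'
#' A (geometry, density, baseline energy, reference energy) triplet plus an
#' optional cached [DescriptorSet-class].
#'
#' @slot system [AtomicSystem-class].
#' @slot density [DensityField-class] (baseline self-consistent or synthetic).
#' @slot eBase numeric baseline total energy, Hartree.
#' @slot eRef numeric reference total energy, Hartree.
#' @slot descriptors ANY; a cached DescriptorSet or NULL.
#' @export
setClass("TrainingSample", representation(
  system      = "AtomicSystem",
  density     = "DensityField",
  eBase       = "numeric",
  eRef        = "numeric",
  descriptors = "ANY"
))

#' Synthetic benchmark specification
#'
#' Deterministic generator settings for model geometries, closed-form
#' densities, baseline energies and reference energies derived from a known
#' analytic target functional.
#'
#' @slot speciesPattern character vector of species for the base geometry.
#' @slot basePositions numeric matrix (n x 3), Bohr, undeformed geometry.
#' @slot valences named numeric vector of valence charges per species.
#' @slot deformAmplitude numeric, per-coordinate Gaussian deformation s.d.
#'   (Bohr).
#' @slot widthRange numeric length-2, range of Gaussian density widths (Bohr).
#' @slot anisotropyRange numeric length-2, range of axis-scaling factors
#'   applied to the per-atom Gaussians.
#' @slot targetParams list with elements `aLocal`, `p`, `aNonlocal`,
#'   `sigmaNonlocal` parameterizing the analytic target functional.
#' @slot noiseSd numeric, Gaussian noise s.d. added to reference energies
#'   (Hartree); 0 for clean recovery.
#' @slot seed integer master seed.
#' @export
setClass("SyntheticSpec", representation(
  speciesPattern  = "character",
  basePositions   = "matrix",
  valences        = "numeric",
  deformAmplitude = "numeric",
  widthRange      = "numeric",
  anisotropyRange = "numeric",
  targetParams    = "list",
  noiseSd         = "numeric",
  seed            = "integer"
))

setValidity("SyntheticSpec", function(object) {
  if (nrow(object@basePositions) != length(object@speciesPattern))
    return("basePositions must align with speciesPattern")
  if (object@deformAmplitude < 0) return("deformAmplitude must be >= 0")
  if (any(object@widthRange <= 0)) return("density widths must be positive")
  if (object@noiseSd < 0) return("noiseSd must be >= 0")
  TRUE
})
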