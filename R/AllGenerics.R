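#' @include AllClasses.R
NULL

#' Integrate a field over its quadrature grid
#'
#' @param x a [DensityField-class], [PotentialField-class], or numeric vector.
#' @param grid a [Grid-class]; required when `x` is a bare numeric vector.
#' @return the quadrature integral, a scalar.
#' @export
setGeneric("integrateField", function(x, grid) standardGeneric("integrateField"))

#' Number of atoms of an object
#' @param x an object with atomic structure.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))

#' Species labels of an object
#' @param x an object with atomic structure.
#' @return character vector of element labels.
#' @export
setGeneric("speciesOf", function(x) standardGeneric("speciesOf"))

#' Project a density onto the atom-centered basis
#'
#' Computes the projection coefficients `c_beta = integral rho(r) psi_beta(r)`
#' by grid quadrature, one coefficient block per atom.
#'
#' @param projector a [ProjectionOperator-class].
#' @param density a [DensityField-class] on the same grid.
#' @return a [DescriptorSet-class] with coefficients filled in (invariants
#'   are added by [symmetrize()]).
#' @export
setGeneric("projectDensity",
           function(projector, density) standardGeneric("projectDensity"))

#' Reduce projection coefficients to rotation invariants
#'
#' Applies the power-spectrum contraction `d_nl = sum_m c_nlm^2`, which is
#' invariant under any rotation or reflection of density and geometry.
#'
#' @param x a [DescriptorSet-class] (or per-atom coefficient vector, see
#'   [symmetrizeBlock()]).
#' @return the input with the `invariants` slot filled.
#' @export
setGeneric("symmetrize", function(x) standardGeneric("symmetrize"))

#' Energy of the learned functional
#'
#' Sum over atoms of the per-species atomic network applied to that atom's
#' preprocessed invariants.
#'
#' @param model an [EnergyModel-class].
#' @param descriptors a [DescriptorSet-class] with invariants present.
#' @return scalar energy in Hartree.
#' @export
setGeneric("modelEnergy",
           function(model, descriptors) standardGeneric("modelEnergy"))

#' Gradient of the learned energy with respect to raw invariants
#'
#' Exact analytic gradient back through principal-axis truncation, scaling
#' and variance masking (the pipeline is affine plus an orthogonal
#' projection, so the gradient is computed in closed form).
#'
#' @param model an [EnergyModel-class].
#' @param descriptors a [DescriptorSet-class] with invariants present.
#' @return list, per atom, of named numeric vectors dE/dd_nl.
#' @export
setGeneric("modelGradient",
           function(model, descriptors) standardGeneric("modelGradient"))
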