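#' @include network.R
NULL

#' Construct an energy model
#'
#' Bundles per-species preprocessing pipelines and atomic networks into the
#' learned energy functional. Identity pipelines (no masking, centering or
#' truncation) can be requested for analytically transparent models.
#'
#' @param species character vector of species.
#' @param pipelines named list of pipelines (see [fitPipeline()]); one per
#'   species.
#' @param networks named list of networks (see [makeNetwork()]).
#' @param useDelta logical; model expects descriptors of the neutral
#'   difference density rather than the full density.
#' @param basisHash character digest of the basis the model belongs to.
#' @param meta list of provenance (training history, config hash).
#' @return an [EnergyModel-class].
#' @export
energyModel <- function(species, pipelines, networks, useDelta = TRUE,
                        basisHash = "", meta = list()) {
  new("EnergyModel", species = species, pipelines = pipelines,
      networks = networks, useDelta = useDelta, basisHash = basisHash,
      meta = meta)
}

#' Identity preprocessing pipeline
#'
#' @param inputDim integer feature count.
#' @return a pipeline that passes features through unchanged.
#' @export
identityPipeline <- function(inputDim) {
  list(mask = rep(TRUE, inputDim), center = numeric(inputDim),
       scale = rep(1, inputDim), rotation = diag(inputDim),
       inputDim = inputDim, explained = 1)
}

.checkCoverage <- function(model, descriptors) {
  unk <- setdiff(unique(descriptors@species), model@species)
  if (length(unk))
    .stopf("model does not cover species: %s", paste(unk, collapse = ", "),
           class = "nxcrCoverageError")
  if (nzchar(model@basisHash) && nzchar(descriptors@basisHash) &&
      !identical(model@basisHash, descriptors@basisHash))
    .stopf("basis hash mismatch between model and descriptors",
           class = "nxcrIntegrityError")
  invisible(TRUE)
}

#' @describeIn modelEnergy sum of per-species atomic network outputs.
#' @export
setMethod("modelEnergy", signature("EnergyModel", "DescriptorSet"),
  function(model, descriptors) {
    .checkCoverage(model, descriptors)
    if (!length(descriptors@invariants))
      descriptors <- symmetrize(descriptors)
    e <- 0
    for (s in unique(descriptors@species)) {
      im <- invariantMatrix(descriptors, s)
      Z <- applyPipeline(model@pipelines[[s]], im$X)
      e <- e + sum(.netForward(model@networks[[s]], Z)$out)
    }
    e
  })

#' @describeIn modelGradient exact per-atom gradient dE/dd_nl.
#' @export
setMethod("modelGradient", signature("EnergyModel", "DescriptorSet"),
  function(model, descriptors) {
    .checkCoverage(model, descriptors)
    if (!length(descriptors@invariants))
      descriptors <- symmetrize(descriptors)
    out <- vector("list", length(descriptors@species))
    for (s in unique(descriptors@species)) {
      im <- invariantMatrix(descriptors, s)
      Z <- applyPipeline(model@pipelines[[s]], im$X)
      dZ <- .netInputGradient(model@networks[[s]], Z)
      dX <- .pipelineBackward(model@pipelines[[s]], dZ)
      for (r in seq_along(im$atom))
        out[[im$atom[r]]] <- stats::setNames(dX[r, ],
                                             colnames(im$X))
    }
    out
  })

#' Derivatives with respect to projection coefficients
#'
#' Chains the model gradient through the power-spectrum contraction,
#' returning dE/dc_beta for every atom (the coefficients of the learned
#' potential in the projection basis).
#'
#' @param model an [EnergyModel-class].
#' @param descriptors a [DescriptorSet-class] with coefficients present.
#' @return list, per atom, of numeric vectors aligned with the beta map.
#' @export
coefficientGradient <- function(model, descriptors) {
  dEdd <- modelGradient(model, descriptors)
  lapply(seq_along(descriptors@species), function(a) {
    tab <- descriptors@betaMap[descriptors@betaMap$atom == a, , drop = FALSE]
    chainRuleBack(dEdd[[a]], descriptors@coefficients[[a]], tab)
  })
}

#' Assemble the learned potential on the grid
#'
#' Tabulates `V(r) = sum_beta w_beta psi_beta(r)` with `w_beta = dE/dc_beta`.
#' The potential vanishes identically outside the union of cutoff spheres by
#' construction.
#'
#' @param dEdc list, per atom, of dE/dc vectors (from [coefficientGradient()]).
#' @param projector the [ProjectionOperator-class] that produced the
#'   coefficients.
#' @return a [PotentialField-class].
#' @export
assemblePotential <- function(dEdc, projector) {
  if (length(dEdc) != length(projector@atoms))
    .stopf("dE/dc blocks do not match the projector's atoms",
           class = "nxcrIntegrityError")
  vals <- numeric(nGridPoints(projector@grid))
  w <- numeric(nBasis(projector))
  for (a in seq_along(projector@atoms)) {
    at <- projector@atoms[[a]]
    if (length(dEdc[[a]]) != ncol(at$psi))
      .stopf("dE/dc block %d has wrong length", a, class = "nxcrIntegrityError")
    w[at$beta] <- dEdc[[a]]
    if (length(at$idx))
      vals[at$idx] <- vals[at$idx] + drop(at$psi %*% dEdc[[a]])
  }
  new("PotentialField", grid = projector@grid, values = vals,
      coefficients = w, betaMap = projector@betaMap)
}

#' Descriptors of a density for a model
#'
#' Projects the density (or, for delta-density models, the density minus the
#' atomic reference) and symmetrizes. Because the reference field does not
#' depend on the density, the functional derivative of the coefficients is
#' the same either way and potential assembly is unchanged.
#'
#' @param projector a [ProjectionOperator-class].
#' @param density a [DensityField-class] of kind `"full"`.
#' @param useDelta logical, subtract the atomic reference before projecting.
#' @return a symmetrized [DescriptorSet-class].
#' @export
descriptorsFor <- function(projector, density, useDelta = FALSE) {
  if (useDelta) {
    rhoAtm <- atomicReferenceDensity(projector@system, projector@spec,
                                     projector@grid)
    density <- deltaDensity(density, rhoAtm)
  }
  symmetrize(projectDensity(projector, density))
}

#' Learned energy and potential of a density
#'
#' One-call evaluation of the learned correction: projection, symmetrization,
#' energy, and the analytically assembled potential.
#'
#' @param model an [EnergyModel-class].
#' @param projector a [ProjectionOperator-class] on the density's grid.
#' @param density a [DensityField-class] of kind `"full"`.
#' @return list with `energy` (Hartree), `potential`
#'   ([PotentialField-class]) and `descriptors`.
#' @export
evaluateFunctional <- function(model, projector, density) {
  ds <- descriptorsFor(projector, density, useDelta = model@useDelta)
  list(energy = modelEnergy(model, ds),
       potential = assemblePotential(coefficientGradient(model, ds), projector),
       descriptors = ds)
}

#' Compose the corrected functional with its baseline
#'
#' Additive composition: the learned energy and potential are added to their
#' baseline counterparts. With a null model the result equals the baseline
#' exactly.
#'
#' @param eBase baseline energy, Hartree.
#' @param vBase baseline potential: numeric vector or [PotentialField-class].
#' @param eML learned energy, Hartree.
#' @param vML learned potential: numeric vector or [PotentialField-class] on
#'   the same grid.
#' @return list with `energy` and `potential` (numeric vector).
#' @export
composeNxc <- function(eBase, vBase, eML, vML) {
  vb <- if (is(vBase, "PotentialField")) vBase@values else as.numeric(vBase)
  vm <- if (is(vML, "PotentialField")) vML@values else as.numeric(vML)
  if (length(vb) != length(vm))
    .stopf("baseline and learned potentials live on different grids",
           class = "nxcrShapeError")
  list(energy = eBase + eML, potential = vb + vm)
}

#' Serialize a model archive
#'
#' Writes a hierarchical archive (RDS) holding pipeline statistics, principal
#' axes, layer weights, species map, basis hash and the delta-density flag.
#' Loading restores a model whose energies are bit-identical.
#'
#' @param model an [EnergyModel-class].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = "nxcr-model", version = 1L,
               species = model@species, pipelines = model@pipelines,
               networks = model@networks, useDelta = model@useDelta,
               basisHash = model@basisHash, meta = model@meta),
          path)
  invisible(path)
}

#' @rdname saveModel
#' @return `loadModel` returns the restored [EnergyModel-class].
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "nxcr-model"))
    .stopf("not a model archive: %s", path, class = "nxcrIntegrityError")
  energyModel(x$species, x$pipelines, x$networks, x$useDelta, x$basisHash,
              x$meta)
}
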