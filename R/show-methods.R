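#' @include cli.R
NULL

setMethod("show", "Grid", function(object) {
  cat(sprintf("Grid: %d points (%s backend)%s; volume %.4f Bohr^3\n",
              nGridPoints(object), object@meta$backend %||% "custom",
              if (object@periodic) ", periodic" else "",
              sum(object@weights)))
})

setMethod("show", "AtomicSystem", function(object) {
  cat(sprintf("AtomicSystem: %d atoms (%s)\n", nAtoms(object),
              paste(object@species, collapse = " ")))
})

setMethod("show", "BasisSpec", function(object) {
  cat("BasisSpec:\n")
  for (i in seq_along(object@species))
    cat(sprintf("  %-3s nMax=%d lMax=%d rO=%.3f Bohr\n", object@species[i],
                object@nMax[i], object@lMax[i], object@rO[i]))
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf("DensityField (%s): %d points, integral %.6f e\n",
              object@kind, nGridPoints(object@grid),
              integrateField(object)))
})

setMethod("show", "ProjectionOperator", function(object) {
  cat(sprintf("ProjectionOperator: %d atoms, %d basis functions on %d grid points\n",
              length(object@atoms), nBasis(object),
              nGridPoints(object@grid)))
})

setMethod("show", "DescriptorSet", function(object) {
  cat(sprintf("DescriptorSet: %d atoms (%s), %d coefficients%s\n",
              length(object@species),
              paste(unique(object@species), collapse = " "),
              sum(lengths(object@coefficients)),
              if (length(object@invariants)) ", symmetrized" else ""))
})

setMethod("show", "EnergyModel", function(object) {
  depths <- vapply(object@networks, function(n) length(n) - 1L, integer(1))
  cat(sprintf("EnergyModel: species {%s}, hidden depth %s, %s-density input\n",
              paste(object@species, collapse = ", "),
              paste(depths, collapse = "/"),
              if (object@useDelta) "delta" else "full"))
})

setMethod("show", "PotentialField", function(object) {
  cat(sprintf("PotentialField: %d points, %d basis coefficients, max |V| %.3e Ha\n",
              nGridPoints(object@grid), length(object@coefficients),
              max(abs(object@values))))
})

setMethod("show", "ToySystem", function(object) {
  cat(sprintf("ToySystem: %d wells, %d electrons, %d grid points\n",
              nAtoms(object@system), object@nElectrons,
              nGridPoints(object@grid)))
})

setMethod("show", "TrainingSample", function(object) {
  cat(sprintf("TrainingSample: %d atoms, E_base %.6f Ha, E_ref %.6f Ha%s\n",
              nAtoms(object@system), object@eBase, object@eRef,
              if (!is.null(object@descriptors)) " (descriptors cached)"
              else ""))
})

setMethod("show", "SyntheticSpec", function(object) {
  cat(sprintf("SyntheticSpec: %d atoms (%s), deform %.3f Bohr, noise %.2e Ha, seed %d\n",
              length(object@speciesPattern),
              paste(object@speciesPattern, collapse = " "),
              object@deformAmplitude, object@noiseSd, object@seed))
})
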