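#' @include AllGenerics.R
NULL

#' Construct an atomic system
#'
#' @param species character vector of element labels.
#' @param positions n x 3 numeric matrix, Bohr.
#' @param valenceCharges named numeric vector, electrons per species.
#' @return an [AtomicSystem-class].
#' @export
atomicSystem <- function(species, positions, valenceCharges = numeric()) {
  new("AtomicSystem", species = as.character(species),
      positions = as.matrix(positions),
      valenceCharges = valenceCharges)
}

#' @describeIn atomicSystem number of atoms.
#' @param x an [AtomicSystem-class].
#' @export
setMethod("nAtoms", "AtomicSystem", function(x) length(x@species))

#' @describeIn atomicSystem species labels.
#' @export
setMethod("speciesOf", "AtomicSystem", function(x) x@species)

#' Atom positions
#' @param x an [AtomicSystem-class].
#' @return n x 3 matrix, Bohr.
#' @export
positionsOf <- function(x) x@positions

#' Rigidly transform an atomic system
#'
#' @param system an [AtomicSystem-class].
#' @param rotation 3 x 3 orthogonal matrix (may include a reflection).
#' @param shift numeric length-3 translation, Bohr.
#' @return the transformed [AtomicSystem-class].
#' @export
transformSystem <- function(system, rotation = diag(3), shift = c(0, 0, 0)) {
  p <- system@positions %*% t(rotation)
  p <- sweep(p, 2L, -as.numeric(shift))
  atomicSystem(system@species, p, system@valenceCharges)
}

#' Construct a basis specification
#'
#' @param species character vector of species.
#' @param nMax integer (scalar or per species), radial functions.
#' @param lMax integer (scalar or per species), maximum angular momentum.
#' @param rO numeric (scalar or per species), outer cutoff radius, Bohr.
#' @return a [BasisSpec-class].
#' @examples
#' basisSpec(c("O", "H"), nMax = 3, lMax = 2, rO = c(2.5, 1.8))
#' @export
basisSpec <- function(species, nMax, lMax, rO) {
  k <- length(species)
  new("BasisSpec", species = as.character(species),
      nMax = as.integer(rep_len(nMax, k)),
      lMax = as.integer(rep_len(lMax, k)),
      rO = as.numeric(rep_len(rO, k)))
}

#' Per-atom basis parameters
#'
#' Expands a [BasisSpec-class] to one row per atom of a species vector.
#'
#' @param spec a [BasisSpec-class].
#' @param species character vector of atom species labels.
#' @return list with vectors `nMax`, `lMax`, `rO` aligned with `species`.
#' @export
basisFor <- function(spec, species) {
  i <- match(species, spec@species)
  if (anyNA(i))
    .stopf("basis spec missing species: %s",
           paste(unique(species[is.na(i)]), collapse = ", "),
           class = "nxcrCoverageError")
  list(nMax = spec@nMax[i], lMax = spec@lMax[i], rO = spec@rO[i])
}

## stable content hash (md5 of a canonical string) used to tie models to the
## basis they were trained with
.hashString <- function(x) {
  tmp <- tempfile(fileext = ".txt")
  on.exit(unlink(tmp))
  writeLines(x, tmp)
  unname(tools::md5sum(tmp))
}

#' Digest of a basis specification
#'
#' Canonical hash of (species, nMax, lMax, rO) used to detect mismatches
#' between a trained model and the descriptors it is evaluated on.
#'
#' @param spec a [BasisSpec-class].
#' @return character md5 digest.
#' @export
basisHash <- function(spec) {
  o <- order(spec@species)
  .hashString(paste(spec@species[o], spec@nMax[o], spec@lMax[o],
                    format(spec@rO[o], digits = 17), sep = ":", collapse = "|"))
}

#' Random rotation matrix
#'
#' Haar-ish random proper rotation obtained from the QR decomposition of a
#' Gaussian matrix (sign-fixed, determinant +1). Uses the current RNG state.
#'
#' @return 3 x 3 rotation matrix.
#' @export
randomRotation <- function() {
  qr. <- qr(matrix(stats::rnorm(9), 3, 3))
  Q <- qr.Q(qr.)
  Q <- Q %*% diag(sign(diag(qr.R(qr.))))
  if (det(Q) < 0) Q[, 1L] <- -Q[, 1L]
  Q
}
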