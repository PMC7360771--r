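#' @include projector.R
NULL

## d_nl = sum_m c_nlm^2: the diagonal power spectrum of each m-block. This is
## the only invariant map used; cross-(n, n') or bispectrum channels are out
## of scope by design.

.nlNames <- function(tab) {
  u <- unique(tab[, c("n", "l"), drop = FALSE])
  sprintf("n%d.l%d", u[, "n"], u[, "l"])
}

#' Power-spectrum contraction of one coefficient block
#'
#' @param cvec named numeric vector of c_nlm for one atom, canonical order.
#' @param tab matrix/data.frame with columns `n`, `l`, `m` aligned to `cvec`.
#' @return named numeric vector d_nl, ordered (n ascending, l ascending).
#' @export
symmetrizeBlock <- function(cvec, tab) {
  tab <- as.matrix(tab[, c("n", "l", "m")])
  if (length(cvec) != nrow(tab))
    .stopf("coefficient block and (n, l, m) table disagree",
           class = "nxcrShapeError")
  key <- tab[, "n"] * 1000L + tab[, "l"]
  ## every (n, l) group must hold a complete m-block
  cnt <- table(key)
  expect <- 2L * tab[match(as.integer(names(cnt)), key), "l"] + 1L
  if (any(as.integer(cnt) != expect))
    .stopf("incomplete m-block in coefficients", class = "nxcrShapeError")
  d <- rowsum(cvec^2, key, reorder = FALSE)
  stats::setNames(drop(d), .nlNames(tab))
}

#' @describeIn symmetrize fill the invariants of a descriptor set.
#' @export
setMethod("symmetrize", "DescriptorSet", function(x) {
  inv <- vector("list", length(x@coefficients))
  for (a in seq_along(x@coefficients)) {
    tab <- x@betaMap[x@betaMap$atom == a, , drop = FALSE]
    inv[[a]] <- symmetrizeBlock(x@coefficients[[a]], tab)
  }
  x@invariants <- inv
  x
})

#' Back-propagate derivatives through the power spectrum
#'
#' Given dE/dd_nl, returns dE/dc_nlm = 2 (dE/dd_nl) c_nlm for one atom.
#'
#' @param dEdd named numeric vector over (n, l), as from [modelGradient()].
#' @param cvec named numeric vector of c_nlm for the same atom.
#' @param tab matrix/data.frame with columns `n`, `l`, `m` aligned to `cvec`.
#' @return numeric vector dE/dc_nlm aligned with `cvec`.
#' @export
chainRuleBack <- function(dEdd, cvec, tab) {
  tab <- as.matrix(tab[, c("n", "l", "m")])
  if (length(cvec) != nrow(tab))
    .stopf("coefficient block and (n, l, m) table disagree",
           class = "nxcrShapeError")
  nm <- sprintf("n%d.l%d", tab[, "n"], tab[, "l"])
  if (length(dEdd) != length(unique(nm)))
    .stopf("dE/dd does not match the (n, l) blocks", class = "nxcrShapeError")
  2 * dEdd[nm] * cvec
}

#' Invariant matrix for a set of atoms
#'
#' Stacks the invariant vectors of all atoms of one species into a matrix
#' (atoms x features), the layout consumed by preprocessing and training.
#'
#' @param dsets list of [DescriptorSet-class] objects (or a single one).
#' @param species species label to extract.
#' @return list with `X` (matrix), `sample` (integer vector mapping rows to
#'   the originating descriptor set) and `atom` (atom index within it).
#' @export
invariantMatrix <- function(dsets, species) {
  if (is(dsets, "DescriptorSet")) dsets <- list(dsets)
  rows <- list(); samp <- integer(); atom <- integer()
  for (i in seq_along(dsets)) {
    ds <- dsets[[i]]
    if (!length(ds@invariants)) ds <- symmetrize(ds)
    for (a in which(ds@species == species)) {
      rows[[length(rows) + 1L]] <- ds@invariants[[a]]
      samp <- c(samp, i); atom <- c(atom, a)
    }
  }
  list(X = do.call(rbind, rows), sample = samp, atom = atom)
}
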