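## Physical constants and unit conversions. Internal units are Hartree atomic
## units (Bohr, Hartree); conversions are applied only at I/O boundaries.

#' Unit conversion constants
#'
#' Named constants used at the I/O boundary. All internal computation is in
#' Hartree atomic units (lengths in Bohr, energies in Hartree).
#'
#' @format A named numeric vector with elements
#'   \describe{
#'     \item{bohrPerAngstrom}{Bohr radii per Angstrom.}
#'     \item{angstromPerBohr}{Angstrom per Bohr radius.}
#'     \item{debyePerEBohr}{Debye per (electron charge x Bohr) of dipole moment.}
#'     \item{evPerHartree}{Electronvolt per Hartree.}
#'   }
#' @export
nxcrUnits <- c(
  bohrPerAngstrom = 1 / 0.52917721067,
  angstromPerBohr = 0.52917721067,
  debyePerEBohr   = 2.541746473,
  evPerHartree    = 27.211386245988
)

## quadrupole: 1 e*Bohr^2 expressed in Debye*Angstrom
.debyeAngstromPerEBohr2 <- unname(nxcrUnits["debyePerEBohr"] *
                                  nxcrUnits["angstromPerBohr"])

.stopf <- function(fmt, ..., class = "nxcrError") {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "nxcrError")))
}

.assertFinite <- function(x, what) {
  if (!all(is.finite(x))) .stopf("non-finite values in %s", what)
  invisible(TRUE)
}
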