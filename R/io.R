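#' @include synthetic.R
NULL

.elementSymbols <- c(
  "H", "He", "Li", "Be", "B", "C", "N", "O", "F", "Ne",
  "Na", "Mg", "Al", "Si", "P", "S", "Cl", "Ar", "K", "Ca")

.symbolToZ <- function(sym) {
  z <- match(sym, .elementSymbols)
  z[is.na(z)] <- 0L  # toy species get a placeholder nuclear number
  z
}

.zToSymbol <- function(z) {
  out <- rep("X", length(z))
  ok <- z >= 1L & z <= length(.elementSymbols)
  out[ok] <- .elementSymbols[z[ok]]
  out
}

#' Read a Gaussian cube file
#'
#' Standard dialect: positive voxel counts mean Bohr units, negative counts
#' Angstrom (converted on read). Values are in cube order (first axis
#' slowest, third fastest), matching [uniformGrid()].
#'
#' @param path cube file path.
#' @return list with `density` (a [DensityField-class]) and `system`
#'   (an [AtomicSystem-class]; valence charges from the per-atom charge
#'   column).
#' @export
readCube <- function(path) {
  ln <- readLines(path)
  parseNums <- function(i, nNeeded) {
    x <- suppressWarnings(as.numeric(strsplit(trimws(ln[i]), "\\s+")[[1]]))
    if (anyNA(x) || length(x) < nNeeded)
      .stopf("malformed cube header at line %d of %s", i, path,
             class = "nxcrParseError")
    x
  }
  if (length(ln) < 7L)
    .stopf("malformed cube header at line %d of %s", length(ln), path,
           class = "nxcrParseError")
  h3 <- parseNums(3L, 4L)
  nAtomsRec <- as.integer(h3[1L])
  origin <- h3[2:4]
  ax <- lapply(4:6, function(i) parseNums(i, 4L))
  counts <- vapply(ax, function(a) as.integer(a[1L]), integer(1))
  axes <- do.call(rbind, lapply(ax, function(a) a[2:4]))
  toBohr <- if (any(counts < 0L)) nxcrUnits[["bohrPerAngstrom"]] else 1
  counts <- abs(counts)
  nAt <- abs(nAtomsRec)
  atomLines <- lapply(seq_len(nAt) + 6L, function(i) parseNums(i, 5L))
  zs <- vapply(atomLines, function(a) as.integer(a[1L]), integer(1))
  charges <- vapply(atomLines, function(a) a[2L], numeric(1))
  pos <- do.call(rbind, lapply(atomLines, function(a) a[3:5])) * toBohr
  vals <- suppressWarnings(as.numeric(unlist(
    strsplit(trimws(ln[seq.int(7L + nAt, length(ln))]), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) != prod(counts))
    .stopf("cube %s holds %d values, expected %d", path, length(vals),
           prod(counts), class = "nxcrParseError")
  grid <- uniformGrid(origin * toBohr, axes * toBohr, counts)
  species <- .zToSymbol(zs)
  valences <- tapply(charges, species, function(x) x[1L])
  sys <- atomicSystem(species, pos,
                      stats::setNames(as.numeric(valences), names(valences)))
  den <- new("DensityField", grid = grid, values = vals / toBohr^3,
             kind = "full", meta = list(source = path))
  list(density = den, system = sys)
}

#' Write a Gaussian cube file
#'
#' Writes in the Bohr dialect (positive voxel counts), `%15.6e` values, six
#' per line; round-trip relative error is bounded by the format precision.
#'
#' @param density a [DensityField-class] on a uniform grid.
#' @param system an [AtomicSystem-class].
#' @param path output path.
#' @param comment header comment.
#' @return `path`, invisibly.
#' @export
writeCube <- function(density, system, path, comment = "generated by nxcr") {
  g <- density@grid
  if (!identical(g@meta$backend, "uniform"))
    .stopf("cube output requires a uniform grid", class = "nxcrShapeError")
  dims <- g@meta$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(comment, "electron density (e/Bohr^3)"), con)
  writeLines(sprintf("%5d %11.6f %11.6f %11.6f", nAtoms(system),
                     g@meta$origin[1], g@meta$origin[2], g@meta$origin[3]),
             con)
  for (i in 1:3)
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f", dims[i],
                       g@meta$axes[i, 1], g@meta$axes[i, 2],
                       g@meta$axes[i, 3]), con)
  zs <- .symbolToZ(system@species)
  vc <- system@valenceCharges[system@species]
  vc[is.na(vc)] <- 0
  for (a in seq_len(nAtoms(system)))
    writeLines(sprintf("%5d %11.6f %11.6f %11.6f %11.6f", zs[a], vc[a],
                       system@positions[a, 1], system@positions[a, 2],
                       system@positions[a, 3]), con)
  v <- density@values
  pad <- (-length(v)) %% 6L
  vm <- matrix(c(sprintf("%15.6e", v), rep("", pad)), ncol = 6L,
               byrow = TRUE)
  writeLines(trimws(apply(vm, 1L, paste, collapse = " "), "right"), con)
  invisible(path)
}

#' Read an XYZ geometry file
#'
#' Coordinates are Angstrom on disk and converted to Bohr.
#'
#' @param path file path.
#' @param valences optional named valence charges to attach.
#' @return an [AtomicSystem-class].
#' @export
readXYZ <- function(path, valences = numeric()) {
  ln <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(ln[1L])))
  if (is.na(n)) .stopf("malformed XYZ header at line 1 of %s", path,
                       class = "nxcrParseError")
  rows <- strsplit(trimws(ln[seq_len(n) + 2L]), "\\s+")
  species <- vapply(rows, `[`, character(1), 1L)
  pos <- do.call(rbind, lapply(rows, function(r)
    as.numeric(r[2:4]))) * nxcrUnits[["bohrPerAngstrom"]]
  atomicSystem(species, pos, valences)
}

#' Write an XYZ geometry file
#'
#' @param system an [AtomicSystem-class] (positions in Bohr; written in
#'   Angstrom).
#' @param path output path.
#' @param comment second-line comment.
#' @return `path`, invisibly.
#' @export
writeXYZ <- function(system, path, comment = "") {
  p <- system@positions * nxcrUnits[["angstromPerBohr"]]
  writeLines(c(sprintf("%d", nAtoms(system)), comment,
               sprintf("%-3s %14.8f %14.8f %14.8f", system@species,
                       p[, 1], p[, 2], p[, 3])),
             path)
  invisible(path)
}

#' Read a basis specification from a config file
#'
#' YAML document mapping species to `nMax` (radial functions), `lMax`
#' (maximum angular momentum) and `rO` (cutoff radius, Bohr). Unambiguous
#' key names are deliberate: bare `n`/`y` are boolean literals in YAML.
#'
#' @param path YAML file path.
#' @return a [BasisSpec-class].
#' @export
readBasisConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!length(cfg)) .stopf("empty basis config %s", path,
                           class = "nxcrConfigError")
  sp <- names(cfg)
  get1 <- function(x, key) {
    if (is.null(x[[key]]))
      .stopf("basis config entry lacks '%s'", key, class = "nxcrConfigError")
    x[[key]]
  }
  basisSpec(sp,
            nMax = vapply(cfg, function(x) as.integer(get1(x, "nMax")),
                          integer(1)),
            lMax = vapply(cfg, function(x) as.integer(get1(x, "lMax")),
                          integer(1)),
            rO = vapply(cfg, function(x) as.numeric(get1(x, "rO")),
                        numeric(1)))
}

#' Descriptor archive round trip
#'
#' Stores descriptor sets hierarchically (one entry per structure, per-atom
#' blocks within) together with the beta index map and basis hash for
#' integrity checking on load.
#'
#' @param dsets list of [DescriptorSet-class].
#' @param path archive path (RDS).
#' @return `path` invisibly; `loadDescriptors` returns the list.
#' @export
saveDescriptors <- function(dsets, path) {
  saveRDS(list(format = "nxcr-descriptors", version = 1L,
               basisHash = dsets[[1]]@basisHash,
               betaMap = dsets[[1]]@betaMap,
               structures = lapply(dsets, function(d)
                 list(coefficients = d@coefficients,
                      invariants = d@invariants, species = d@species,
                      betaMap = d@betaMap, basisHash = d@basisHash))),
          path)
  invisible(path)
}

#' @rdname saveDescriptors
#' @param expectedHash optional basis hash that must match the archive.
#' @export
loadDescriptors <- function(path, expectedHash = NULL) {
  x <- readRDS(path)
  if (!identical(x$format, "nxcr-descriptors"))
    .stopf("not a descriptor archive: %s", path, class = "nxcrIntegrityError")
  if (!is.null(expectedHash) && !identical(expectedHash, x$basisHash))
    .stopf("descriptor archive basis hash mismatch",
           class = "nxcrIntegrityError")
  lapply(x$structures, function(s)
    new("DescriptorSet", coefficients = s$coefficients,
        invariants = s$invariants, species = s$species,
        betaMap = s$betaMap, basisHash = s$basisHash))
}

#' Write a tab-separated energy table
#'
#' Columns `id`, `E_base`, `E_ref` (Hartree).
#'
#' @param samples list of [TrainingSample-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEnergyTable <- function(samples, path) {
  df <- data.frame(id = seq_along(samples),
                   E_base = vapply(samples, function(s) s@eBase, numeric(1)),
                   E_ref = vapply(samples, function(s) s@eRef, numeric(1)))
  utils::write.table(format(df, digits = 17), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeEnergyTable
#' @export
readEnergyTable <- function(path)
  utils::read.table(path, header = TRUE, sep = "\t")
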