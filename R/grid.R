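#' @include AllGenerics.R
NULL

#' Uniform voxel grid
#'
#' Builds a cube-file-style uniform grid: `dims` voxels along three axis
#' vectors starting at `origin`. Weights are the voxel volume, so the weight
#' sum equals the covered volume exactly. Midpoint quadrature on such a grid
#' converges super-algebraically for smooth, rapidly decaying integrands
#' (Gaussian-type densities), but carries a looser effective tolerance than
#' the atom-centered rule for basis-function integrals.
#'
#' @param origin numeric length-3, Bohr.
#' @param axes 3 x 3 matrix, rows are voxel step vectors, Bohr.
#' @param dims integer length-3, voxel counts per axis.
#' @param periodic logical; when `TRUE`, `cell` defaults to `dims * axes`.
#' @param cell optional 3 x 3 lattice matrix (rows), Bohr.
#' @return a [Grid-class]. Point ordering is cube-file order: the first axis
#'   varies slowest, the third fastest.
#' @examples
#' g <- uniformGrid(c(0, 0, 0), diag(0.5, 3), c(4L, 4L, 4L))
#' sum(gridWeights(g))  # 8 Bohr^3
#' @export
uniformGrid <- function(origin, axes, dims, periodic = FALSE, cell = NULL) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(dims < 1L)) .stopf("dims must be 3 positive counts")
  axes <- as.matrix(axes)
  vol <- abs(det(axes))
  if (vol <= 0) .stopf("voxel axes are singular")
  i <- seq_len(dims[1L]) - 1L
  j <- seq_len(dims[2L]) - 1L
  k <- seq_len(dims[3L]) - 1L
  idx <- cbind(rep(i, each = dims[2L] * dims[3L]),
               rep(rep(j, each = dims[3L]), times = dims[1L]),
               rep(k, times = dims[1L] * dims[2L]))
  pts <- sweep(idx %*% axes, 2L, -as.numeric(origin))
  if (periodic && is.null(cell)) cell <- diag(dims) %*% axes
  new("Grid",
      points = pts,
      weights = rep(vol, nrow(pts)),
      periodic = isTRUE(periodic),
      cell = if (is.null(cell)) matrix(0, 3, 3) else as.matrix(cell),
      meta = list(backend = "uniform", origin = as.numeric(origin),
                  axes = axes, dims = dims))
}

#' Cubic box grid
#'
#' Convenience wrapper for a cube-shaped [uniformGrid()] centered on a point.
#'
#' @param center numeric length-3, box center, Bohr.
#' @param length numeric, edge length, Bohr.
#' @param n integer, voxels per edge.
#' @param periodic logical.
#' @return a [Grid-class].
#' @export
boxGrid <- function(center, length, n, periodic = FALSE) {
  h <- length / n
  ## place voxel centers (midpoint rule)
  origin <- as.numeric(center) - length / 2 + h / 2
  uniformGrid(origin, diag(h, 3), rep(n, 3L), periodic = periodic,
              cell = if (periodic) diag(length, 3) else NULL)
}

#' Atom-centered product quadrature grid
#'
#' Per-atom Gauss--Legendre radial rule on `[0, rO]` crossed with a spherical
#' product rule (Gauss--Legendre in cos(theta), equispaced trapezoid in phi).
#' The angular rule integrates spherical harmonics exactly up to degree
#' `nTheta - 1`, and the radial rule resolves the polynomial radial basis
#' exactly, so per-atom basis orthonormality holds to near machine precision.
#' Cutoff spheres must not overlap; the union of spheres is the integration
#' domain and the weight sum equals its volume.
#'
#' @param system an [AtomicSystem-class].
#' @param spec a [BasisSpec-class] supplying per-species cutoff radii.
#' @param nRadial integer, radial nodes per atom.
#' @param nTheta integer, polar nodes; `2 * nTheta` azimuthal nodes are used.
#' @return a [Grid-class] with per-atom point ranges in `meta$atomRanges`.
#' @export
atomCenteredGrid <- function(system, spec, nRadial = 40L, nTheta = 14L) {
  stopifnot(is(system, "AtomicSystem"), is(spec, "BasisSpec"))
  nA <- nrow(system@positions)
  rOs <- basisFor(spec, system@species)$rO
  ## non-overlap guard: each integrand is confined to its own sphere
  if (nA > 1L) {
    d <- as.matrix(stats::dist(system@positions))
    lim <- outer(rOs, rOs, "+")
    diag(d) <- Inf
    if (any(d < lim))
      .stopf("cutoff spheres overlap; use a uniform grid backend instead")
  }
  nPhi <- 2L * nTheta
  ang <- pracma::gaussLegendre(nTheta, -1, 1)
  phis <- (seq_len(nPhi) - 0.5) * (2 * pi / nPhi)
  st <- sqrt(pmax(0, 1 - ang$x^2))
  dirs <- cbind(
    as.vector(outer(st, cos(phis))),
    as.vector(outer(st, sin(phis))),
    rep(ang$x, times = nPhi)
  )
  wAng <- rep(ang$w, times = nPhi) * (2 * pi / nPhi)
  ptsL <- vector("list", nA); wL <- vector("list", nA)
  ranges <- vector("list", nA)
  ofs <- 0L
  for (a in seq_len(nA)) {
    rad <- pracma::gaussLegendre(nRadial, 0, rOs[a])
    npts <- nRadial * nrow(dirs)
    p <- dirs[rep(seq_len(nrow(dirs)), each = nRadial), , drop = FALSE] *
      rep(rad$x, times = nrow(dirs))
    ptsL[[a]] <- sweep(p, 2L, -system@positions[a, ])
    wL[[a]] <- rep(rad$w * rad$x^2, times = nrow(dirs)) *
      rep(wAng, each = nRadial)
    ranges[[a]] <- seq.int(ofs + 1L, ofs + npts)
    ofs <- ofs + npts
  }
  new("Grid",
      points = do.call(rbind, ptsL),
      weights = unlist(wL),
      periodic = FALSE,
      cell = matrix(0, 3, 3),
      meta = list(backend = "atomic", atomRanges = ranges,
                  nRadial = nRadial, nTheta = nTheta))
}

#' @describeIn integrateField quadrature integral of a density field.
#' @export
setMethod("integrateField", signature("DensityField", "missing"),
          function(x, grid) sum(x@grid@weights * x@values))

#' @describeIn integrateField quadrature integral of a potential field.
#' @export
setMethod("integrateField", signature("PotentialField", "missing"),
          function(x, grid) sum(x@grid@weights * x@values))

#' @describeIn integrateField quadrature integral of bare values on a grid.
#' @export
setMethod("integrateField", signature("numeric", "Grid"),
          function(x, grid) sum(grid@weights * x))

#' Grid accessors
#'
#' @param grid a [Grid-class].
#' @return `gridPoints` the n x 3 node matrix; `gridWeights` the weight
#'   vector; `nGridPoints` the node count.
#' @export
gridPoints <- function(grid) grid@points

#' @rdname gridPoints
#' @export
gridWeights <- function(grid) grid@weights

#' @rdname gridPoints
#' @export
nGridPoints <- function(grid) nrow(grid@points)

## minimum-image displacement of grid points relative to a center
.displacements <- function(grid, center) {
  disp <- sweep(grid@points, 2L, center)
  if (grid@periodic) {
    ## fractional wrap; general (possibly non-orthogonal) cell
    frac <- disp %*% solve(grid@cell)
    frac <- frac - round(frac)
    disp <- frac %*% grid@cell
  }
  disp
}

#' Evaluate a closed-form field on a grid
#'
#' @param fn function taking an n x 3 matrix of points and returning n values.
#' @param grid a [Grid-class].
#' @param kind density kind, see [DensityField-class].
#' @param meta metadata list stored with the field.
#' @return a [DensityField-class].
#' @export
evaluateOnGrid <- function(fn, grid, kind = "full", meta = list()) {
  v <- as.numeric(fn(grid@points))
  new("DensityField", grid = grid, values = v, kind = kind, meta = meta)
}
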