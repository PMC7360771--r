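## Shared fixtures, built in code and memoized per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtureCache)) {
    assign(name, builder(), envir = .fixtureCache)
  }
  get(name, envir = .fixtureCache)
}

## small single-species basis used throughout the unit tests
unitBasis <- function() basisSpec("X", nMax = 3L, lMax = 2L, rO = 2.0)

## one off-center atom with a tight atom-centered grid and projector
unitProjector <- function() {
  fixture("unitProjector", function() {
    sys <- atomicSystem("X", matrix(c(0.3, -0.2, 0.1), 1, 3), c(X = 6))
    g <- atomCenteredGrid(sys, unitBasis(), nRadial = 40L, nTheta = 14L)
    list(system = sys, grid = g,
         projector = buildProjector(sys, unitBasis(), g))
  })
}

## a density field equal to a linear combination of two basis functions
basisCombinationField <- function(proj, coef) {
  at <- proj@atoms[[1]]
  v <- numeric(nGridPoints(proj@grid))
  v[at$idx] <- as.numeric(at$psi %*% coef)
  new("DensityField", grid = proj@grid, values = v, kind = "full",
      meta = list())
}

## default synthetic spec + a modest descriptor-attached dataset reused by
## training tests (analytic-density path, no stored fields)
unitSyntheticBasis <- function()
  basisSpec(c("O", "H"), nMax = c(4L, 3L), lMax = c(3L, 2L),
            rO = c(2.5, 2.2))

unitDataset <- function() {
  fixture("unitDataset", function() {
    spec <- syntheticSpec(seed = 11L)
    ds <- generateDataset(spec, 60, keepDensity = FALSE)
    attachDescriptors(ds, unitSyntheticBasis(), useDelta = TRUE)
  })
}

## an analytic single-Gaussian system for rotation/moment tests
unitGaussianSystem <- function() {
  spec <- syntheticSpec(seed = 3L, speciesPattern = "O",
                        basePositions = matrix(0, 1, 3),
                        deformAmplitude = 0)
  sys <- generateSystem(spec, 1L)
  list(spec = spec, system = sys, params = densityParams(sys, spec, 1L))
}

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(abs(actual - expected) / max(abs(expected), 1e-300), tol)
}
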