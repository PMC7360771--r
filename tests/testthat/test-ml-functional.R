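## random small model over the unit basis (9 invariants per X atom)
randomUnitModel <- function(seed = 1, hidden = 5L, nFeat = 9L) {
  set.seed(seed)
  energyModel("X", list(X = identityPipeline(nFeat)),
              list(X = makeNetwork(nFeat, hidden)), useDelta = FALSE)
}

## two well-separated X atoms with an analytic two-Gaussian density
twoAtomSetup <- function() {
  fixture("twoAtomSetup", function() {
    sys <- atomicSystem(c("X", "X"), rbind(c(-3, 0, 0), c(3, 0.4, -0.2)),
                       c(X = 6))
    g <- atomCenteredGrid(sys, unitBasis(), nRadial = 30L, nTheta = 10L)
    proj <- buildProjector(sys, unitBasis(), g)
    gs <- list(
      list(center = c(-3, 0, 0), precision = diag(1 / 0.6^2, 3),
           norm = 6 / ((2 * pi)^1.5 * 0.6^3)),
      list(center = c(3, 0.4, -0.2), precision = diag(1 / 0.8^2, 3),
           norm = 6 / ((2 * pi)^1.5 * 0.8^3)))
    den <- evaluateOnGrid(function(p) nxcr:::.gaussianMixture(p, gs), g)
    list(system = sys, grid = g, projector = proj, density = den,
         descriptors = symmetrize(projectDensity(proj, den)))
  })
}

test_that("model energy is additive over atoms and permutation invariant", {
  m <- randomUnitModel(2)
  ts <- twoAtomSetup()
  ds <- ts$descriptors
  ## zero output layer: zero energy
  m0 <- m
  L <- length(m0@networks$X)
  m0@networks$X[[L]]$W[] <- 0; m0@networks$X[[L]]$b[] <- 0
  expect_identical(modelEnergy(m0, ds), 0)
  ## identical invariants on both atoms: energy doubles the single-atom one
  dsSame <- ds
  dsSame@coefficients[[2]] <- ds@coefficients[[1]]
  dsSame@invariants[[2]] <- ds@invariants[[1]]
  dsSingle <- new("DescriptorSet",
                  coefficients = ds@coefficients[1],
                  invariants = ds@invariants[1], species = "X",
                  betaMap = ds@betaMap[ds@betaMap$atom == 1, ],
                  basisHash = ds@basisHash)
  expect_equal(modelEnergy(m, dsSame), 2 * modelEnergy(m, dsSingle),
               tolerance = 1e-14)
  ## permuting same-species atoms leaves the energy unchanged
  dsPerm <- ds
  dsPerm@coefficients <- ds@coefficients[c(2, 1)]
  dsPerm@invariants <- ds@invariants[c(2, 1)]
  expect_rel_equal(modelEnergy(m, dsPerm), modelEnergy(m, ds), 1e-12)
  ## unknown species is a coverage error
  dsBad <- ds; dsBad@species <- c("X", "Zz")
  expect_error(modelEnergy(m, dsBad), "cover")
})

test_that("model energy is invariant under rigid rotations of density and geometry", {
  gsys <- unitGaussianSystem()
  spec <- basisSpec("O", 4L, 3L, 2.5)
  m <- energyModel("O", list(O = identityPipeline(16L)),
                   list(O = { set.seed(4); makeNetwork(16L, 6L) }),
                   useDelta = FALSE)
  eOf <- function(sys, params) {
    g <- atomCenteredGrid(sys, spec, nRadial = 30L, nTheta = 12L)
    proj <- buildProjector(sys, spec, g)
    den <- evaluateOnGrid(function(p) nxcr:::.gaussianMixture(p, params), g)
    modelEnergy(m, symmetrize(projectDensity(proj, den)))
  }
  e0 <- eOf(gsys$system, gsys$params)
  set.seed(11)
  for (i in 1:5) {
    R <- randomRotation()
    eR <- eOf(transformSystem(gsys$system, R),
              transformDensityParams(gsys$params, R))
    expect_rel_equal(eR, e0, 1e-6)
  }
})

test_that("model gradient matches finite differences through the full pipeline", {
  ts <- twoAtomSetup()
  ds <- ts$descriptors
  ## constant model: zero gradient
  mC <- randomUnitModel(3)
  L <- length(mC@networks$X)
  for (i in seq_len(L)) mC@networks$X[[i]]$W[] <- 0
  gC <- modelGradient(mC, ds)
  expect_true(all(abs(unlist(gC)) == 0))
  ## linear model with identity pipeline: gradient equals the coefficients
  set.seed(8)
  a <- rnorm(9)
  mL <- energyModel("X", list(X = identityPipeline(9L)),
                    list(X = list(list(W = matrix(a, 9, 1), b = 0,
                                       activation = "linear",
                                       frozen = FALSE))),
                    useDelta = FALSE)
  gL <- modelGradient(mL, ds)
  expect_equal(unname(gL[[1]]), a, tolerance = 1e-14)
  ## random network, non-trivial fitted pipeline: central differences
  X <- rbind(ds@invariants[[1]], ds@invariants[[2]],
             ds@invariants[[1]] * 1.1, ds@invariants[[2]] * 0.9,
             ds@invariants[[1]] * 0.95)
  pipe <- fitPipeline(X, varThreshold = 1e-12, gamma = 1)
  set.seed(9)
  m <- energyModel("X", list(X = pipe),
                   list(X = makeNetwork(ncol(pipe$rotation), 5L)),
                   useDelta = FALSE)
  g <- modelGradient(m, ds)
  eOf <- function(dset) modelEnergy(m, dset)
  h <- 1e-5
  for (atom in 1:2) {
    for (j in seq(1, 9, by = 3)) {
      dp <- ds; dm <- ds
      dp@invariants[[atom]][j] <- dp@invariants[[atom]][j] + h
      dm@invariants[[atom]][j] <- dm@invariants[[atom]][j] - h
      fd <- (eOf(dp) - eOf(dm)) / (2 * h)
      if (abs(fd) > 1e-10) expect_rel_equal(g[[atom]][j], fd, 1e-6)
    }
  }
})

test_that("assembled potential is the basis expansion of the coefficient gradient", {
  ts <- twoAtomSetup()
  proj <- ts$projector
  nb <- nBasis(proj)
  ## all-zero derivatives give the zero potential
  z <- assemblePotential(list(numeric(nb / 2), numeric(nb / 2)), proj)
  expect_true(all(z@values == 0))
  ## a single nonzero derivative reproduces that basis function pointwise
  w1 <- numeric(nb / 2); w1[7] <- 1.3
  pot <- assemblePotential(list(w1, numeric(nb / 2)), proj)
  at <- proj@atoms[[1]]
  expect_equal(pot@values[at$idx], 1.3 * at$psi[, 7], tolerance = 1e-14)
  expect_identical(pot@coefficients[at$beta[7]], 1.3)
  ## support: the potential vanishes outside the union of cutoff spheres
  m <- randomUnitModel(5)
  full <- assemblePotential(coefficientGradient(m, ts$descriptors), proj)
  outside <- setdiff(seq_len(nGridPoints(proj@grid)),
                     unique(unlist(lapply(proj@atoms, `[[`, "idx"))))
  expect_true(all(full@values[outside] == 0))
  expect_error(assemblePotential(list(numeric(3), numeric(3)), proj),
               "wrong length")
})

test_that("the potential is the functional derivative of the model energy", {
  ## directional-derivative check with a quadratic Richardson fit:
  ## E[rho + eps * drho] - E[rho] = eps * integral(V drho) + O(eps^2)
  ts <- twoAtomSetup()
  proj <- ts$projector
  m <- randomUnitModel(6)
  w <- ts$grid@weights
  energyOfValues <- function(v) {
    den <- new("DensityField", grid = ts$grid, values = v, kind = "full",
               meta = list())
    modelEnergy(m, symmetrize(projectDensity(proj, den)))
  }
  e0 <- energyOfValues(ts$density@values)
  V <- assemblePotential(coefficientGradient(m, ts$descriptors), proj)@values
  pts <- ts$grid@points
  shapes <- list(
    function(p) exp(-2 * rowSums(sweep(p, 2L, c(-3, 0, 0))^2)),
    function(p) sweep(p, 2L, c(3, 0.4, -0.2))[, 1] *
      exp(-3 * rowSums(sweep(p, 2L, c(3, 0.4, -0.2))^2)),
    function(p) exp(-1.5 * rowSums(sweep(p, 2L, c(-2.6, 0.3, 0.2))^2)))
  for (shape in shapes) {
    drho <- shape(pts)
    lin <- sum(w * V * drho)
    errAt <- function(eps)
      abs(energyOfValues(ts$density@values + eps * drho) - e0 - eps * lin)
    e1 <- errAt(1e-3); e2 <- errAt(1e-4)
    order <- log10(e1 / e2)
    expect_gt(order, 1.9)
  }
})

test_that("additive composition reduces to the baseline for a null correction", {
  g <- boxGrid(c(0, 0, 0), 4, 6L)
  vb <- rnorm(nGridPoints(g))
  out <- composeNxc(-1.5, vb, 0, numeric(length(vb)))
  expect_identical(out$energy, -1.5)
  expect_identical(out$potential, vb)
  ## additivity: composing halves twice equals composing the sum once
  vm <- rnorm(length(vb))
  once <- composeNxc(-1.5, vb, 0.3, vm)
  twice <- composeNxc(-1.5 + 0.15, vb + vm / 2, 0.15, vm / 2)
  expect_equal(once$energy, twice$energy, tolerance = 1e-15)
  expect_equal(once$potential, twice$potential, tolerance = 1e-15)
  expect_error(composeNxc(0, vb, 0, vm[1:5]), "different grids")
})

test_that("model archives round-trip with identical energies", {
  ts <- twoAtomSetup()
  m <- randomUnitModel(7)
  path <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, path)
  m2 <- loadModel(path)
  expect_identical(modelEnergy(m, ts$descriptors),
                   modelEnergy(m2, ts$descriptors))
  expect_identical(m@networks, m2@networks)
  ## a foreign file is rejected
  bad <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), bad)
  expect_error(loadModel(bad), "not a model archive")
})
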