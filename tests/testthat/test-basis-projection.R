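test_that("raw radial functions vanish at the origin and the cutoff", {
  expect_identical(radialRaw(1, 2, rO = 2), 0)
  expect_identical(radialRaw(1, 0, rO = 2), 0)
  expect_identical(radialRaw(4, 5, rO = 2), 0)  # beyond the cutoff
  ## direct evaluation of the closed form: r^2 (rO - r)^(n+2)
  expect_equal(radialRaw(2, 1, rO = 2), 1)
  expect_equal(radialRaw(1, 0.5, rO = 2, normalization = 2),
               0.25 * 1.5^3 / 2)
  expect_error(radialRaw(1, -0.1, rO = 2), "non-negative")
  expect_error(radialRaw(1, 1, rO = 0), "positive")
  expect_error(radialRaw(0, 1, rO = 2), ">= 1")
})

test_that("radial normalization and overlaps match the Beta-function closed form", {
  ## independent oracle: integral_0^rO r^6 (rO-r)^a dr = rO^(a+7) B(7, a+1)
  rO <- 2.5
  for (n in 1:5) {
    Ncf <- sqrt(rO^(2 * n + 11) * beta(7, 2 * n + 5))
    expect_rel_equal(radialNormalization(n, rO), Ncf, 1e-12)
  }
})

test_that("Loewdin orthogonalization yields an orthonormal radial basis", {
  rO <- 2.5; nMax <- 5L
  spec <- basisSpec("X", nMax, 2L, rO)
  ob <- orthogonalizeRadial(spec)$X
  ## closed-form raw overlap as the independent oracle
  Ncf <- sqrt(rO^(2 * (1:nMax) + 11) * beta(7, 2 * (1:nMax) + 5))
  S <- outer(1:nMax, 1:nMax,
             function(n, k) rO^(n + k + 11) * beta(7, n + k + 5)) /
    outer(Ncf, Ncf)
  expect_lt(max(abs(ob$M %*% S %*% t(ob$M) - diag(nMax))), 1e-10)
  ## single-function case: M = 1 / sqrt(raw norm), i.e. 1 for unit-norm raws
  ob1 <- orthogonalizeRadial(basisSpec("X", 1L, 0L, rO))$X
  expect_equal(dim(ob1$M), c(1L, 1L))
  expect_rel_equal(ob1$M[1, 1], 1, 1e-12)
  ## quadrature check of the orthonormality contract
  q <- pracma::gaussLegendre(64, 0, rO)
  Z <- radialOrtho(ob, q$x)
  G <- crossprod(Z * sqrt(q$w * q$x^2))
  expect_lt(max(abs(G - diag(nMax))), 1e-10)
})

test_that("real spherical harmonics follow the fixed convention and are orthonormal", {
  expect_equal(realSphericalHarmonic(0, 0, c(1, 0, 0)), 1 / sqrt(4 * pi))
  expect_equal(realSphericalHarmonic(1, 0, c(0, 0, 1)), sqrt(3 / (4 * pi)))
  ## Condon-Shortley-free sign: Y_11 ~ +x
  expect_gt(realSphericalHarmonic(1, 1, c(1, 0, 0)), 0)
  expect_error(realSphericalHarmonic(1, 2, c(0, 0, 1)), "exceed")
  ## Gram matrix of all harmonics up to l = 4 under a spherical product rule
  nt <- 12L; ang <- pracma::gaussLegendre(nt, -1, 1)
  phis <- (seq_len(2 * nt) - 0.5) * pi / nt
  st <- sqrt(1 - ang$x^2)
  dirs <- cbind(as.vector(outer(st, cos(phis))),
                as.vector(outer(st, sin(phis))),
                rep(ang$x, 2 * nt))
  w <- rep(ang$w, 2 * nt) * (pi / nt)
  Y <- sphericalHarmonics(4L, dirs)
  expect_lt(max(abs(crossprod(Y * sqrt(w)) - diag(25))), 1e-10)
})

test_that("grid weights integrate to the covered volume and stay positive", {
  g <- boxGrid(c(0, 0, 0), 4, 8L)
  expect_equal(sum(gridWeights(g)), 64, tolerance = 1e-12)
  expect_true(all(gridWeights(g) > 0))
  up <- unitProjector()
  ## atom-centered rule: union of cutoff spheres
  expect_rel_equal(sum(gridWeights(up$grid)), 4 / 3 * pi * 2^3, 1e-12)
})

test_that("projector enumerates the canonical basis and is orthonormal per atom", {
  sys <- atomicSystem("X", matrix(0, 1, 3), c(X = 6))
  spec <- basisSpec("X", 2L, 1L, 2.0)
  g <- atomCenteredGrid(sys, spec, nRadial = 30L, nTheta = 10L)
  proj <- buildProjector(sys, spec, g)
  expect_identical(nBasis(proj), 8L)  # 2 radial x (1 + 3) angular
  expect_identical(proj@betaMap$n, rep(1:2, each = 4L))
  expect_identical(proj@betaMap$m[1:4], c(0L, -1L, 0L, 1L))
  G <- atomGram(proj, 1)
  expect_lt(max(abs(G - diag(nrow(G)))), 1e-6)
  up <- unitProjector()
  G2 <- atomGram(up$projector, 1)
  expect_lt(max(abs(G2 - diag(nrow(G2)))), 1e-6)
})

test_that("translating system and grid together leaves the tabulation unchanged", {
  up <- unitProjector()
  shift <- c(1.7, -0.4, 2.2)
  sys2 <- transformSystem(up$system, diag(3), shift)
  g2 <- new("Grid", points = sweep(up$grid@points, 2L, -shift),
            weights = up$grid@weights, periodic = FALSE,
            cell = matrix(0, 3, 3), meta = up$grid@meta)
  proj2 <- buildProjector(sys2, unitBasis(), g2)
  expect_equal(proj2@atoms[[1]]$psi, up$projector@atoms[[1]]$psi,
               tolerance = 1e-12)
})

test_that("periodic tabulation wraps by minimum image", {
  spec <- basisSpec("X", 2L, 1L, 2.0)
  L <- 8; n <- 40L
  ## atom near the cell boundary of a periodic grid
  sysP <- atomicSystem("X", matrix(c(0.3, 4, 4), 1, 3), c(X = 6))
  gP <- boxGrid(c(L / 2, L / 2, L / 2), L, n, periodic = TRUE)
  projP <- buildProjector(sysP, spec, gP)
  GP <- atomGram(projP, 1)
  expect_lt(max(abs(GP - diag(nrow(GP)))), 1e-4)
  ## supercell oracle: project the same (wrapped) Gaussian density in the
  ## periodic cell and in an aperiodic box with the atom centered; both
  ## approximate the same continuum coefficient
  sig <- 0.8
  dispP <- gP@points
  dispP <- sweep(dispP, 2L, c(0.3, 4, 4))
  frac <- dispP %*% solve(gP@cell); frac <- frac - round(frac)
  r2P <- rowSums((frac %*% gP@cell)^2)
  denP <- new("DensityField", grid = gP, values = exp(-r2P / (2 * sig^2)),
              kind = "full", meta = list())
  cP <- projectDensity(projP, denP)@coefficients[[1]]
  sysA <- atomicSystem("X", matrix(c(L / 2, L / 2, L / 2), 1, 3), c(X = 6))
  gA <- boxGrid(c(L / 2, L / 2, L / 2), L, n)
  projA <- buildProjector(sysA, spec, gA)
  r2A <- rowSums(sweep(gA@points, 2L, c(L / 2, L / 2, L / 2))^2)
  denA <- new("DensityField", grid = gA, values = exp(-r2A / (2 * sig^2)),
              kind = "full", meta = list())
  cA <- projectDensity(projA, denA)@coefficients[[1]]
  expect_lt(abs(cP[1] - cA[1]), 1e-5)
  expect_lt(max(abs(cP - cA)), 1e-4)
  ## cutoff sphere exceeding half the cell is ambiguous
  wide <- basisSpec("X", 2L, 1L, 4.5)
  expect_error(buildProjector(sysP, wide, gP), "cell vector")
})

test_that("projection recovers known coefficients by orthonormality and linearity", {
  up <- unitProjector()
  proj <- up$projector
  zero <- new("DensityField", grid = up$grid,
              values = numeric(nGridPoints(up$grid)), kind = "full",
              meta = list())
  expect_true(all(projectDensity(proj, zero)@coefficients[[1]] == 0))
  coef <- numeric(nBasis(proj)); coef[5] <- 0.7; coef[11] <- 0.2
  ds <- projectDensity(proj, basisCombinationField(proj, coef))
  cc <- ds@coefficients[[1]]
  expect_lt(abs(cc[5] - 0.7), 1e-6)
  expect_lt(abs(cc[11] - 0.2), 1e-6)
  expect_lt(max(abs(cc[-c(5, 11)])), 1e-6)
  ## exact linearity of the quadrature projection
  f1 <- basisCombinationField(proj, coef)
  coef2 <- numeric(nBasis(proj)); coef2[2] <- -1.3
  f2 <- basisCombinationField(proj, coef2)
  both <- new("DensityField", grid = up$grid,
              values = 2 * f1@values - 0.5 * f2@values, kind = "full",
              meta = list())
  cBoth <- projectDensity(proj, both)@coefficients[[1]]
  cLin <- 2 * projectDensity(proj, f1)@coefficients[[1]] -
    0.5 * projectDensity(proj, f2)@coefficients[[1]]
  expect_lt(max(abs(cBoth - cLin)), 1e-13)
  ## grid mismatch is a shape error
  gOther <- boxGrid(c(0, 0, 0), 4, 4L)
  denOther <- new("DensityField", grid = gOther,
                  values = numeric(64), kind = "full", meta = list())
  expect_error(projectDensity(proj, denOther), "different grids")
})

test_that("perturbations outside every cutoff sphere leave coefficients unchanged", {
  spec <- basisSpec("X", 2L, 1L, 1.5)
  sys <- atomicSystem("X", matrix(0, 1, 3), c(X = 6))
  g <- boxGrid(c(0, 0, 0), 8, 24L)
  proj <- buildProjector(sys, spec, g)
  r <- sqrt(rowSums(g@points^2))
  base <- exp(-r^2)
  den1 <- new("DensityField", grid = g, values = base, kind = "full",
              meta = list())
  pert <- base + (r > 1.6) * 0.5
  den2 <- new("DensityField", grid = g, values = pert, kind = "full",
              meta = list())
  expect_identical(projectDensity(proj, den1)@coefficients,
                   projectDensity(proj, den2)@coefficients)
})

test_that("atomic reference density carries the valence charges", {
  spec <- unitSyntheticBasis()
  sys <- atomicSystem(c("O", "H", "H"),
                      rbind(c(0, 0, 0), c(5.6, 0, 0), c(-2.8, 4.85, 0)),
                      c(O = 6, H = 1))
  gA <- atomCenteredGrid(sys, spec, nRadial = 30L, nTheta = 10L)
  atm <- atomicReferenceDensity(sys, spec, gA)
  expect_identical(atm@kind, "atomic")
  expect_rel_equal(integrateField(atm), 8, 1e-6)
  ## on a coarse uniform grid the same contract holds to quadrature accuracy
  g <- boxGrid(colMeans(sys@positions), 18, 48L)
  expect_rel_equal(integrateField(atomicReferenceDensity(sys, spec, g)),
                   8, 2e-5)
  ## single atom integrates to its own valence
  sys1 <- atomicSystem("O", matrix(0, 1, 3), c(O = 6))
  g1 <- boxGrid(c(0, 0, 0), 8, 32L)
  expect_rel_equal(integrateField(atomicReferenceDensity(sys1, spec, g1)),
                   6, 1e-6)
  ## missing valence charge is a configuration error
  sysBad <- atomicSystem("O", matrix(0, 1, 3), c(H = 1))
  expect_error(atomicReferenceDensity(sysBad, spec, g1), "valence")
})

test_that("difference density is neutral and vanishes for rho = rho_atm", {
  spec <- unitSyntheticBasis()
  sspec <- syntheticSpec(seed = 5L)
  sys <- generateSystem(sspec, 1L)
  g <- boxGrid(colMeans(sys@positions), 22, 52L)
  rho <- generateDensity(sys, sspec, 1L, g)
  atm <- atomicReferenceDensity(sys, spec, g)
  delta <- deltaDensity(rho, atm)
  expect_identical(delta@kind, "neutral")
  ## integral rho equals the valence count, so delta integrates to zero
  expect_lt(abs(integrateField(delta)), 1e-6)
  expect_identical(delta@values, rho@values - atm@values)
  ## rho = rho_atm gives the zero field
  atmAsFull <- new("DensityField", grid = g, values = atm@values,
                   kind = "full", meta = list())
  expect_true(all(deltaDensity(atmAsFull, atm)@values == 0))
  ## and quadrature linearity ties the pieces together
  expect_lt(abs(integrateField(delta) -
                (integrateField(rho) - integrateField(atm))), 1e-10)
})
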