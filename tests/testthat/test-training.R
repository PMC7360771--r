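test_that("delta loss is the residual sum of squares and gauge invariant", {
  expect_lt(deltaLoss(c(1, 2), c(0.4, 1.1), c(0.6, 0.9)), 1e-30)
  expect_equal(deltaLoss(0.1, 0, 0), 0.01)
  set.seed(1)
  eR <- rnorm(20); eB <- rnorm(20); eM <- rnorm(20)
  brute <- sum(vapply(1:20, function(i) ((eR[i] - eB[i]) - eM[i])^2,
                      numeric(1)))
  expect_rel_equal(deltaLoss(eR, eB, eM), brute, 1e-12)
  ## adding any constant to both reference and baseline changes nothing
  expect_equal(deltaLoss(eR + 13.7, eB + 13.7, eM), deltaLoss(eR, eB, eM),
               tolerance = 1e-12)
  expect_error(deltaLoss(eR, eB[1:3], eM), "length")
})

test_that("preprocessing masks constant features and truncates by explained variance", {
  set.seed(5)
  n <- 60
  ## 3 informative directions embedded in 10 features, 7 exactly constant
  latent <- matrix(rnorm(n * 3), n, 3)
  X <- cbind(latent %*% matrix(rnorm(9), 3, 3), matrix(2.5, n, 7))
  pipe <- fitPipeline(X, varThreshold = 1e-10, gamma = 0.95)
  expect_identical(unname(pipe$mask), c(rep(TRUE, 3), rep(FALSE, 7)))
  expect_lte(ncol(pipe$rotation), 3L)
  ## gamma = 1 keeps every axis and the pipeline is invertible on them
  pipeFull <- fitPipeline(X, gamma = 1)
  expect_identical(ncol(pipeFull$rotation), 3L)
  Z <- applyPipeline(pipeFull, X)
  back <- Z %*% t(pipeFull$rotation)
  Xs <- sweep(sweep(X[, 1:3], 2L, pipeFull$center), 2L, pipeFull$scale, "/")
  expect_equal(back, Xs, tolerance = 1e-10)
  ## eigen-spectrum oracle: retained variance matches the PCA spectrum
  ev <- prcomp(Xs, center = FALSE)$sdev^2
  expect_rel_equal(pipe$explained,
                   sum(ev[seq_len(ncol(pipe$rotation))]) / sum(ev), 1e-10)
  expect_error(fitPipeline(X[1, , drop = FALSE]), "2 rows")
  expect_error(fitPreprocessing(list(O = X[1, , drop = FALSE])), "fewer than 2")
})

test_that("a linear delta target is recovered to the least-squares solution", {
  ds <- unitDataset()[1:40]
  ## construct a target that is exactly linear in the invariants
  set.seed(12)
  nO <- length(ds[[1]]@descriptors@invariants[[1]])
  nH <- length(ds[[1]]@descriptors@invariants[[2]])
  aO <- rnorm(nO, sd = 0.2); aH <- rnorm(nH, sd = 0.2)
  ## the variance filter drops numerically constant features; keep the
  ## target inside the representable (surviving-feature) space
  XO <- t(vapply(ds, function(s) s@descriptors@invariants[[1]], numeric(nO)))
  XH <- do.call(rbind, lapply(ds, function(s)
    rbind(s@descriptors@invariants[[2]], s@descriptors@invariants[[3]])))
  aO[apply(XO, 2, var) < 1e-9] <- 0
  aH[apply(XH, 2, var) < 1e-9] <- 0
  ds <- lapply(ds, function(s) {
    inv <- s@descriptors@invariants
    s@eRef <- s@eBase + sum(inv[[1]] * aO) + sum(inv[[2]] * aH) +
      sum(inv[[3]] * aH)
    s
  })
  cfg <- trainingConfig(hidden = integer(), epochs = 16000L, lr = 0.02,
                        lrDecay = 0.9994, seed = 3L, valFraction = 0)
  m <- trainOnce(ds, cfg)
  expect_lt(maeOf(m, ds), 1e-8)
  ## independent closed-form least-squares oracle reaches (essentially) zero
  X <- t(vapply(ds, function(s) unlist(s@descriptors@invariants),
                numeric(nO + 2 * nH)))
  y <- vapply(ds, function(s) s@eRef - s@eBase, numeric(1))
  fit <- lm.fit(cbind(1, X), y)
  expect_lt(mean(abs(fit$residuals)), 1e-10)
})

test_that("a zero-variance target trains to a constant predictor", {
  ds <- lapply(unitDataset()[1:15], function(s) { s@eRef <- s@eBase + 0.25; s })
  cfg <- trainingConfig(hidden = integer(), epochs = 30000L, lr = 0.05,
                        lrDecay = 0.9997, seed = 2L, valFraction = 0,
                        l2 = 1e-3)
  m <- trainOnce(ds, cfg)
  expect_lt(maeOf(m, ds), 1e-6)
  pred <- predictDelta(m, ds)
  expect_lt(max(pred) - min(pred), 1e-5)
})

test_that("training is reproducible and divergence is reported with the epoch", {
  ds <- unitDataset()[1:20]
  cfg <- trainingConfig(hidden = 4L, epochs = 150L, seed = 9L)
  m1 <- trainOnce(ds, cfg)
  m2 <- trainOnce(ds, cfg)
  expect_identical(m1@networks, m2@networks)
  expect_identical(m1@meta$history$loss, m2@meta$history$loss)
  cfgBad <- trainingConfig(hidden = 4L, epochs = 200L, lr = 1e200, seed = 9L,
                           valFraction = 0)
  expect_error(trainOnce(ds, cfgBad), "epoch",
               class = "nxcrTrainingError")
})

test_that("unknown training-config keys are rejected", {
  expect_error(trainingConfig(learningRate = 0.1), "unknown config keys",
               class = "nxcrConfigError")
  cfg <- trainingConfig(hidden = c(4L, 4L), gamma = 0.97)
  expect_identical(cfg$hidden, c(4L, 4L))
})

test_that("cross-validation is deterministic with first-wins tie-breaking", {
  ds <- unitDataset()[1:25]
  cfg <- trainingConfig(hidden = integer(), epochs = 400L, lr = 0.02,
                        seed = 5L, k = 5L)
  ## one-point grid: returned as-is, k rows per point in the table
  cv1 <- crossValidate(ds, list(list(gamma = 1)), cfg)
  expect_identical(cv1$bestIndex, 1L)
  expect_identical(nrow(cv1$table), 5L)
  ## duplicate grid points score identically; ties break by grid order
  cv2 <- crossValidate(ds, list(list(gamma = 1), list(gamma = 1)), cfg)
  expect_equal(cv2$meanMAE[1], cv2$meanMAE[2], tolerance = 1e-14)
  expect_identical(cv2$bestIndex, 1L)
  ## same seed, same folds, same selection
  cv3 <- crossValidate(ds, list(list(gamma = 1), list(gamma = 1)), cfg)
  expect_identical(cv3$meanMAE, cv2$meanMAE)
  expect_error(crossValidate(ds, list(), cfg), "empty",
               class = "nxcrConfigError")
  expect_error(crossValidate(ds[1:3], list(list(gamma = 1)), cfg), "fold")
})

test_that("gamma selection is stable when the target lives on the top principal axis", {
  ## controlled spectrum: targets depend only on the dominant invariant
  ## direction, so gamma = 0.95 and gamma = 1 score within noise
  ds <- unitDataset()[1:30]
  X <- t(vapply(ds, function(s) unlist(s@descriptors@invariants),
                numeric(sum(lengths(ds[[1]]@descriptors@invariants)))))
  top <- prcomp(scale(X))$x[, 1]
  ds <- lapply(seq_along(ds), function(i) {
    s <- ds[[i]]; s@eRef <- s@eBase + 0.05 * top[i]; s
  })
  cfg <- trainingConfig(hidden = integer(), epochs = 1500L, lr = 0.02,
                        lrDecay = 0.999, seed = 5L, k = 5L)
  cv <- crossValidate(ds, list(list(gamma = 0.95), list(gamma = 1)), cfg)
  expect_lt(abs(cv$meanMAE[1] - cv$meanMAE[2]),
            0.5 * max(cv$meanMAE))
  cvRepeat <- crossValidate(ds, list(list(gamma = 0.95), list(gamma = 1)),
                            cfg)
  expect_identical(cv$bestIndex, cvRepeat$bestIndex)
})

test_that("freeze-and-grow preserves the learned function and freezes bitwise", {
  ds <- unitDataset()[1:20]
  cfg <- trainingConfig(hidden = 4L, epochs = 300L, seed = 7L,
                        valFraction = 0)
  m <- trainOnce(ds, cfg)
  set.seed(31)
  g <- freezeAndGrow(m, width = 4L)
  ## the grown (untrained) model evaluates to the same energies
  expect_equal(predictDelta(g, ds), predictDelta(m, ds), tolerance = 1e-13)
  ## depth grew by one; old hidden layers are frozen
  expect_identical(length(g@networks$O), length(m@networks$O) + 1L)
  expect_true(g@networks$O[[1]]$frozen)
  expect_false(g@networks$O[[length(g@networks$O)]]$frozen)
  ## continued training leaves frozen weights bitwise untouched
  m2 <- trainOnce(ds, trainingConfig(hidden = 4L, epochs = 150L, seed = 8L,
                                     valFraction = 0), init = g)
  expect_identical(m2@networks$O[[1]]$W, m@networks$O[[1]]$W)
  expect_identical(m2@networks$H[[1]]$W, m@networks$H[[1]]$W)
})

test_that("held-out error improves with training-set size", {
  ## statistical mirror of the learning curve: median over 3 seeds,
  ## n = 150 versus n = 10, shared held-out set
  maes <- vapply(1:3, function(sd) {
    spec <- syntheticSpec(seed = 100L + sd)
    ds <- generateDataset(spec, 190, boxLength = 22, nGrid = 40L,
                          keepDensity = FALSE)
    ds <- attachDescriptors(ds, unitSyntheticBasis(), useDelta = TRUE)
    te <- ds[151:190]
    cfgBig <- trainingConfig(hidden = 8L, epochs = 2500L, lr = 0.01,
                             lrDecay = 0.999, seed = sd, valFraction = 0)
    cfgSmall <- trainingConfig(hidden = 8L, epochs = 2500L, lr = 0.01,
                               lrDecay = 0.999, seed = sd, valFraction = 0,
                               l2 = 1e-4)
    c(big = maeOf(trainOnce(ds[1:150], cfgBig), te),
      small = maeOf(trainOnce(ds[1:10], cfgSmall), te))
  }, numeric(2))
  expect_lt(median(maes["big", ]), median(maes["small", ]))
})
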