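#' @include model.R
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a training sample
#'
#' @param system an [AtomicSystem-class].
#' @param density a [DensityField-class] (baseline self-consistent or
#'   synthetic).
#' @param eBase baseline total energy, Hartree.
#' @param eRef reference total energy, Hartree.
#' @param descriptors optional cached [DescriptorSet-class].
#' @return a [TrainingSample-class].
#' @export
trainingSample <- function(system, density, eBase, eRef, descriptors = NULL) {
  new("TrainingSample", system = system, density = density,
      eBase = eBase, eRef = eRef, descriptors = descriptors)
}

.knownConfigKeys <- c(
  "gamma", "varThreshold", "lr", "lrDecay", "beta1", "beta2", "l2",
  "hidden", "k", "epochs", "tol", "seed", "valFraction", "patience",
  "useDelta", "maxIter", "checkEvery"
)

#' Training configuration
#'
#' Defaults follow standard practice for this kind of model: Adam with
#' learning rate 0.001 and decay rates beta1 = 0.9, beta2 = 0.999, a feature
#' variance filter at 1e-10, explained-variance retention gamma in [0.95, 1],
#' and k-fold cross-validation with k = 5 below 100 samples and k = 3
#' otherwise (`k = NULL` selects this automatically).
#'
#' @param ... overrides for any of: `gamma`, `varThreshold`, `lr`, `lrDecay`
#'   (multiplicative per-epoch learning-rate factor, 1 = constant), `beta1`,
#'   `beta2`, `l2` (weight penalty), `hidden` (integer vector of hidden
#'   widths), `k`, `epochs`, `tol` (relative self-consistent MAE change that
#'   stops iterative training), `seed`, `valFraction` (internal validation
#'   split for early stopping), `patience` (validation checks without
#'   improvement before stopping), `useDelta`, `maxIter` (iterative-training
#'   cap), `checkEvery` (epochs between validation checks). Unknown keys are
#'   rejected.
#' @return named list of settings.
#' @export
trainingConfig <- function(...) {
  cfg <- list(
    gamma = 1.0, varThreshold = 1e-10,
    lr = 0.001, lrDecay = 1, beta1 = 0.9, beta2 = 0.999, l2 = 0,
    hidden = 8L, k = NULL, epochs = 2000L, tol = 0.01,
    seed = 1L, valFraction = 0.1, patience = 25L,
    useDelta = TRUE, maxIter = 5L, checkEvery = 20L
  )
  over <- list(...)
  bad <- setdiff(names(over), .knownConfigKeys)
  if (length(bad))
    .stopf("unknown config keys: %s", paste(bad, collapse = ", "),
           class = "nxcrConfigError")
  cfg[names(over)] <- over
  cfg
}

#' Delta-learning loss
#'
#' Sum of squared residuals between the learned correction and the
#' reference-minus-baseline energy difference. Invariant under adding any
#' constant to both `eRef` and `eBase`.
#'
#' @param eRef numeric vector of reference energies, Hartree.
#' @param eBase numeric vector of baseline energies, Hartree.
#' @param eML numeric vector of learned corrections, Hartree.
#' @return scalar loss, Hartree^2.
#' @export
deltaLoss <- function(eRef, eBase, eML) {
  if (length(eRef) != length(eBase) || length(eRef) != length(eML))
    .stopf("energy vectors differ in length", class = "nxcrShapeError")
  sum(((eRef - eBase) - eML)^2)
}

#' Fit per-species preprocessing pipelines
#'
#' @param invariants named list (per species) of matrices, atoms x features.
#' @param config a [trainingConfig()] list.
#' @return named list of pipelines.
#' @export
fitPreprocessing <- function(invariants, config = trainingConfig()) {
  out <- lapply(names(invariants), function(s) {
    X <- invariants[[s]]
    if (is.null(X) || nrow(X) < 2L)
      .stopf("species %s has fewer than 2 training rows", s,
             class = "nxcrFitError")
    fitPipeline(X, config$varThreshold, config$gamma)
  })
  stats::setNames(out, names(invariants))
}

#' Compute and cache descriptors for training samples
#'
#' For densities generated from a closed-form Gaussian model (analytic
#' parameters in the field's `meta`), descriptors are evaluated on a fresh
#' atom-centered quadrature grid for tight accuracy; otherwise the density's
#' own grid is used.
#'
#' @param samples list of [TrainingSample-class].
#' @param spec a [BasisSpec-class].
#' @param useDelta logical; project the neutral difference density.
#' @param nRadial,nTheta atom-centered quadrature orders (analytic path).
#' @return the samples with `descriptors` filled.
#' @export
attachDescriptors <- function(samples, spec, useDelta = TRUE,
                              nRadial = 20L, nTheta = 8L) {
  lapply(samples, function(sm) {
    gs <- sm@density@meta$gaussians
    if (!is.null(gs)) {
      g <- atomCenteredGrid(sm@system, spec, nRadial = nRadial,
                            nTheta = nTheta)
      den <- evaluateOnGrid(function(p) .gaussianMixture(p, gs), g,
                            kind = "full", meta = sm@density@meta)
    } else {
      g <- sm@density@grid
      den <- sm@density
    }
    proj <- buildProjector(sm@system, spec, g)
    sm@descriptors <- descriptorsFor(proj, den, useDelta = useDelta)
    sm
  })
}

#' Learned corrections for a list of samples
#'
#' @param model an [EnergyModel-class].
#' @param samples list of [TrainingSample-class] with descriptors cached.
#' @return numeric vector of E_ML per sample, Hartree.
#' @export
predictDelta <- function(model, samples) {
  vapply(samples, function(sm) {
    if (is.null(sm@descriptors))
      .stopf("samples carry no descriptors; call attachDescriptors() first")
    modelEnergy(model, sm@descriptors)
  }, numeric(1))
}

#' Mean absolute error of the corrected energies
#'
#' @inheritParams predictDelta
#' @return mean of |(eRef - eBase) - E_ML| in Hartree.
#' @export
maeOf <- function(model, samples) {
  y <- vapply(samples, function(s) s@eRef - s@eBase, numeric(1))
  mean(abs(y - predictDelta(model, samples)))
}

## ------------------------------------------------------------------------
## Adam training

.cloneNetworks <- function(networks) networks

.adamInit <- function(networks) {
  lapply(networks, function(net) lapply(net, function(l)
    list(mW = l$W * 0, vW = l$W * 0, mb = l$b * 0, vb = l$b * 0)))
}

#' Train (or fine-tune) an energy model
#'
#' Minimizes the delta-learning loss with full-batch Adam. Preprocessing
#' pipelines are fitted on the training split only; an internal validation
#' split (fraction `valFraction`) drives early stopping, restoring the best
#' parameters seen. Frozen layers (iterative training) are left bitwise
#' untouched. The l2 penalty applies to trainable weights only, never to
#' biases.
#'
#' @param samples list of [TrainingSample-class]; descriptors are computed on
#'   demand when `spec` is given.
#' @param config a [trainingConfig()] list.
#' @param spec optional [BasisSpec-class] for descriptor computation.
#' @param init optional [EnergyModel-class] to grow from (freeze-and-grow);
#'   its preprocessing pipelines are reused unchanged so that frozen layers
#'   keep operating in the coordinates they were trained in.
#' @return an [EnergyModel-class]; training history in `meta$history`.
#' @export
trainOnce <- function(samples, config = trainingConfig(), spec = NULL,
                      init = NULL) {
  if (!length(samples)) .stopf("empty dataset")
  if (is.null(samples[[1]]@descriptors)) {
    if (is.null(spec)) .stopf("no descriptors cached and no basis spec given")
    samples <- attachDescriptors(samples, spec, useDelta = config$useDelta)
  }
  n <- length(samples)
  y <- vapply(samples, function(s) s@eRef - s@eBase, numeric(1))
  set.seed(config$seed)
  nVal <- if (config$valFraction > 0 && n >= 10L)
    max(1L, floor(config$valFraction * n)) else 0L
  valIdx <- if (nVal > 0L) sort(sample.int(n, nVal)) else integer()
  trIdx <- setdiff(seq_len(n), valIdx)

  dsets <- lapply(samples, function(s) s@descriptors)
  speciesAll <- sort(unique(unlist(lapply(dsets, function(d) d@species))))

  ## pipelines on the training split only
  invTrain <- lapply(speciesAll, function(s)
    invariantMatrix(dsets[trIdx], s)$X)
  names(invTrain) <- speciesAll
  ## when growing from an existing model the pipelines are kept bitwise:
  ## the frozen layers were trained in those feature coordinates, and the
  ## function-preserving warm start depends on them staying fixed
  pipelines <- if (is.null(init)) fitPreprocessing(invTrain, config)
               else init@pipelines

  networks <- if (is.null(init)) {
    stats::setNames(lapply(speciesAll, function(s)
      makeNetwork(ncol(pipelines[[s]]$rotation),
                  hidden = as.integer(config$hidden))), speciesAll)
  } else .cloneNetworks(init@networks)

  ## preprocessed features for every atom row, grouped by species
  feat <- lapply(speciesAll, function(s) {
    im <- invariantMatrix(dsets, s)
    list(Z = applyPipeline(pipelines[[s]], im$X), sample = im$sample)
  })
  names(feat) <- speciesAll

  forwardAll <- function() {
    e <- numeric(n)
    fwds <- vector("list", length(speciesAll))
    names(fwds) <- speciesAll
    for (s in speciesAll) {
      fw <- .netForward(networks[[s]], feat[[s]]$Z)
      agg <- rowsum(matrix(fw$out, ncol = 1L), feat[[s]]$sample)
      e[as.integer(rownames(agg))] <- e[as.integer(rownames(agg))] + agg[, 1L]
      fwds[[s]] <- fw
    }
    list(e = e, fwds = fwds)
  }

  adam <- .adamInit(networks)
  lr <- config$lr
  t <- 0L
  bestVal <- Inf; bestNets <- networks; sinceBest <- 0L
  histLoss <- numeric(0); histVal <- numeric(0)
  inTrain <- seq_len(n) %in% trIdx

  for (epoch in seq_len(as.integer(config$epochs))) {
    fa <- forwardAll()
    r <- y - fa$e
    loss <- sum(r[trIdx]^2)
    if (!is.finite(loss))
      .stopf("training diverged (non-finite loss) at epoch %d", epoch,
             class = "nxcrTrainingError")
    histLoss <- c(histLoss, loss)
    dOutScale <- ifelse(inTrain, -2, 0)
    t <- t + 1L
    for (s in speciesAll) {
      dOut <- dOutScale[feat[[s]]$sample] * r[feat[[s]]$sample]
      bw <- .netBackward(networks[[s]], fa$fwds[[s]], dOut)
      for (i in seq_along(networks[[s]])) {
        if (networks[[s]][[i]]$frozen) next
        dW <- bw$layers[[i]]$dW + 2 * config$l2 * networks[[s]][[i]]$W
        db <- bw$layers[[i]]$db
        st <- adam[[s]][[i]]
        st$mW <- config$beta1 * st$mW + (1 - config$beta1) * dW
        st$vW <- config$beta2 * st$vW + (1 - config$beta2) * dW^2
        st$mb <- config$beta1 * st$mb + (1 - config$beta1) * db
        st$vb <- config$beta2 * st$vb + (1 - config$beta2) * db^2
        mWh <- st$mW / (1 - config$beta1^t)
        vWh <- st$vW / (1 - config$beta2^t)
        mbh <- st$mb / (1 - config$beta1^t)
        vbh <- st$vb / (1 - config$beta2^t)
        networks[[s]][[i]]$W <- networks[[s]][[i]]$W -
          lr * mWh / (sqrt(vWh) + 1e-8)
        networks[[s]][[i]]$b <- networks[[s]][[i]]$b -
          lr * mbh / (sqrt(vbh) + 1e-8)
        adam[[s]][[i]] <- st
      }
    }
    lr <- lr * config$lrDecay
    if (nVal > 0L && epoch %% config$checkEvery == 0L) {
      vm <- mean(abs(r[valIdx]))
      histVal <- c(histVal, vm)
      if (vm < bestVal - 1e-15) {
        bestVal <- vm; bestNets <- networks; sinceBest <- 0L
      } else {
        sinceBest <- sinceBest + 1L
        if (sinceBest >= config$patience) break
      }
    }
  }
  if (nVal > 0L && is.finite(bestVal)) networks <- bestNets

  energyModel(speciesAll, pipelines, networks,
              useDelta = isTRUE(config$useDelta),
              basisHash = dsets[[1]]@basisHash,
              meta = list(history = list(loss = histLoss, val = histVal,
                                         valIdx = valIdx),
                          seed = config$seed,
                          configHash = .hashString(paste(
                            deparse(config[order(names(config))]),
                            collapse = ""))))
}

#' k-fold cross-validation over a hyperparameter grid
#'
#' Folds are assigned deterministically from the config seed. Each grid
#' point is scored by the mean validation MAE over folds; the smallest mean
#' wins, ties broken by grid order, and the winning settings are used to
#' retrain one final time on the entire training set.
#'
#' @param samples list of [TrainingSample-class] with descriptors cached.
#' @param grid list of named lists, each a partial config override.
#' @param config base [trainingConfig()].
#' @return list with `best` (winning overrides), `model` (final retrained
#'   [EnergyModel-class]), and `table` (data.frame of per-fold MAEs).
#' @export
crossValidate <- function(samples, grid, config = trainingConfig()) {
  if (!length(grid)) .stopf("empty hyperparameter grid",
                            class = "nxcrConfigError")
  n <- length(samples)
  k <- config$k %||% (if (n < 100L) 5L else 3L)
  if (n < k) .stopf("dataset smaller than fold count k = %d", k)
  set.seed(config$seed)
  fold <- sample(rep_len(seq_len(k), n))
  rows <- list()
  means <- numeric(length(grid))
  for (gIdx in seq_along(grid)) {
    cfg <- config
    cfg[names(grid[[gIdx]])] <- grid[[gIdx]]
    cfg$valFraction <- 0  # folds supply the validation signal
    maes <- numeric(k)
    for (f in seq_len(k)) {
      m <- trainOnce(samples[fold != f], cfg)
      maes[f] <- maeOf(m, samples[fold == f])
      rows[[length(rows) + 1L]] <- data.frame(
        point = gIdx, fold = f, valMAE = maes[f])
    }
    means[gIdx] <- mean(maes)
  }
  best <- which.min(means)  # first minimum wins on ties
  cfg <- config
  cfg[names(grid[[best]])] <- grid[[best]]
  final <- trainOnce(samples, cfg)
  list(best = grid[[best]], bestIndex = best, meanMAE = means,
       model = final, table = do.call(rbind, rows))
}

#' Freeze hidden layers and append a new one
#'
#' Iterative-training growth step: every existing hidden layer is frozen
#' (bitwise) and a new trainable sigmoid layer of width `width` is inserted
#' immediately before the linear head, wired as a skip connection: the head
#' sees both the previous top activations and the new layer's outputs, and
#' its weights on the new block start at zero. The grown model therefore
#' evaluates to exactly the same energies as `model` before any training --
#' growth can only improve the fit, never silently discard what iteration n
#' had learned.
#'
#' @param model an [EnergyModel-class].
#' @param width integer width of the appended hidden layer.
#' @return the grown [EnergyModel-class] (untrained, function-identical to
#'   the input).
#' @export
freezeAndGrow <- function(model, width = 8L) {
  width <- as.integer(width)
  nets <- lapply(model@networks, function(net) {
    L <- length(net)
    for (i in seq_len(L - 1L)) net[[i]]$frozen <- TRUE
    inDim <- nrow(net[[L]]$W)  # width the old head consumed
    newHidden <- list(
      W = matrix(stats::rnorm(inDim * width, sd = 0.1), inDim, width),
      b = numeric(width), activation = "sigmoid", frozen = FALSE,
      concat = TRUE)
    head <- list(W = rbind(net[[L]]$W, matrix(0, width, 1L)),
                 b = net[[L]]$b, activation = "linear", frozen = FALSE)
    c(net[seq_len(L - 1L)], list(newHidden), list(head))
  })
  energyModel(model@species, model@pipelines, nets, model@useDelta,
              model@basisHash, model@meta)
}

#' Iterative (freeze-and-grow) training against a self-consistent driver
#'
#' Iteration 1 trains on the provided baseline densities. Every further
#' iteration re-projects densities made self-consistent with the previous
#' model, freezes the existing hidden layers, appends one new trainable
#' hidden layer, and optimizes it on the updated descriptors and the
#' unchanged residual targets. Training stops when the self-consistent MAE
#' changes by less than `config$tol` (relative) across two subsequent
#' iterations, or after `config$maxIter` iterations.
#'
#' @param scfDriver function(model, samples) returning, per sample, a list
#'   with `density` (a [DensityField-class]), `energy` (self-consistent
#'   corrected total energy, Hartree) and `ok` (logical convergence flag).
#'   `model = NULL` requests the plain baseline solve.
#' @param samples list of [TrainingSample-class] (baseline densities).
#' @param config a [trainingConfig()].
#' @param spec a [BasisSpec-class].
#' @return list with `models` (one per iteration), `final`, `scMAE`
#'   (per-iteration self-consistent MAE, Hartree), `flagged` (indices of
#'   samples whose SCF failed in the last evaluation), `converged`.
#' @export
iterativeTrain <- function(scfDriver, samples, config = trainingConfig(),
                           spec = NULL) {
  if (is.null(samples[[1]]@descriptors)) {
    if (is.null(spec)) .stopf("no descriptors cached and no basis spec given")
    samples <- attachDescriptors(samples, spec, useDelta = config$useDelta)
  }
  eRef <- vapply(samples, function(s) s@eRef, numeric(1))

  scEval <- function(model) {
    res <- scfDriver(model, samples)
    ok <- vapply(res, function(r) isTRUE(r$ok), logical(1))
    if (!any(ok))
      .stopf("self-consistent solve failed for every sample",
             class = "nxcrIterationError")
    en <- vapply(res, function(r) r$energy, numeric(1))
    list(res = res, ok = ok, mae = mean(abs(en[ok] - eRef[ok])))
  }

  models <- list()
  model <- trainOnce(samples, config, spec = spec)
  models[[1L]] <- model
  ev <- scEval(model)
  scMAE <- ev$mae
  converged <- FALSE
  width <- as.integer(config$hidden)[1L]
  cur <- samples
  for (it in 2:max(2L, as.integer(config$maxIter))) {
    ## rebuild samples on the self-consistent densities of the previous
    ## model; the delta target moves with them, so the baseline energy is
    ## re-evaluated at the current density (the loss compares E_ref with
    ## E_base[rho] + E_ML[rho] at the same rho)
    cur <- lapply(seq_along(cur), function(i) {
      sm <- cur[[i]]
      if (ev$ok[i]) {
        sm@density <- ev$res[[i]]$density
        sm@eBase <- ev$res[[i]]$eBase
      }
      sm@descriptors <- NULL
      sm
    })
    cur <- attachDescriptors(cur, spec %||% models[[1L]]@meta$spec,
                             useDelta = config$useDelta)
    set.seed(config$seed + it)
    grown <- freezeAndGrow(model, width = width)
    model <- trainOnce(cur, config, init = grown)
    models[[it]] <- model
    ev <- scEval(model)
    scMAE <- c(scMAE, ev$mae)
    denom <- max(abs(scMAE[it - 1L]), 1e-12)
    if (abs(scMAE[it] - scMAE[it - 1L]) < config$tol * denom) {
      converged <- TRUE
      break
    }
    if (it >= as.integer(config$maxIter)) break
  }
  list(models = models, final = model, scMAE = scMAE,
       flagged = which(!ev$ok), converged = converged)
}
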