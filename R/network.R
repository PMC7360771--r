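#' @include symmetrizer.R
NULL

## Minimal dense feed-forward machinery with analytic gradients. Kept
## self-contained (~100 lines) because the potential pathway needs exact
## derivatives with respect to the *inputs*, which generic R ML wrappers do
## not expose.

.sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a feed-forward atomic network
#'
#' Sigmoid hidden layers, linear scalar output with trainable bias (the
#' per-species constant shift). Weights are initialized from the current RNG
#' state with variance 1/fan-in.
#'
#' @param inputDim integer, number of input features.
#' @param hidden integer vector of hidden-layer widths (possibly empty for a
#'   purely linear model).
#' @return a network: list of layers with `W`, `b`, `activation`, `frozen`.
#' @export
makeNetwork <- function(inputDim, hidden = integer()) {
  dims <- c(inputDim, hidden, 1L)
  acts <- c(rep("sigmoid", length(hidden)), "linear")
  lapply(seq_len(length(dims) - 1L), function(i) {
    list(W = matrix(stats::rnorm(dims[i] * dims[i + 1L], sd = sqrt(1 / max(1, dims[i]))),
                    dims[i], dims[i + 1L]),
         b = numeric(dims[i + 1L]),
         activation = acts[i], frozen = FALSE)
  })
}

## forward pass; returns output column and per-layer activations for
## backprop. A layer with `concat = TRUE` (freeze-and-grow growth step)
## passes its input through alongside its own activations, so the next
## layer sees [input, activation].
.netForward <- function(net, X) {
  A <- list(X)
  H <- X
  for (i in seq_along(net)) {
    l <- net[[i]]
    Z <- sweep(H %*% l$W, 2L, -l$b)
    act <- if (l$activation == "sigmoid") .sigmoid(Z) else Z
    H <- if (isTRUE(l$concat)) cbind(A[[i]], act) else act
    A[[i + 1L]] <- H
  }
  list(out = drop(H), act = A)
}

## backward pass: dOut is dLoss/dOutput per row; returns per-layer dW, db and
## the gradient with respect to the input rows
.netBackward <- function(net, fwd, dOut) {
  L <- length(net)
  grads <- vector("list", L)
  delta <- matrix(dOut, ncol = 1L)
  for (i in L:1) {
    l <- net[[i]]
    inDim <- ncol(fwd$act[[i]])
    if (isTRUE(l$concat)) {
      deltaDirect <- delta[, seq_len(inDim), drop = FALSE]
      deltaOwn <- delta[, -seq_len(inDim), drop = FALSE]
      own <- fwd$act[[i + 1L]][, -seq_len(inDim), drop = FALSE]
    } else {
      deltaDirect <- 0
      deltaOwn <- delta
      own <- fwd$act[[i + 1L]]
    }
    if (l$activation == "sigmoid") deltaOwn <- deltaOwn * own * (1 - own)
    grads[[i]] <- list(dW = crossprod(fwd$act[[i]], deltaOwn),
                       db = colSums(deltaOwn))
    delta <- deltaOwn %*% t(l$W) + deltaDirect
  }
  list(layers = grads, dX = delta)
}

## gradient of the summed scalar output with respect to each input row
.netInputGradient <- function(net, X) {
  fwd <- .netForward(net, X)
  .netBackward(net, fwd, rep(1, nrow(X)))$dX
}

#' Fit the per-species preprocessing pipeline
#'
#' Variance filter (features with training variance below `varThreshold` are
#' dropped), shift/scale to zero mean and unit variance, and projection onto
#' the principal axes of the scaled features, retaining the smallest axis
#' count whose cumulative explained variance reaches `gamma`.
#'
#' @param X matrix (atoms x features) of raw invariants for one species.
#' @param varThreshold numeric variance filter threshold.
#' @param gamma explained-variance retention in (0, 1].
#' @return a pipeline: list with `mask`, `center`, `scale`, `rotation`,
#'   `inputDim`, `explained`.
#' @export
fitPipeline <- function(X, varThreshold = 1e-10, gamma = 1) {
  if (nrow(X) < 2L)
    .stopf("need at least 2 rows to fit a pipeline", class = "nxcrFitError")
  if (gamma <= 0 || gamma > 1) .stopf("gamma must lie in (0, 1]")
  v <- apply(X, 2L, stats::var)
  mask <- v >= varThreshold
  if (!any(mask))
    .stopf("variance filter removed every feature", class = "nxcrFitError")
  Xm <- X[, mask, drop = FALSE]
  center <- colMeans(Xm)
  scl <- sqrt(v[mask])
  Xs <- sweep(sweep(Xm, 2L, center), 2L, scl, "/")
  pc <- stats::prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  expl <- cumsum(ev) / sum(ev)
  k <- which(expl >= gamma - 1e-12)[1L]
  if (is.na(k)) k <- length(ev)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  ## fix axis signs for run-to-run reproducibility
  for (j in seq_len(ncol(rot))) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) rot[, j] <- -rot[, j]
  }
  list(mask = mask, center = center, scale = scl, rotation = rot,
       inputDim = ncol(X), explained = expl[k])
}

#' Apply a preprocessing pipeline
#'
#' @param pipe a pipeline from [fitPipeline()].
#' @param X matrix (atoms x raw features).
#' @return matrix of preprocessed features (atoms x retained axes).
#' @export
applyPipeline <- function(pipe, X) {
  if (ncol(X) != pipe$inputDim)
    .stopf("feature dimension %d does not match pipeline input %d",
           ncol(X), pipe$inputDim, class = "nxcrIntegrityError")
  Xs <- sweep(sweep(X[, pipe$mask, drop = FALSE], 2L, pipe$center),
              2L, pipe$scale, "/")
  Xs %*% pipe$rotation
}

## exact gradient back through the (affine + orthogonal projection) pipeline
.pipelineBackward <- function(pipe, dZ) {
  dXm <- sweep(dZ %*% t(pipe$rotation), 2L, pipe$scale, "/")
  dX <- matrix(0, nrow(dZ), pipe$inputDim)
  dX[, pipe$mask] <- dXm
  dX
}
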