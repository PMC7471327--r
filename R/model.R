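#' Network configuration
#'
#' Assembles all architecture and optimization settings of the temporal
#' convolutional network. Defaults follow the reference architecture:
#' kernel sizes 6, 9, ..., 51 (16 sizes), 64 filters per block, four
#' blocks (P and F inputs, each max- and average-pooled), hidden layers
#' of 128 and 32 units, 11 output units. With 52 time steps this gives a
#' fully-connected input of `4 * 16 * 26 + 2 = 1666` components.
#' Activations, batch size, learning rate and early-stopping patience
#' are tunable; tanh throughout is the default.
#'
#' @param kernelSizes integer vector of temporal kernel sizes.
#' @param nFilters filters per convolutional block (default 64).
#' @param hidden sizes of the two hidden dense layers.
#' @param nLabels number of output labels (default 11).
#' @param convActivation,hiddenActivation,outputActivation one of
#'   `"tanh"`, `"relu"`, `"identity"`.
#' @param learningRate Adam learning rate.
#' @param batchSize minibatch size.
#' @param patience early-stopping patience in epochs (0 stops at the
#'   first epoch without validation improvement).
#' @param maxEpochs hard epoch cap.
#' @return a named list of class `NetworkConfig`.
#' @export
networkConfig <- function(kernelSizes = seq(6L, 51L, by = 3L),
                          nFilters = 64L, hidden = c(128L, 32L),
                          nLabels = 11L,
                          convActivation = "tanh",
                          hiddenActivation = "tanh",
                          outputActivation = "tanh",
                          learningRate = 1e-3, batchSize = 64L,
                          patience = 5L, maxEpochs = 40L) {
  cfg <- list(kernelSizes = as.integer(kernelSizes),
              nFilters = as.integer(nFilters),
              hidden = as.integer(hidden), nLabels = as.integer(nLabels),
              convActivation = convActivation,
              hiddenActivation = hiddenActivation,
              outputActivation = outputActivation,
              learningRate = learningRate,
              batchSize = as.integer(batchSize),
              patience = as.integer(patience),
              maxEpochs = as.integer(maxEpochs))
  if (any(cfg$kernelSizes < 1L)) stop("kernel sizes must be positive")
  if (length(cfg$hidden) != 2L) stop("exactly two hidden layers")
  class(cfg) <- "NetworkConfig"
  cfg
}

.activation <- function(name) switch(name,
  tanh = tanh,
  relu = function(x) pmax(x, 0),
  identity = , linear = identity,
  stop("unknown activation: ", name))

#' Forward pass of one temporal convolutional block (reference)
#'
#' Readable single-sample reference implementation of a TCNN block: for
#' each kernel size `s`, `nFilters` 1D convolutions spanning `s` time
#' steps and all `d` input columns with "same" zero padding (the extra
#' pad element goes at the sequence end for even `s`), activation,
#' `2 x 1` pooling with stride 2, an addition layer summing the filters,
#' and concatenation over kernel sizes. The batched training path in
#' compiled code must agree with this function.
#'
#' @param X numeric `t x d` matrix (t even).
#' @param weights list over kernel sizes, each with `W` (`(s*d) x
#'   nFilters`; row order: time offset fast, column slow) and `b`
#'   (length `nFilters`).
#' @param kernelSizes integer vector matching `weights`.
#' @param pool `"max"` or `"average"`.
#' @param activation activation name applied after the convolution.
#' @return numeric vector of length `length(kernelSizes) * t/2`.
#' @export
tcnnBlockForward <- function(X, weights, kernelSizes, pool = c("max", "average"),
                             activation = "tanh") {
  pool <- match.arg(pool)
  act <- .activation(activation)
  t <- nrow(X); d <- ncol(X)
  if (t %% 2L != 0L) stop("t must be even for 2x1 pooling")
  out <- numeric(0)
  for (k in seq_along(kernelSizes)) {
    s <- kernelSizes[k]
    padLeft <- (s - 1L) %/% 2L
    Xpad <- rbind(matrix(0, padLeft, d), X,
                  matrix(0, s - 1L - padLeft, d))
    patches <- matrix(0, t, s * d)
    for (tt in seq_len(t))
      patches[tt, ] <- as.vector(Xpad[tt:(tt + s - 1L), , drop = FALSE])
    A <- act(sweep(patches %*% weights[[k]]$W, 2, weights[[k]]$b, "+"))
    odd <- A[seq(1, t, by = 2), , drop = FALSE]
    even <- A[seq(2, t, by = 2), , drop = FALSE]
    pooled <- if (pool == "max") pmax(odd, even) else (odd + even) / 2
    out <- c(out, rowSums(pooled))
  }
  out
}

## split the (s*d) x (2*nf) training weight matrix of one kernel size
## into the max-block and average-block halves
.splitConvWeights <- function(weights, half = c("max", "average")) {
  half <- match.arg(half)
  lapply(weights, function(wk) {
    nf <- ncol(wk$W) %/% 2L
    cols <- if (half == "max") seq_len(nf) else nf + seq_len(nf)
    list(W = wk$W[, cols, drop = FALSE], b = as.numeric(wk$b)[cols])
  })
}

#' Full network forward pass (reference)
#'
#' Single-sample composition of the four convolutional blocks (P max, P
#' average, F max, F average), the gender/age concatenation and the
#' dense head. Used as the readable reference the compiled batched path
#' is tested against.
#'
#' @param P,F scaled input matrices (`52 x dP`, `52 x dF`, values in
#'   `[0, 1]`).
#' @param gender,age scaled scalar features.
#' @param weights weight list as produced by training (elements `P`,
#'   `F`, `dense`).
#' @param config a [networkConfig()].
#' @return numeric vector of `nLabels` continuous scores.
#' @export
networkForward <- function(P, F, gender, age, weights, config) {
  if (any(P < 0 | P > 1) || any(F < 0 | F > 1))
    warning("inputs outside [0, 1]; did you forget phi scaling?")
  S <- config$kernelSizes
  feat <- c(
    tcnnBlockForward(P, .splitConvWeights(weights$P, "max"), S, "max",
                     config$convActivation),
    tcnnBlockForward(P, .splitConvWeights(weights$P, "average"), S,
                     "average", config$convActivation),
    tcnnBlockForward(F, .splitConvWeights(weights$F, "max"), S, "max",
                     config$convActivation),
    tcnnBlockForward(F, .splitConvWeights(weights$F, "average"), S,
                     "average", config$convActivation),
    gender, age)
  hAct <- .activation(config$hiddenActivation)
  oAct <- .activation(config$outputActivation)
  d <- weights$dense
  h1 <- hAct(as.numeric(feat %*% d$W1) + as.numeric(d$b1))
  h2 <- hAct(as.numeric(h1 %*% d$W2) + as.numeric(d$b2))
  oAct(as.numeric(h2 %*% d$W3) + as.numeric(d$b3))
}

#' BP-MLL pairwise ranking loss
#'
#' For continuous scores `c` and binary labels `y`, with `Y` the
#' relevant and `Ybar` the irrelevant label sets, the per-sample loss is
#' `(1/(|Y| |Ybar|)) * sum_{k in Y} sum_{l in Ybar} exp(-(c_k - c_l))`,
#' exponentially penalizing every (relevant, irrelevant) pair ranked in
#' the wrong order. For matrices the mean over rows is returned; rows
#' with all-zero or all-one labels are excluded (the loss is undefined
#' there) and counted in the `"skipped"` attribute.
#'
#' @param c numeric vector of scores, or matrix (samples x labels).
#' @param y binary vector or matrix matching `c`.
#' @return the loss (scalar) with attribute `skipped`.
#' @export
bpmllLoss <- function(c, y) {
  if (is.null(dim(c))) { c <- rbind(c); y <- rbind(y) }
  stopifnot(all(dim(c) == dim(y)))
  per <- rep(NA_real_, nrow(c))
  for (i in seq_len(nrow(c))) {
    pos <- which(y[i, ] > 0.5); neg <- which(y[i, ] <= 0.5)
    if (length(pos) == 0L || length(neg) == 0L) next
    per[i] <- mean(exp(-outer(c[i, pos], c[i, neg], `-`)))
  }
  ok <- !is.na(per)
  out <- if (any(ok)) mean(per[ok]) else NA_real_
  attr(out, "skipped") <- sum(!ok)
  out
}

#' @rdname bpmllLoss
#' @return `bpmllGradient`: the gradient of the (mean) loss with respect
#'   to `c`, with the shape of `c`.
#' @export
bpmllGradient <- function(c, y) {
  vecIn <- is.null(dim(c))
  if (vecIn) { c <- rbind(c); y <- rbind(y) }
  g <- matrix(0, nrow(c), ncol(c))
  used <- 0L
  for (i in seq_len(nrow(c))) {
    pos <- which(y[i, ] > 0.5); neg <- which(y[i, ] <= 0.5)
    if (length(pos) == 0L || length(neg) == 0L) next
    E <- exp(-outer(c[i, pos], c[i, neg], `-`))
    norm <- 1 / (length(pos) * length(neg))
    g[i, pos] <- -rowSums(E) * norm
    g[i, neg] <- colSums(E) * norm
    used <- used + 1L
  }
  if (used > 0L) g <- g / used
  if (vecIn) g[1, ] else g
}

#' Per-label threshold calibration
#'
#' For each label independently, picks the threshold minimizing the sum
#' of false positives and false negatives on a validation set.
#' Candidates are the midpoints between consecutive sorted unique
#' scores plus a below-minimum and an above-maximum sentinel; ties are
#' broken toward the smallest candidate. A label constant in the
#' validation set gets the above-maximum threshold (predict
#' all-negative) if all-negative, the below-minimum one if all-positive.
#'
#' @param scores numeric matrix (samples x labels) of continuous model
#'   outputs on the validation set.
#' @param labels binary matrix of the same shape.
#' @return numeric vector of per-label thresholds with attribute
#'   `flags` naming degenerate labels.
#' @export
calibrateThresholds <- function(scores, labels) {
  stopifnot(all(dim(scores) == dim(labels)))
  if (nrow(scores) == 0L) stop("empty validation set")
  flags <- character(0)
  theta <- vapply(seq_len(ncol(scores)), function(j) {
    s <- scores[, j]; y <- labels[, j]
    below <- min(s) - 1; above <- max(s) + 1
    if (all(y == 0)) { flags <<- c(flags, sprintf("label %d all-negative", j))
      return(above) }
    if (all(y == 1)) { flags <<- c(flags, sprintf("label %d all-positive", j))
      return(below) }
    u <- sort(unique(s))
    cand <- c(below, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, above)
    cost <- vapply(cand, function(th)
      sum(y == 0 & s > th) + sum(y == 1 & s <= th), 0)
    cand[which.min(cost)]  # which.min takes the first = smallest candidate
  }, 0)
  attr(theta, "flags") <- flags
  theta
}

## scaled model inputs from a WindowSet: phi on P/F, min-max on age
.modelInputs <- function(ws, scaling = new("ScalingConfig")) {
  list(P = scalePhi(ws@P, scaling),
       F = scalePhi(ws@F, scaling),
       extra = cbind(ws@gender, scaleAge(ws@age, scaling)),
       y = ws@y * 1.0)
}

#' Train the temporal convolutional network
#'
#' Scales the window inputs (phi on the count matrices, min-max on age),
#' trains the network on the training split by minimizing the mean
#' BP-MLL loss with Adam, early-stops on the validation loss (restoring
#' the best-validation weights), and calibrates per-label thresholds on
#' the validation scores.
#'
#' @param ws a [WindowSet-class] (raw counts).
#' @param trainIdx,valIdx disjoint integer index vectors over windows.
#' @param config a [networkConfig()]; `nLabels` must equal `ncol(y)`.
#' @param scaling a [ScalingConfig-class].
#' @param seed integer seed for weight initialization and batch
#'   shuffling.
#' @param verbose print per-epoch losses.
#' @return a [TCNNModel-class].
#' @export
trainTCNN <- function(ws, trainIdx, valIdx, config = NULL,
                      scaling = new("ScalingConfig"), seed = 1,
                      verbose = FALSE) {
  if (length(intersect(trainIdx, valIdx)))
    stop("training and validation sets must be disjoint")
  dF <- dim(ws@F)[2]
  if (is.null(config)) config <- networkConfig()
  if (config$nLabels != ncol(ws@y))
    stop("config$nLabels must match the label width of the windows")
  inp <- .modelInputs(ws, scaling)
  fit <- withSeed(seed, {
    w0 <- cpp_tcnn_init(config, dim(ws@P)[2], dF, dim(ws@P)[1])
    cpp_tcnn_train(inp$P, inp$F, inp$extra, inp$y,
                   as.integer(trainIdx), as.integer(valIdx),
                   config, w0, verbose)
  })
  if (fit$skippedAllOnes > 0)
    message(fit$skippedAllOnes,
            " sample(s) with degenerate labels excluded from the loss")
  valScores <- cpp_tcnn_forward(
    inp$P[, , valIdx, drop = FALSE], inp$F[, , valIdx, drop = FALSE],
    inp$extra[valIdx, , drop = FALSE], fit$weights, config)
  theta <- calibrateThresholds(valScores, ws@y[valIdx, , drop = FALSE])
  new("TCNNModel", config = unclass(config), weights = fit$weights,
      thresholds = as.numeric(theta),
      trainingLog = data.frame(epoch = seq_along(fit$trainLoss),
                               trainLoss = unlist(fit$trainLoss),
                               valLoss = unlist(fit$valLoss)),
      scaling = scaling)
}

#' Predict scores and labels for a window set
#'
#' @param model a [TCNNModel-class] or [BaselineModel-class].
#' @param ws a [WindowSet-class] (raw counts; scaling is applied
#'   internally with the model's stored configuration).
#' @param idx optional window subset.
#' @return a [PredictionScores-class].
#' @export
predictScores <- function(model, ws, idx = seq_len(nWindows(ws))) {
  if (is(model, "TCNNModel")) {
    inp <- .modelInputs(ws[idx], model@scaling)
    cfg <- model@config
    class(cfg) <- "NetworkConfig"
    sc <- cpp_tcnn_forward(inp$P, inp$F, inp$extra, model@weights, cfg)
    theta <- model@thresholds
  } else if (is(model, "BaselineModel")) {
    X <- flattenWindows(ws[idx], model@scaling)
    if (model@kind == "rf") {
      pr <- stats::predict(model@fit, data = data.frame(X))$predictions
      combos <- model@config$combos[colnames(pr), , drop = FALSE]
      sc <- pr %*% combos          # per-label score = sum of class probs
      theta <- rep(0.5, ncol(combos))
    } else {
      sc <- .mlpForward(model@fit, X)
      theta <- model@thresholds
    }
  } else stop("unsupported model class: ", class(model))
  sc <- unname(as.matrix(sc))
  new("PredictionScores", c = sc, theta = as.numeric(theta),
      yHat = .binarize(sc, theta))
}

## binarize scores at per-label thresholds
.binarize <- function(scores, theta) {
  matrix(as.integer(sweep(scores, 2, theta, ">")), nrow(scores))
}

#' Flatten windows for the baseline models
#'
#' Concatenates the phi-scaled flattened `P` (column-major) and `F`
#' matrices with gender and scaled age: with the default shapes this is
#' `52*8 + 52*19 + 2 = 1406` components per window.
#'
#' @param ws a [WindowSet-class].
#' @param scaling a [ScalingConfig-class].
#' @return numeric matrix (windows x features).
#' @export
flattenWindows <- function(ws, scaling = new("ScalingConfig")) {
  n <- nWindows(ws)
  dP <- dim(ws@P); dF <- dim(ws@F)
  ## each row is one window's matrix, flattened column-major
  P <- t(matrix(scalePhi(ws@P, scaling), dP[1] * dP[2], n))
  F <- t(matrix(scalePhi(ws@F, scaling), dF[1] * dF[2], n))
  cbind(P, F, ws@gender, scaleAge(ws@age, scaling))
}

#' Fit a flat-input baseline model
#'
#' Both baselines consume the flattened window vector (see
#' [flattenWindows()]). `"rf"` fits a single random forest over the
#' observed label combinations (label powerset): per-label scores are
#' sums of class probabilities, binarized at 0.5. `"mlp"` fits a dense
#' 128-32-11 network on the
#' same input, trained with the BP-MLL loss, Adam and early stopping,
#' and calibrated with the same per-label threshold rule as the TCNN.
#'
#' @param kind `"rf"` or `"mlp"`.
#' @param ws a [WindowSet-class].
#' @param trainIdx training window indices.
#' @param valIdx validation indices (required for `"mlp"`; ignored by
#'   `"rf"`).
#' @param config optional list: for `"rf"`, `numTrees` (default 200),
#'   `mtry`; for `"mlp"`, a [networkConfig()] (kernel settings ignored).
#' @param scaling a [ScalingConfig-class].
#' @param seed integer seed.
#' @return a [BaselineModel-class].
#' @export
fitBaseline <- function(kind = c("rf", "mlp"), ws, trainIdx, valIdx = NULL,
                        config = NULL, scaling = new("ScalingConfig"),
                        seed = 1) {
  kind <- match.arg(kind)
  X <- flattenWindows(ws, scaling)
  y <- ws@y
  if (kind == "rf") {
    numTrees <- if (!is.null(config$numTrees)) config$numTrees else 200L
    key <- apply(y[trainIdx, , drop = FALSE], 1, paste, collapse = "")
    combos <- unique(y[trainIdx, , drop = FALSE])
    rownames(combos) <- apply(combos, 1, paste, collapse = "")
    df <- data.frame(X[trainIdx, , drop = FALSE])
    df$.combo <- factor(key, levels = rownames(combos))
    fit <- ranger::ranger(
      dependent.variable.name = ".combo", data = df,
      num.trees = numTrees, probability = TRUE, seed = seed,
      num.threads = 1,
      mtry = if (!is.null(config$mtry)) config$mtry else NULL)
    return(new("BaselineModel", kind = "rf", fit = fit,
               thresholds = rep(NA_real_, ncol(y)),
               config = list(numTrees = numTrees, combos = combos),
               scaling = scaling))
  }
  if (is.null(valIdx) || length(valIdx) == 0L)
    stop("the MLP baseline needs a validation split for early stopping")
  cfg <- if (is.null(config)) networkConfig() else config
  fit <- withSeed(seed, .mlpTrain(
    X[trainIdx, , drop = FALSE], y[trainIdx, , drop = FALSE],
    X[valIdx, , drop = FALSE], y[valIdx, , drop = FALSE],
    hidden = cfg$hidden, nLabels = cfg$nLabels,
    activation = cfg$hiddenActivation,
    outputActivation = cfg$outputActivation,
    lr = cfg$learningRate, batchSize = cfg$batchSize,
    patience = cfg$patience, maxEpochs = cfg$maxEpochs))
  valScores <- .mlpForward(fit, X[valIdx, , drop = FALSE])
  theta <- calibrateThresholds(valScores, y[valIdx, , drop = FALSE])
  new("BaselineModel", kind = "mlp", fit = fit,
      thresholds = as.numeric(theta), config = unclass(cfg),
      scaling = scaling)
}
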