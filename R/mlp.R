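## Dense multilayer perceptron trained with the BP-MLL loss: the flat
## baseline sharing the loss, optimizer and early-stopping contract with
## the convolutional model. Small enough to live comfortably in R.

.mlpInit <- function(nIn, hidden, nLabels) {
  layer <- function(ni, no) matrix(rnorm(ni * no, sd = sqrt(1 / ni)), ni, no)
  list(W1 = layer(nIn, hidden[1]), b1 = numeric(hidden[1]),
       W2 = layer(hidden[1], hidden[2]), b2 = numeric(hidden[2]),
       W3 = layer(hidden[2], nLabels), b3 = numeric(nLabels),
       activation = "tanh", outputActivation = "tanh")
}

.mlpForward <- function(fit, X, cache = FALSE) {
  hAct <- .activation(fit$activation)
  oAct <- .activation(fit$outputActivation)
  H1 <- hAct(sweep(X %*% fit$W1, 2, fit$b1, "+"))
  H2 <- hAct(sweep(H1 %*% fit$W2, 2, fit$b2, "+"))
  C <- oAct(sweep(H2 %*% fit$W3, 2, fit$b3, "+"))
  if (cache) list(H1 = H1, H2 = H2, C = C) else C
}

## tanh-only derivative helper (the baselines default to tanh layers)
.actDeriv <- function(a, name) switch(name,
  tanh = 1 - a^2,
  relu = (a > 0) * 1,
  identity = , linear = array(1, dim(a)),
  stop("unknown activation: ", name))

.mlpTrain <- function(Xtr, Ytr, Xval, Yval, hidden = c(128L, 32L),
                      nLabels = ncol(Ytr), activation = "tanh",
                      outputActivation = "tanh", lr = 1e-3,
                      batchSize = 64L, patience = 5L, maxEpochs = 40L) {
  fit <- .mlpInit(ncol(Xtr), hidden, nLabels)
  fit$activation <- activation
  fit$outputActivation <- outputActivation
  pn <- c("W1", "b1", "W2", "b2", "W3", "b3")
  m <- lapply(fit[pn], function(p) p * 0)
  v <- m
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; b1t <- 1; b2t <- 1
  best <- fit; bestVal <- Inf; sinceBest <- 0L
  log <- NULL
  for (epoch in seq_len(maxEpochs)) {
    ord <- sample(nrow(Xtr))
    epochLoss <- 0; used <- 0L
    for (start in seq(1, nrow(Xtr), by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, nrow(Xtr))]
      fc <- .mlpForward(fit, Xtr[idx, , drop = FALSE], cache = TRUE)
      loss <- bpmllLoss(fc$C, Ytr[idx, , drop = FALSE])
      nUsed <- length(idx) - attr(loss, "skipped")
      if (nUsed == 0L) next
      if (!is.finite(loss)) stop("MLP training diverged at epoch ", epoch)
      epochLoss <- epochLoss + loss * nUsed; used <- used + nUsed
      dC <- bpmllGradient(fc$C, Ytr[idx, , drop = FALSE])
      dZ3 <- dC * .actDeriv(fc$C, outputActivation)
      g <- list(W3 = t(fc$H2) %*% dZ3, b3 = colSums(dZ3))
      dZ2 <- (dZ3 %*% t(fit$W3)) * .actDeriv(fc$H2, activation)
      g$W2 <- t(fc$H1) %*% dZ2; g$b2 <- colSums(dZ2)
      dZ1 <- (dZ2 %*% t(fit$W2)) * .actDeriv(fc$H1, activation)
      g$W1 <- t(Xtr[idx, , drop = FALSE]) %*% dZ1; g$b1 <- colSums(dZ1)
      b1t <- b1t * b1; b2t <- b2t * b2
      corr <- lr * sqrt(1 - b2t) / (1 - b1t)
      for (p in pn) {
        m[[p]] <- b1 * m[[p]] + (1 - b1) * g[[p]]
        v[[p]] <- b2 * v[[p]] + (1 - b2) * g[[p]]^2
        fit[[p]] <- fit[[p]] - corr * m[[p]] / (sqrt(v[[p]]) + eps)
      }
    }
    valLoss <- bpmllLoss(.mlpForward(fit, Xval), Yval)
    log <- rbind(log, data.frame(epoch = epoch,
                                 trainLoss = epochLoss / max(used, 1L),
                                 valLoss = as.numeric(valLoss)))
    if (is.finite(valLoss) && valLoss < bestVal) {
      bestVal <- valLoss; best <- fit; sinceBest <- 0L
    } else {
      sinceBest <- sinceBest + 1L
      if (sinceBest > patience) break
    }
  }
  best$trainingLog <- log
  best
}
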