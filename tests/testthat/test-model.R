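## small helper: random weights for a single block in the reference layout
randomBlockWeights <- function(S, d, nf, seed = 1) {
  withSeed(seed, lapply(S, function(s)
    list(W = matrix(rnorm(s * d * nf, sd = 0.3), s * d, nf),
         b = rnorm(nf, sd = 0.1))))
}

test_that("block output length is nS * t/2 and zeros propagate", {
  S <- seq(6L, 51L, by = 3L)
  w <- randomBlockWeights(S, 19, 4)
  out <- tcnnBlockForward(matrix(0, 52, 19),
                          lapply(w, function(x) list(W = x$W, b = 0 * x$b)),
                          S, "max")
  expect_length(out, 16 * 26)   # (51-6)/3+1 = 16 sizes, t/2 = 26
  expect_true(all(out == 0))    # zero input, zero bias -> zero output
  out2 <- tcnnBlockForward(matrix(0, 52, 19),
                           lapply(w, function(x) list(W = x$W, b = 0 * x$b)),
                           S, "average")
  expect_true(all(out2 == 0))

  ## randomized spec sizes
  for (rep in 1:5) {
    S2 <- sort(sample(1:20, sample(2:4, 1)))
    t2 <- 2L * sample(5:12, 1)
    d2 <- sample(2:6, 1)
    w2 <- randomBlockWeights(S2, d2, 3, seed = rep)
    out <- tcnnBlockForward(matrix(rnorm(t2 * d2), t2, d2), w2, S2, "max")
    expect_length(out, length(S2) * t2 / 2)
  }
})

test_that("block forward matches a hand convolution on a toy input", {
  ## t=4, d=1, single filter with kernel of ones, s=1, average pooling,
  ## no activation: input (1,0,0,0) pools to (0.5, 0)
  X <- matrix(c(1, 0, 0, 0), 4, 1)
  w <- list(list(W = matrix(1, 1, 1), b = 0))
  out <- tcnnBlockForward(X, w, 1L, "average", activation = "identity")
  expect_equal(out, c(0.5, 0))

  ## s=3 kernel (1,2,3): same padding, hand-computed convolution
  X2 <- matrix(c(1, 0, 2, 0), 4, 1)
  w2 <- list(list(W = matrix(c(1, 2, 3), 3, 1), b = 0))
  conv <- c(1 * 2 + 0 * 3,            # pad|1,0   -> 2*1+3*0 (+1*pad)
            1 * 1 + 0 * 2 + 2 * 3,    # 1,0,2
            0 * 1 + 2 * 2 + 0 * 3,    # 0,2,0
            2 * 1 + 0 * 2)            # 2,0|pad
  expect_equal(
    tcnnBlockForward(X2, w2, 3L, "max", activation = "identity"),
    c(max(conv[1:2]), max(conv[3:4])))
})

test_that("even kernel sizes pad the extra element at the sequence end", {
  ## s=2 kernel (a, b): row r sees (x[r], x[r+1]) with one trailing pad
  X <- matrix(c(5, 1, 0, 0), 4, 1)
  w <- list(list(W = matrix(c(1, 10), 2, 1), b = 0))
  conv <- c(5 + 10, 1, 0, 0)  # last row: x[4]*1 + pad*10
  expect_equal(
    tcnnBlockForward(X, w, 2L, "average", activation = "identity"),
    c(mean(conv[1:2]), mean(conv[3:4])))
})

test_that("the dense head input length is 4*nS*t/2 + 2 by construction", {
  cfg <- networkConfig()
  nS <- length(cfg$kernelSizes)
  expect_equal(nS, 16L)
  expect_equal(4 * nS * 26 + 2, 1666)
  ## weights generated for the default architecture have matching shapes
  set.seed(1)
  w <- facast:::cpp_tcnn_init(cfg, 8L, 19L, 52L)
  expect_equal(nrow(w$dense$W1), 1666)
  expect_equal(dim(w$dense$W2), c(128, 32))
  expect_equal(dim(w$dense$W3), c(32, 11))
  expect_equal(dim(w$P[[16]]$W), c(51 * 8, 128))  # max+avg filters share
})

test_that("compiled batched forward agrees with the R reference network", {
  ws <- toyWindowSet(6, nTop = 4, dF = 9, kP = 3, seed = 2)
  cfg <- networkConfig(kernelSizes = c(2L, 5L, 8L), nFilters = 4L,
                       hidden = c(10L, 6L), nLabels = 5L)
  set.seed(3)
  w <- facast:::cpp_tcnn_init(cfg, 3L, 9L, 52L)
  inp <- facast:::.modelInputs(ws)
  sc <- facast:::cpp_tcnn_forward(inp$P, inp$F, inp$extra, w, cfg)
  ref <- t(vapply(1:6, function(i)
    networkForward(inp$P[, , i], inp$F[, , i], inp$extra[i, 1],
                   inp$extra[i, 2], w, cfg), numeric(5)))
  expect_equal(sc, ref, tolerance = 1e-5)
  ## identical inputs give identical outputs
  sc2 <- facast:::cpp_tcnn_forward(inp$P, inp$F, inp$extra, w, cfg)
  expect_identical(sc, sc2)
})

test_that("BP-MLL matches hand-evaluated pair sums", {
  c1 <- c(0.5, -0.5); y1 <- c(1, 0)
  expect_equal(as.numeric(bpmllLoss(c1, y1)), exp(-1), tolerance = 1e-12)
  c2 <- c(0.8, -0.3, 0.1); y2 <- c(1, 0, 0)
  expect_equal(as.numeric(bpmllLoss(c2, y2)),
               (exp(-1.1) + exp(-0.7)) / 2, tolerance = 1e-12)
  ## perfect ranking drives the loss toward zero
  expect_lt(as.numeric(bpmllLoss(c(50, -50), c(1, 0))), 1e-20)
  ## all-ones rows are excluded and counted
  L <- bpmllLoss(rbind(c1, c(0.1, 0.2)), rbind(y1, c(1, 1)))
  expect_equal(attr(L, "skipped"), 1L)
  expect_equal(as.numeric(L), exp(-1))
})

test_that("BP-MLL analytic gradient matches central differences", {
  set.seed(19)
  h <- 1e-5
  for (rep in 1:20) {
    n <- sample(6:11, 1)
    c0 <- rnorm(n)
    y <- rbinom(n, 1, 0.5)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[2] <- 0
    g <- bpmllGradient(c0, y)
    fd <- vapply(seq_len(n), function(j) {
      e <- rep(0, n); e[j] <- h
      (as.numeric(bpmllLoss(c0 + e, y)) -
         as.numeric(bpmllLoss(c0 - e, y))) / (2 * h)
    }, 0)
    expect_equal(g, fd, tolerance = 1e-5)
  }
})

test_that("compiled BP-MLL agrees with the R implementation", {
  set.seed(4)
  C <- matrix(rnorm(8 * 11), 8, 11)
  Y <- matrix(rbinom(8 * 11, 1, 0.4), 8, 11)
  Y[rowSums(Y) == 0, 1] <- 1
  out <- facast:::cpp_bpmll_batch(C, Y)
  expect_equal(out$loss, as.numeric(bpmllLoss(C, Y)), tolerance = 1e-6)
  expect_equal(out$grad, bpmllGradient(C, Y), tolerance = 1e-6)
})

test_that("network gradients match finite differences through all layers", {
  set.seed(11)
  n <- 6
  P <- array(runif(8 * 2 * n), c(8, 2, n))
  F <- array(runif(8 * 3 * n), c(8, 3, n))
  extra <- cbind(runif(n), runif(n))
  y <- matrix(rbinom(n * 4, 1, 0.5), n, 4)
  y[rowSums(y) == 0, 1] <- 1L; y[rowSums(y) == 4, 2] <- 0L
  cfg <- networkConfig(kernelSizes = c(2L, 3L), nFilters = 2L,
                       hidden = c(5L, 3L), nLabels = 4L, batchSize = 8L)
  set.seed(3)
  w0 <- facast:::cpp_tcnn_init(cfg, 2L, 3L, 8L)
  gr <- facast:::cpp_tcnn_grad(P, F, extra, y * 1.0, w0, cfg)
  lossAt <- function(w) {
    C <- t(vapply(1:n, function(i)
      networkForward(P[, , i], F[, , i], extra[i, 1], extra[i, 2], w, cfg),
      numeric(4)))
    as.numeric(bpmllLoss(C, y))
  }
  h <- 1e-4
  probes <- list(list("P", 1, "W"), list("F", 2, "W"), list("F", 1, "b"),
                 list("dense", NA, "W1"), list("dense", NA, "W3"),
                 list("dense", NA, "b2"))
  set.seed(8)
  for (pr in probes) {
    getM <- function(w) if (pr[[1]] == "dense") w$dense[[pr[[3]]]]
      else w[[pr[[1]]]][[pr[[2]]]][[pr[[3]]]]
    setM <- function(w, M) {
      if (pr[[1]] == "dense") w$dense[[pr[[3]]]] <- M
      else w[[pr[[1]]]][[pr[[2]]]][[pr[[3]]]] <- M
      w
    }
    idx <- sample(length(getM(w0)), 1)
    bump <- function(sign) {
      M <- getM(w0); M[idx] <- M[idx] + sign * h; setM(w0, M)
    }
    fd <- (lossAt(bump(1)) - lossAt(bump(-1))) / (2 * h)
    expect_equal(getM(gr$grad)[idx], fd, tolerance = 1e-3)
  }
})

test_that("threshold calibration minimizes FP+FN with midpoint rule", {
  s <- c(0.9, 0.2, 0.8, 0.1); y <- c(1, 0, 1, 0)
  th <- calibrateThresholds(cbind(s), cbind(y))
  expect_equal(as.numeric(th), 0.5)  # midpoint of 0.2 and 0.8
  cost <- sum(y == 0 & s > th) + sum(y == 1 & s <= th)
  expect_equal(cost, 0)

  ## perfectly inverted scores: best achievable cost is min(#pos, #neg)
  s2 <- c(0.1, 0.9, 0.2, 0.8, 0.3)
  y2 <- c(1, 0, 1, 0, 1)
  th2 <- calibrateThresholds(cbind(s2), cbind(y2))
  cost2 <- sum(y2 == 0 & s2 > th2) + sum(y2 == 1 & s2 <= th2)
  expect_equal(cost2, min(sum(y2 == 1), sum(y2 == 0)))

  ## degenerate labels
  thPos <- calibrateThresholds(cbind(c(0.3, 0.6)), cbind(c(1, 1)))
  expect_lt(as.numeric(thPos), 0.3)  # predict all-positive
  thNeg <- calibrateThresholds(cbind(c(0.3, 0.6)), cbind(c(0, 0)))
  expect_gt(as.numeric(thNeg), 0.6)  # predict all-negative
  expect_length(attr(thNeg, "flags"), 1)
})

test_that("threshold calibration equals the brute-force scan", {
  set.seed(77)
  for (rep in 1:40) {
    n <- sample(5:60, 1)
    s <- round(rnorm(n), sample(1:3, 1))  # ties likely
    y <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    th <- as.numeric(calibrateThresholds(cbind(s), cbind(y)))
    expect_equal(th, bruteThreshold(s, y))
  }
})

test_that("training learns a deterministic label rule on toy windows", {
  set.seed(2)
  n <- 200
  P <- array(0L, c(52, 4, n))
  F <- array(0L, c(52, 12, n))
  y <- matrix(0L, n, 5)
  for (i in 1:n) {
    act <- sample(1:12, sample(2:4, 1))
    for (a in act) F[sample(1:52, 3), a, i] <- 1L
    P[sample(1:52, 4), sample(1:4, 1), i] <- 1L
    y[i, 1:4] <- as.integer(1:4 %in% act)
    y[i, 5] <- as.integer(any(act > 4))
  }
  ws <- new("WindowSet", P = P, F = F, Ftilde = array(0L, c(9, 12, n)),
            gender = rep(0, n), age = rep(40, n), y = y,
            patientId = rep("p", n), windowId = seq_len(n),
            catalog = toyCatalog(4, 12))
  cfg <- networkConfig(kernelSizes = c(6L, 12L), nFilters = 16L,
                       hidden = c(32L, 16L), nLabels = 5L,
                       maxEpochs = 120L, patience = 20L,
                       learningRate = 3e-3, batchSize = 32L)
  m <- trainTCNN(ws, 1:140, 141:180, config = cfg, seed = 4)
  log <- m@trainingLog
  ## optimization makes clear progress on the ranking loss
  expect_lt(log$trainLoss[nrow(log)], 0.3 * log$trainLoss[1])
  pred <- predictScores(m, ws, 141:180)
  valHam <- mean(hammingDistance(ws@y[141:180, ], pred@yHat))
  expect_lt(valHam, 0.1)  # near-perfect recovery of the generating rule
})

test_that("training is deterministic and early stopping obeys patience", {
  ws <- toyWindowSet(60, nTop = 3, dF = 6, kP = 2, seed = 21)
  cfg <- networkConfig(kernelSizes = c(4L, 9L), nFilters = 4L,
                       hidden = c(8L, 4L), nLabels = 4L,
                       maxEpochs = 15L, patience = 2L, batchSize = 16L)
  m1 <- trainTCNN(ws, 1:40, 41:55, config = cfg, seed = 12)
  m2 <- trainTCNN(ws, 1:40, 41:55, config = cfg, seed = 12)
  expect_identical(m1@trainingLog, m2@trainingLog)
  expect_identical(m1@weights, m2@weights)

  ## patience 0: stops at the first epoch without improvement
  cfg0 <- cfg; cfg0$patience <- 0L; cfg0$maxEpochs <- 40L
  m0 <- trainTCNN(ws, 1:40, 41:55, config = cfg0, seed = 12)
  v <- m0@trainingLog$valLoss
  if (length(v) < 40) {  # stopped early: last epoch failed to improve
    expect_gte(v[length(v)], min(v[-length(v)]))
    expect_true(all(diff(cummin(v[-length(v)])) < 0))
  }
})

test_that("flattened baseline input has 52*8 + 52*19 + 2 components", {
  ws <- toyWindowSet(4, nTop = 10, dF = 19, kP = 8, seed = 6)
  X <- flattenWindows(ws)
  expect_equal(ncol(X), 52 * 8 + 52 * 19 + 2)
  expect_equal(ncol(X), 1406)
  ## flattening preserves values through phi
  expect_equal(X[2, 1:52], unname(scalePhi(ws@P[, 1, 2])))
})

test_that("baselines fit, predict and share the evaluation contract", {
  ws <- toyWindowSet(80, nTop = 3, dF = 6, kP = 2, seed = 14)
  ## RF on constant labels predicts the constant
  wsConst <- ws
  wsConst@y <- matrix(rep(c(1L, 0L, 0L, 1L), each = 80), 80, 4)
  rf <- fitBaseline("rf", wsConst, 1:60,
                    config = list(numTrees = 1L), seed = 3)
  pr <- predictScores(rf, wsConst, 61:80)
  expect_true(all(pr@yHat == rep(c(1L, 0L, 0L, 1L), each = 20)))

  ## MLP trains with BP-MLL and the shared threshold calibration
  cfg <- networkConfig(hidden = c(16L, 8L), nLabels = 4L, maxEpochs = 10L,
                       batchSize = 16L)
  mlp <- fitBaseline("mlp", ws, 1:50, 51:65, config = cfg, seed = 5)
  expect_length(mlp@thresholds, 4)
  pm <- predictScores(mlp, ws, 66:80)
  expect_equal(dim(pm@c), c(15L, 4L))
  expect_equal(pm@yHat,
               matrix(as.integer(sweep(pm@c, 2, pm@theta, ">")), 15))
  expect_error(fitBaseline("mlp", ws, 1:50), "validation")
})
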