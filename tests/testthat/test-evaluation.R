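test_that("hammingDistance counts disagreeing labels", {
  y <- c(1, 0, 1, 0, 0, 1, 0, 0, 0, 0, 1)
  expect_equal(hammingDistance(y, y), 0)
  y2 <- y; y2[c(2, 7)] <- 1 - y2[c(2, 7)]
  expect_equal(hammingDistance(y, y2), 2)
  expect_equal(hammingDistance(y, 1 - y), 11)
  expect_error(hammingDistance(y, y[-1]), "length")
  ## matrix form returns one distance per row
  Y <- rbind(y, y, y); Y2 <- rbind(y, y2, 1 - y)
  expect_equal(unname(hammingDistance(Y, Y2)), c(0, 2, 11))
})

test_that("exact accuracy and its top-facilities variant", {
  Y <- matrix(rbinom(44, 1, 0.5), 4, 11)
  expect_equal(exactAccuracy(Y, Y), 1)
  Yh <- Y; Yh[1, 3] <- 1 - Yh[1, 3]; Yh[2, 5] <- 1 - Yh[2, 5]
  Yh[3, 1] <- 1 - Yh[3, 1]
  expect_equal(exactAccuracy(Y, Yh), 0.25)
  ## an error only in the last label vanishes when it is ignored
  Yh2 <- Y; Yh2[, 11] <- 1 - Yh2[, 11]
  expect_equal(exactAccuracy(Y, Yh2), 0)
  expect_equal(exactAccuracy(Y, Yh2, ignoreLast = TRUE), 1)
  expect_error(exactAccuracy(Y[0, ], Y[0, ]), "empty")
})

test_that("exact accuracy is never above the ignore-last variant", {
  set.seed(42)
  for (rep in 1:20) {
    Y <- matrix(rbinom(110, 1, 0.3), 10, 11)
    Yh <- matrix(rbinom(110, 1, 0.3), 10, 11)
    expect_lte(exactAccuracy(Y, Yh),
               exactAccuracy(Y, Yh, ignoreLast = TRUE))
  }
})

test_that("per-label metrics follow the confusion-matrix formulas", {
  y <- c(1, 1, 0, 0); yh <- c(1, 0, 1, 0); s <- c(0.9, 0.4, 0.6, 0.1)
  m <- perLabelMetrics(cbind(y), cbind(yh), cbind(s))
  expect_equal(m$accuracy, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$recall, 0.5)
  expect_equal(m$f1, 0.5)
  ## perfectly ranked scores give AUC 1
  m2 <- perLabelMetrics(cbind(c(1, 1, 0, 0)), cbind(c(1, 1, 0, 0)),
                        cbind(c(0.9, 0.8, 0.2, 0.1)))
  expect_equal(m2$auc, 1)
  ## no predicted positives: precision reported 0 with a flag
  m3 <- perLabelMetrics(cbind(c(1, 0)), cbind(c(0, 0)), cbind(c(0.6, 0.4)))
  expect_equal(m3$precision, 0)
  expect_match(attr(m3, "flags"), "no predicted positives", all = FALSE)
})

test_that("AUC of random scores on balanced labels is near one half", {
  set.seed(33)
  n <- 10000
  auc <- aucScore(runif(n), rbinom(n, 1, 0.5))
  expect_lt(abs(auc - 0.5), 0.02)
})

test_that("rank-statistic AUC equals trapezoidal ROC integration", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(10:100, 1)
    s <- round(rnorm(n), sample(1:3, 1))   # with ties
    y <- rbinom(n, 1, 0.4)
    if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
    expect_equal(aucScore(s, y), trapezoidAUC(s, y), tolerance = 1e-10)
  }
  expect_true(is.na(aucScore(rnorm(5), rep(1, 5))))
})

test_that("pooled AUC equals the O(n^2) pair-counting oracle", {
  set.seed(66)
  s <- rnorm(40); y <- rbinom(40, 1, 0.5)
  pairAUC <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  }
  expect_equal(aucScore(s, y), pairAUC(s, y), tolerance = 1e-12)
})

test_that("micro metrics pool counts; identical labels collapse to macro", {
  y <- cbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  yh <- cbind(c(1, 0, 1, 0), c(1, 0, 1, 0))
  s <- cbind(c(0.9, 0.4, 0.6, 0.1), c(0.9, 0.4, 0.6, 0.1))
  ov <- overallMetrics(y, yh, s)
  expect_equal(unname(ov["microPrecision"]), unname(ov["macroPrecision"]))
  expect_equal(unname(ov["microF1"]), 0.5)
  ## a dominant label drags the micro average toward itself
  y2 <- cbind(rep(c(1, 0), c(50, 50)), rep(c(1, 0), c(2, 98)))
  yh2 <- cbind(rep(1, 100), rep(0, 100))          # label 1 perfect recall
  s2 <- cbind(runif(100), runif(100))
  ov2 <- overallMetrics(y2, yh2, s2)
  expect_gt(unname(ov2["microRecall"]), 0.9)      # pooled positives mostly label 1
})

test_that("mean Hamming equals pooled (FP + FN) / n", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:50, 1)
    Y <- matrix(rbinom(n * 11, 1, 0.3), n, 11)
    Yh <- matrix(rbinom(n * 11, 1, 0.3), n, 11)
    cc <- confusionCounts(Y, Yh)
    expect_equal(mean(hammingDistance(Y, Yh)),
                 sum(cc$FP + cc$FN) / n, tolerance = 1e-12)
    ## lower-bound ledger identities
    lb <- attendanceLowerBound(Yh, Y, nTop = 11)
    expect_equal(lb$predicted, unname(cc$TP + cc$FP))
    expect_equal(lb$actual, unname(cc$TP + cc$FN))
  }
})

test_that("first-access accuracy restricts to unseen-facility positives", {
  ws <- toyWindowSet(40, nTop = 3, dF = 6, kP = 2, seed = 9)
  yh <- ws@y  # start from perfect predictions
  fa <- firstAccessAccuracy(ws, yh)
  ## brute-force subset per facility
  for (j in 1:3) {
    sub <- which(vapply(seq_len(40), function(i)
      sum(ws@F[, j, i]) == 0 && ws@y[i, j] == 1, TRUE))
    expect_equal(fa$n[j], length(sub))
    if (length(sub) > 0) expect_equal(fa$accuracy[j], 1)
  }
  ## all-negative predictor scores zero on every non-empty subset
  fa0 <- firstAccessAccuracy(ws, matrix(0L, 40, 4))
  expect_true(all(fa0$accuracy[fa0$n > 0] == 0))
  ## empty subsets are flagged, not errors
  wsAll <- ws
  wsAll@F[1, , ] <- 1L  # every facility visited in every window
  faE <- firstAccessAccuracy(wsAll, yh)
  expect_true(all(faE$n == 0))
  expect_length(attr(faE, "flags"), 3)
})

test_that("attendance lower bound compares prediction to actual volume", {
  Y <- matrix(rbinom(200, 1, 0.4), 20, 10)
  lb <- attendanceLowerBound(Y, Y, nTop = 10)
  expect_true(all(lb$ratio[lb$actual > 0] == 1))
  lb0 <- attendanceLowerBound(matrix(0L, 20, 10), Y, nTop = 10)
  expect_true(all(lb0$ratio[lb0$actual > 0] == 0))
  expect_equal(lb0$predicted, rep(0, 10))
  ## zero actual positives flagged as NA ratio
  lbNA <- attendanceLowerBound(cbind(1, 0), cbind(0, 0), nTop = 2)
  expect_true(all(is.na(lbNA$ratio)))
})

test_that("evaluatePredictions assembles a consistent report", {
  ws <- toyWindowSet(30, nTop = 3, dF = 6, kP = 2, seed = 10)
  set.seed(3)
  sc <- matrix(rnorm(30 * 4), 30, 4)
  theta <- rep(0, 4)
  pred <- new("PredictionScores", c = sc, theta = theta,
              yHat = matrix(as.integer(sc > 0), 30, 4))
  rep <- evaluatePredictions(ws, pred)
  cc <- confusionCounts(ws@y, pred@yHat)
  expect_equal(rep@meanHamming, sum(cc$FP + cc$FN) / 30)
  expect_equal(rep@n, 30L)
  expect_lte(rep@exactAccuracy, rep@top10ExactAccuracy)
  js <- jsonlite::fromJSON(metricsJSON(rep))
  expect_equal(js$mean_hamming, rep@meanHamming)
  row <- metricsRow(rep)
  expect_equal(row$meanHamming, rep@meanHamming)
})
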