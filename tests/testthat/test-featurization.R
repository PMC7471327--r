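test_that("weekCalendar and weekIndex follow the 7-day block rule", {
  cal <- weekCalendar("2014-01-01", "2018-12-31")
  expect_equal(cal@nWeeks, ceiling(as.numeric(
    as.Date("2018-12-31") - as.Date("2014-01-01") + 1) / 7))
  expect_equal(weekIndex(cal, as.Date("2014-01-01")), 1L)
  expect_equal(weekIndex(cal, as.Date("2014-01-08")), 2L)  # day 8 -> week 2
  expect_equal(weekIndex(cal, as.Date("2014-01-07")), 1L)
  expect_error(weekIndex(cal, as.Date("2019-01-01")), "outside")
  expect_error(weekCalendar("2014-02-01", "2014-01-01"), "precede")
})

test_that("buildWeeklyMatrices places counts at (week, column) cells", {
  cal <- weekCalendar("2014-01-01", "2014-12-31")
  b <- makeBookings(1, appointment_date = as.Date("2014-01-01"),
                    prescription_date = as.Date("2014-01-01"))
  wm <- buildWeeklyMatrices(b, cal)
  expect_equal(wm$P[["P1"]][1, 1], 1)
  expect_equal(wm$F[["P1"]][1, 1], 1)
  expect_equal(sum(wm$P[["P1"]]), 1)

  ## two appointments in one week, same facility, different provisions
  b <- makeBookings(2, appointment_date = as.Date("2014-03-03") + c(0, 1),
                    prescription_date = as.Date("2014-03-01"),
                    provision_id = c("S1", "S2"))
  wm <- buildWeeklyMatrices(b, cal)
  w <- weekIndex(cal, as.Date("2014-03-03"))
  expect_equal(sum(wm$F[["P1"]][w, ]), 2)
  expect_equal(as.numeric(wm$P[["P1"]][w, ]), c(1, 1))

  ## totals of P and F agree with the appointment count
  ds <- generateDataset(generatorConfig("ci", nPatients = 20, seed = 3,
                                        invalidFraction = 0,
                                        negativeWaitFraction = 0,
                                        unknownIdFraction = 0))
  cal2 <- weekCalendar("2014-01-01", "2016-12-31")
  wm2 <- buildWeeklyMatrices(ds$bookings, cal2)
  for (p in wm2$patients[1:5]) {
    nb <- sum(ds$bookings$patient_id == p)
    expect_equal(sum(wm2$P[[p]]), nb)
    expect_equal(sum(wm2$F[[p]]), nb)
  }
  expect_error(
    buildWeeklyMatrices(makeBookings(1,
      appointment_date = as.Date("2015-06-01")), cal),
    "outside")
})

test_that("provisionFeatures builds the documented feature set", {
  cal <- weekCalendar("2014-01-01", "2014-12-31")
  b <- makeBookings(3, provision_id = c("a", "b", "b"),
                    patient_id = c("P1", "P1", "P2"),
                    appointment_date = as.Date("2014-01-10") + c(0, 10, 20),
                    age = c(40L, 40L, 60L))
  ft <- provisionFeatures(b, cal)
  raw <- attr(ft, "raw")
  expect_equal(sum(raw[, "frequency"]), 1)
  expect_equal(raw["a", "n_patients"], 1)
  expect_equal(raw["a", "week_coverage"], 1 / cal@nWeeks)
  expect_equal(raw["a", "age_sd"], 0)   # single record
  expect_equal(raw["b", "n_patients"], 2)
  ## standardized columns have zero mean
  expect_true(all(abs(colMeans(ft)) < 1e-12))
})

test_that("identical booking patterns give identical feature vectors", {
  cal <- weekCalendar("2014-01-01", "2014-12-31")
  b <- rbind(
    makeBookings(2, provision_id = "a",
                 appointment_date = as.Date("2014-02-03") + c(0, 30)),
    makeBookings(2, provision_id = "b",
                 appointment_date = as.Date("2014-02-03") + c(0, 30)))
  ft <- provisionFeatures(b, cal)
  expect_equal(unname(ft["a", ]), unname(ft["b", ]))
})

test_that("clusterProvisions is exact on degenerate and separable cases", {
  x <- matrix(rnorm(40), 8, 5, dimnames = list(paste0("s", 1:8), NULL))
  cl <- clusterProvisions(x, k = 8, seed = 1)
  expect_equal(cl@wcss, 0)
  expect_equal(sort(unname(cl@assignment)), 1:8)

  ## two well-separated blobs are recovered exactly
  set.seed(7)
  blob <- rbind(matrix(rnorm(50, 0, 0.1), 10, 5),
                matrix(rnorm(50, 20, 0.1), 10, 5))
  rownames(blob) <- paste0("s", 1:20)
  cl2 <- clusterProvisions(blob, k = 2, seed = 2)
  a <- unname(cl2@assignment)
  expect_true(all(a[1:10] == a[1]) && all(a[11:20] == a[11]) &&
                a[1] != a[11])

  ## permuting rows leaves the partition unchanged up to relabeling
  perm <- sample(20)
  cl3 <- clusterProvisions(blob[perm, ], k = 2, seed = 2)
  same <- outer(cl2@assignment[rownames(blob)],
                cl2@assignment[rownames(blob)], "==")
  same3 <- outer(cl3@assignment[rownames(blob)],
                 cl3@assignment[rownames(blob)], "==")
  expect_equal(same, same3)

  expect_error(clusterProvisions(x, k = 20, seed = 1), "cannot form")
  expect_identical(clusterProvisions(blob, k = 2, seed = 9)@assignment,
                   clusterProvisions(blob, k = 2, seed = 9)@assignment)
})

test_that("rankFacilities ranks by volume with lexicographic ties", {
  ids <- paste0("F", sprintf("%02d", 1:12))
  totals <- stats::setNames(c(12:1), ids)
  districtOf <- stats::setNames(paste0("D", c(1:8, 1:4)), ids)
  cat <- suppressMessages(rankFacilities(totals, districtOf))
  expect_equal(topFacilities(cat), ids[1:10])
  expect_equal(unname(facilityColumn(cat)[ids[1:10]]), 1:10)
  ## F11 (district D3) joins D3's group column; groups follow rank order
  expect_equal(unname(facilityColumn(cat)[["F11"]]), 10 + 3)
  expect_equal(cat@nColumns, 19L)

  ## tie broken toward the smaller id
  totals2 <- totals; totals2[["F02"]] <- totals2[["F03"]]
  cat2 <- suppressMessages(rankFacilities(totals2, districtOf))
  expect_equal(topFacilities(cat2)[2:3], c("F02", "F03"))

  ## a facility in a district absent from the top-10 goes to the rest
  districtOf3 <- districtOf; districtOf3[["F12"]] <- "D99"
  cat3 <- suppressMessages(rankFacilities(totals, districtOf3))
  expect_equal(unname(facilityColumn(cat3)[["F12"]]), cat3@nColumns)

  ## fewer distinct districts shrink the catalog
  districtOf4 <- stats::setNames(rep("D1", 12), ids)
  cat4 <- suppressMessages(rankFacilities(totals, districtOf4))
  expect_equal(cat4@nColumns, 12L)  # 10 + 1 district + rest
})

test_that("extractWindows matches the worked examples", {
  T <- 70
  mk <- function(weeks) {
    P <- Matrix::sparseMatrix(i = weeks, j = rep(1, length(weeks)), x = 1,
                              dims = c(T, 2))
    F <- Matrix::sparseMatrix(i = weeks, j = rep(1, length(weeks)), x = 1,
                              dims = c(T, 3))
    list(P = P, F = F)
  }
  h <- mk(c(1, 10, 20, 30, 55))
  wins <- extractWindows(h$P, h$F)
  starts <- vapply(wins, `[[`, 0, "start")
  expect_true(1 %in% starts)    # 4 active weeks in 1..52, week 55 in horizon
  expect_false(2 %in% starts)   # only 3 active weeks in 2..53

  h2 <- mk(c(1, 2, 3))
  expect_length(extractWindows(h2$P, h2$F), 0)

  h3 <- mk(1:T)
  expect_length(extractWindows(h3$P, h3$F), T - 60)

  ## emitted slices carry the right shapes and counts
  w1 <- wins[[which(starts == 1)]]
  expect_equal(dim(w1$P), c(52, 2))
  expect_equal(dim(w1$Ftilde), c(9, 3))
  expect_equal(sum(w1$Ftilde), 1)  # week 55 = horizon week 3
})

test_that("extractWindows agrees with the brute-force start checker", {
  set.seed(31)
  for (rep in 1:50) {
    T <- sample(61:80, 1)
    nb <- sample(1:30, 1)
    weeks <- sample(T, nb, replace = TRUE)
    tot <- tabulate(weeks, nbins = T)
    P <- Matrix::sparseMatrix(i = weeks, j = sample(2, nb, TRUE), x = 1,
                              dims = c(T, 2))
    wins <- extractWindows(P, P)
    expect_equal(vapply(wins, `[[`, 0, "start"),
                 bruteExtractStarts(tot, 52, 9, 4))
  }
})

test_that("collapseColumns sums group columns and conserves counts", {
  clustering <- new("ProvisionClustering",
                    assignment = stats::setNames(c(1L, 1L, 2L),
                                                 c("a", "b", "c")),
                    k = 2L, centers = matrix(0, 2, 1),
                    features = matrix(0, 3, 1), wcss = 0)
  cat <- toyCatalog(2, 4)
  P <- matrix(0, 52, 3, dimnames = list(NULL, c("a", "b", "c")))
  P[5, "a"] <- 1; P[5, "b"] <- 1; P[9, "c"] <- 2
  F <- matrix(0, 52, 4, dimnames = list(NULL, paste0("F", 1:4)))
  F[3, "F2"] <- 1
  Ft <- matrix(0, 9, 4, dimnames = list(NULL, paste0("F", 1:4)))
  Ft[3, "F3"] <- 1
  out <- collapseColumns(list(start = 1, P = P, F = F, Ftilde = Ft),
                         clustering, cat)
  expect_equal(out$P[5, 1], 2)       # two same-cluster provisions add up
  expect_equal(out$P[9, 2], 2)
  expect_equal(sum(out$P), sum(P))
  expect_equal(sum(out$F), sum(F))
  expect_equal(out$Ftilde[3, 3], 1)
  bad <- list(start = 1, P = cbind(P, z = 0), F = F, Ftilde = Ft)
  expect_error(collapseColumns(bad, clustering, cat), "z")
})

test_that("phi scaling is exact at zero and strictly concave-increasing", {
  expect_identical(scalePhi(0), 0)
  x <- 0:30
  v <- scalePhi(x)
  expect_true(all(diff(v) > 0))          # strictly increasing
  expect_true(all(diff(diff(v)) < 0))    # shrinking increments
  expect_true(all(v >= 0 & v < 1))
  expect_error(scalePhi(-1), ">= 0")
  ## lambda must exceed 1 for the map to make sense
  expect_error(new("ScalingConfig", lambda = 0.9), "lambda")
})

test_that("age scaling is the clamped min-max map", {
  expect_equal(scaleAge(0), 0)
  expect_equal(scaleAge(120), 1)
  expect_equal(scaleAge(60), 0.5)
  expect_equal(scaleAge(c(-5, 150)), c(0, 1))
})

test_that("labelWindow reads the forecast matrix columns", {
  Ft <- matrix(0, 9, 19)
  Ft[3, 7] <- 2
  expect_equal(labelWindow(Ft), c(rep(0L, 6), 1L, rep(0L, 3), 0L))
  Ft2 <- matrix(0, 9, 19); Ft2[1, 15] <- 1
  expect_equal(labelWindow(Ft2), c(rep(0L, 10), 1L))
  Ft3 <- matrix(0, 9, 19); Ft3[2, 2] <- 1; Ft3[5, 12] <- 3
  y <- labelWindow(Ft3)
  expect_equal(which(y == 1L), c(2L, 11L))
})

test_that("rebalanceWindows keeps positives and a seventh of the rest", {
  ws <- toyWindowSet(120, nTop = 4, dF = 8, kP = 3, seed = 5)
  out <- rebalanceWindows(ws, seed = 9)
  nPos <- sum(rowSums(ws@y[, 1:4]) > 0)
  nRest <- nWindows(ws) - nPos
  expect_equal(nWindows(out), nPos + round(nRest / 7))
  ## all positive windows survive
  expect_true(all(rowSums(out@y[, 1:4]) > 0 |
                    rowSums(out@y[, 1:4]) == 0))
  expect_equal(sum(rowSums(out@y[, 1:4]) > 0), nPos)
  ## determinism and no-op cases
  out2 <- rebalanceWindows(ws, seed = 9)
  expect_identical(out@windowId, out2@windowId)
  expect_equal(nWindows(rebalanceWindows(ws, keepFraction = 1)),
               nWindows(ws))
})

test_that("rebalancing raises the relative frequency of positive labels", {
  p <- smallPipeline()
  ws <- p$windows
  out <- rebalanceWindows(ws, seed = 13)
  nTop <- ncol(ws@y) - 1L
  before <- colMeans(ws@y[, 1:nTop, drop = FALSE])
  after <- colMeans(out@y[, 1:nTop, drop = FALSE])
  expect_true(all(after >= before))
  expect_true(mean(after) > mean(before))
})

test_that("prepareWindows output satisfies the window invariants", {
  p <- smallPipeline()
  ws <- p$windows
  n <- nWindows(ws)
  expect_gt(n, 50)
  for (i in seq_len(min(n, 80))) {
    weekly <- rowSums(ws@P[, , i])
    expect_gte(sum(weekly > 0), 4)            # >= 4 active weeks
    expect_gte(sum(ws@Ftilde[, , i]), 1)      # forecast activity
    ## P and F describe the same appointments
    expect_equal(rowSums(ws@P[, , i]), rowSums(ws@F[, , i]))
  }
  expect_true(all(rowSums(ws@y) > 0))         # labels never all-zero
  expect_equal(ncol(ws@y), length(ws@catalog@topFacilities) + 1L)
})

test_that("WindowSet round-trips through its container file", {
  ws <- toyWindowSet(12, nTop = 3, dF = 6, kP = 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".rds")
  saveWindowSet(ws, f)
  back <- loadWindowSet(f)
  expect_equal(back@P, ws@P)
  expect_equal(back@y, ws@y)
  expect_equal(back@catalog@columnOf, ws@catalog@columnOf)
})
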