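## Shared fixtures: everything is generated in code, no stored data.

## hand-written bookings table; defaults give one well-formed Valid row
makeBookings <- function(n = 1, patient_id = "P1", gender = 0L, age = 40L,
                         prescription_date = as.Date("2014-01-01"),
                         appointment_date = as.Date("2014-01-10"),
                         status = "Valid", facility_id = "F1",
                         provision_id = "S1", district_id = "D1") {
  data.frame(patient_id = rep_len(patient_id, n),
             gender = rep_len(gender, n),
             age_at_prescription = rep_len(age, n),
             practitioner_id = NA_character_,
             prescription_date = rep_len(prescription_date, n),
             appointment_date = rep_len(appointment_date, n),
             status = rep_len(status, n),
             facility_id = rep_len(facility_id, n),
             provision_id = rep_len(provision_id, n),
             district_id = rep_len(district_id, n),
             stringsAsFactors = FALSE)
}

## catalog with identity column map: facilities F1..FdF, columns 1..dF
toyCatalog <- function(nTop, dF) {
  ids <- paste0("F", seq_len(dF))
  new("FacilityCatalog", topFacilities = ids[seq_len(nTop)],
      districtOf = stats::setNames(rep("D1", dF), ids),
      columnOf = stats::setNames(seq_len(dF), ids),
      districts = paste0("D", seq_len(dF - nTop - 1L)),
      nColumns = as.integer(dF))
}

## random labeled WindowSet (raw counts); labels derived from Ftilde so
## the labeling invariant holds by construction
toyWindowSet <- function(n = 50, nTop = 10, dF = 19, kP = 8, seed = 1) {
  withSeed(seed, {
    P <- array(rpois(52 * kP * n, 0.05), c(52, kP, n))
    F <- array(rpois(52 * dF * n, 0.04), c(52, dF, n))
    Ftilde <- array(rpois(9 * dF * n, 0.08), c(9, dF, n))
    for (i in seq_len(n))   # guarantee at least one forecast appointment
      if (sum(Ftilde[, , i]) == 0) Ftilde[sample(9, 1), sample(dF, 1), i] <- 1
    y <- t(vapply(seq_len(n), function(i) labelWindow(Ftilde[, , i], nTop),
                  integer(nTop + 1L)))
    new("WindowSet", P = P, F = F, Ftilde = Ftilde,
        gender = rbinom(n, 1, 0.5), age = runif(n, 10, 90), y = y,
        patientId = paste0("P", sample(10, n, replace = TRUE)),
        windowId = seq_len(n), catalog = toyCatalog(nTop, dF))
  })
}

## brute-force window-extraction oracle: tests every start independently
bruteExtractStarts <- function(weeklyTotals, windowLen, horizon,
                               minActiveWeeks) {
  T <- length(weeklyTotals)
  keep <- integer(0)
  for (w in seq_len(max(0, T - windowLen - horizon + 1))) {
    input <- weeklyTotals[w:(w + windowLen - 1)]
    future <- weeklyTotals[(w + windowLen):(w + windowLen + horizon - 1)]
    if (sum(input > 0) >= minActiveWeeks && sum(future) >= 1)
      keep <- c(keep, w)
  }
  keep
}

## trapezoidal ROC integration oracle for the AUC rank statistic
trapezoidAUC <- function(scores, labels) {
  th <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(th, function(t) mean(scores[labels == 1] >= t), 0)
  fpr <- vapply(th, function(t) mean(scores[labels == 0] >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

## exhaustive FP+FN minimization over every candidate threshold
bruteThreshold <- function(s, y) {
  u <- sort(unique(s))
  cand <- c(min(s) - 1, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2,
            max(s) + 1)
  cost <- vapply(cand, function(th) sum(y == 0 & s > th) +
                   sum(y == 1 & s <= th), 0)
  cand[which.min(cost)]
}

## small generated data set shared by the slower integration tests,
## built once per test run
.fixtureEnv <- new.env(parent = emptyenv())
smallPipeline <- function() {
  if (!is.null(.fixtureEnv$pipeline)) return(.fixtureEnv$pipeline)
  cfg <- generatorConfig("ci", nPatients = 150, seed = 42)
  ds <- generateDataset(cfg)
  cl <- cleanRecords(ds$bookings)
  cal <- weekCalendar(cfg$periodStart, cfg$periodEnd)
  districtOf <- stats::setNames(ds$facilities$district_id,
                                ds$facilities$facility_id)
  pw <- suppressMessages(
    prepareWindows(cl$records, cal, districtOf, maxWindows = 400,
                   seed = 42))
  .fixtureEnv$pipeline <- list(cfg = cfg, ds = ds, cleaned = cl,
                               calendar = cal, districtOf = districtOf,
                               windows = pw$windows,
                               clustering = pw$clustering,
                               catalog = pw$catalog)
  .fixtureEnv$pipeline
}
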