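#' Construct a weekly calendar
#'
#' @param periodStart,periodEnd period bounds, `Date` or ISO-8601
#'   strings.
#' @return a [WeekCalendar-class].
#' @export
weekCalendar <- function(periodStart, periodEnd) {
  s <- as.Date(periodStart); e <- as.Date(periodEnd)
  new("WeekCalendar", periodStart = s, periodEnd = e,
      nWeeks = as.integer(ceiling(as.numeric(e - s + 1) / 7)))
}

#' Week index of dates within a calendar
#'
#' Weeks are consecutive 7-day blocks anchored at the period start:
#' `floor((date - periodStart) / 7) + 1`.
#'
#' @param calendar a [WeekCalendar-class].
#' @param dates `Date` vector; must fall inside the period.
#' @return integer week indices in `1..nWeeks`.
#' @export
weekIndex <- function(calendar, dates) {
  dates <- as.Date(dates)
  out <- dates < calendar@periodStart | dates > calendar@periodEnd
  if (any(out, na.rm = TRUE))
    stop("date(s) outside the calendar period: ",
         paste(format(head(dates[which(out)], 3)), collapse = ", "))
  as.integer(floor(as.numeric(dates - calendar@periodStart) / 7)) + 1L
}

#' Build per-patient weekly count matrices
#'
#' For every patient, two sparse matrices with weeks as rows: `P` counts
#' appointments per provision and `F` per facility. Row/column totals of
#' the two matrices agree with the patient's appointment count.
#'
#' @param records cleaned bookings data.frame; all appointment dates must
#'   fall inside the calendar.
#' @param calendar a [WeekCalendar-class].
#' @param provisionIds,facilityIds optional column universes (character);
#'   default: the distinct ids present, sorted.
#' @return list with `patients` (character), `P` and `F` (per-patient
#'   lists of `dgCMatrix`), `provisionIds`, `facilityIds`, `calendar`.
#' @export
buildWeeklyMatrices <- function(records, calendar,
                                provisionIds = NULL, facilityIds = NULL) {
  validateBookings(records)
  if (any(is.na(records$appointment_date)))
    stop("records with missing appointment dates: clean first (row ",
         which(is.na(records$appointment_date))[1], ")")
  wk <- weekIndex(calendar, records$appointment_date)
  if (is.null(provisionIds)) provisionIds <- sort(unique(records$provision_id))
  if (is.null(facilityIds)) facilityIds <- sort(unique(records$facility_id))
  pcol <- match(records$provision_id, provisionIds)
  fcol <- match(records$facility_id, facilityIds)
  if (anyNA(pcol)) stop("provision id outside the declared universe: ",
                        records$provision_id[which(is.na(pcol))[1]])
  if (anyNA(fcol)) stop("facility id outside the declared universe: ",
                        records$facility_id[which(is.na(fcol))[1]])
  T <- calendar@nWeeks
  sp <- split(seq_len(nrow(records)), records$patient_id)
  Pm <- lapply(sp, function(idx)
    Matrix::sparseMatrix(i = wk[idx], j = pcol[idx], x = 1,
                         dims = c(T, length(provisionIds))))
  Fm <- lapply(sp, function(idx)
    Matrix::sparseMatrix(i = wk[idx], j = fcol[idx], x = 1,
                         dims = c(T, length(facilityIds))))
  list(patients = names(sp), P = Pm, F = Fm,
       provisionIds = provisionIds, facilityIds = facilityIds,
       calendar = calendar)
}

#' Statistical features of provisions
#'
#' Per provision: overall relative frequency, number of distinct
#' patients, mean and standard deviation of patient age at prescription,
#' mean weekly appointment count, proportion of weeks with at least one
#' booking, and mean prescription-to-appointment wait in days. Columns
#' are standardized to zero mean and unit variance (constant columns are
#' set to zero); provisions seen once get a zero age standard deviation.
#'
#' @param records cleaned bookings data.frame.
#' @param calendar a [WeekCalendar-class] (for week counts/coverage).
#' @return numeric matrix, one row per provision (rownames = provision
#'   id), with attribute `raw` holding the unstandardized features.
#' @export
provisionFeatures <- function(records, calendar) {
  validateBookings(records)
  T <- calendar@nWeeks
  wk <- weekIndex(calendar, records$appointment_date)
  wait <- as.numeric(records$appointment_date - records$prescription_date)
  sp <- split(seq_len(nrow(records)), records$provision_id)
  n <- nrow(records)
  raw <- t(vapply(sp, function(idx) {
    ages <- records$age_at_prescription[idx]
    c(frequency = length(idx) / n,
      n_patients = length(unique(records$patient_id[idx])),
      age_mean = mean(ages),
      age_sd = if (length(idx) > 1) sd(ages) else 0,
      weekly_mean = length(idx) / T,
      week_coverage = length(unique(wk[idx])) / T,
      wait_mean = mean(wait[idx]))
  }, numeric(7)))
  std <- scale(raw)
  std[, attr(std, "scaled:scale") == 0] <- 0
  std <- std[, , drop = FALSE]
  attr(std, "scaled:center") <- NULL
  attr(std, "scaled:scale") <- NULL
  attr(std, "raw") <- raw
  std
}

## k-means++ seeding (Lloyd iterations are delegated to stats::kmeans)
.kmeansppCenters <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) centers[j + 1L] <- sample.int(n, 1)
    else centers[j + 1L] <- sample.int(n, 1, prob = d2)
    dNew <- rowSums((x - matrix(x[centers[j + 1L], ], n, ncol(x),
                                byrow = TRUE))^2)
    d2 <- pmin(d2, dNew)
  }
  x[centers, , drop = FALSE]
}

#' Cluster provisions by their statistical features
#'
#' Lloyd's K-means with k-means++ initialization, repeated `nstart` times
#' keeping the fit with the lowest within-cluster sum of squares;
#' deterministic for a fixed seed.
#'
#' @param features matrix from [provisionFeatures()] (rownames are
#'   provision ids).
#' @param k number of clusters (default 8).
#' @param seed integer RNG seed.
#' @param nstart number of restarts (default 10).
#' @return a [ProvisionClustering-class].
#' @export
clusterProvisions <- function(features, k = 8, seed = 1, nstart = 10) {
  if (nrow(features) < k)
    stop("cannot form ", k, " clusters from ", nrow(features), " provisions")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nstart)) {
      init <- .kmeansppCenters(features, k)
      ## jitter exact duplicate centers so stats::kmeans accepts them
      while (anyDuplicated(init))
        init[duplicated(init), ] <- init[duplicated(init), , drop = FALSE] +
          rnorm(sum(duplicated(init)) * ncol(init), sd = 1e-9)
      fit <- suppressWarnings(
        kmeans(features, centers = init, iter.max = 100,
               algorithm = "Lloyd"))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  assignment <- as.integer(best$cluster)
  names(assignment) <- rownames(features)
  new("ProvisionClustering", assignment = assignment, k = as.integer(k),
      centers = best$centers, features = features,
      wcss = best$tot.withinss)
}

#' Rank facilities and build the column regrouping
#'
#' Facilities are sorted by their total appointment volume over the
#' forecast horizons of the extracted windows (descending, ties broken by
#' lexicographic facility id). The top `nTop` get columns `1..nTop`; the
#' remaining facilities map to one column per district represented among
#' the top facilities (district order = order of first appearance in the
#' ranking) or to a final rest-of-the-universe column.
#'
#' @param forecastTotals named numeric vector: per-facility appointment
#'   totals over all extracted windows' forecast slices (raw columns).
#' @param districtOf named character vector mapping every facility id to
#'   its district.
#' @param nTop number of target facilities (default 10).
#' @return a [FacilityCatalog-class].
#' @export
rankFacilities <- function(forecastTotals, districtOf, nTop = 10) {
  ids <- names(forecastTotals)
  if (is.null(ids)) stop("forecastTotals must be named by facility id")
  if (!all(ids %in% names(districtOf)))
    stop("district metadata missing for: ",
         paste(head(setdiff(ids, names(districtOf)), 3), collapse = ", "))
  if (length(ids) <= nTop)
    stop("need more than ", nTop, " facilities to rank")
  ord <- order(-forecastTotals, ids)
  top <- ids[ord[seq_len(nTop)]]
  topDistricts <- unique(unname(districtOf[top]))
  if (length(topDistricts) != 8L)
    message("top-", nTop, " facilities span ", length(topDistricts),
            " district(s); using ", length(topDistricts),
            " district group columns")
  nCols <- nTop + length(topDistricts) + 1L
  columnOf <- integer(length(districtOf))
  names(columnOf) <- names(districtOf)
  columnOf[] <- nCols                                   # rest of the universe
  grp <- match(unname(districtOf), topDistricts)
  columnOf[!is.na(grp)] <- nTop + grp[!is.na(grp)]
  columnOf[top] <- seq_len(nTop)
  columnOf <- stats::setNames(as.integer(columnOf), names(columnOf))
  new("FacilityCatalog", topFacilities = top, districtOf = districtOf,
      columnOf = columnOf, districts = topDistricts,
      nColumns = as.integer(nCols))
}

## Shared eligibility rule for sliding windows: weekly appointment totals
## in, logical vector of kept start weeks out.
.keptStarts <- function(weeklyTotals, windowLen, horizon, minActiveWeeks) {
  T <- length(weeklyTotals)
  nStarts <- T - windowLen - horizon + 1L
  if (nStarts < 1L) return(integer(0))
  csA <- cumsum(c(0, weeklyTotals > 0))
  csT <- cumsum(c(0, weeklyTotals))
  w <- seq_len(nStarts)
  active <- csA[w + windowLen] - csA[w] >= minActiveWeeks
  future <- csT[w + windowLen + horizon] - csT[w + windowLen] >= 1
  w[active & future]
}

#' Extract eligible sliding windows from one patient's history
#'
#' Slides a `windowLen`-week window with stride 1 over the patient's
#' weekly matrices. A window starting at week `w` is kept iff the
#' 52-week slice has appointments in at least `minActiveWeeks` distinct
#' weeks and the following `horizon` weeks contain at least one
#' appointment.
#'
#' @param P,F the patient's full-period weekly matrices (weeks x
#'   provisions, weeks x facilities); dense or `Matrix` sparse.
#' @param windowLen input window length in weeks (default 52).
#' @param horizon forecast period length in weeks (default 9).
#' @param minActiveWeeks minimum distinct active weeks in the input
#'   window (default 4).
#' @return list of windows, each a list with `start`, `P` (windowLen x
#'   nProvisions), `F` (windowLen x nFacilities) and `Ftilde` (horizon x
#'   nFacilities); empty list if nothing is eligible.
#' @export
extractWindows <- function(P, F, windowLen = 52, horizon = 9,
                           minActiveWeeks = 4) {
  if (nrow(P) != nrow(F)) stop("P and F must cover the same weeks")
  tot <- Matrix::rowSums(P)
  starts <- .keptStarts(tot, windowLen, horizon, minActiveWeeks)
  lapply(starts, function(w) list(
    start = w,
    P = P[w:(w + windowLen - 1L), , drop = FALSE],
    F = F[w:(w + windowLen - 1L), , drop = FALSE],
    Ftilde = F[(w + windowLen):(w + windowLen + horizon - 1L), ,
               drop = FALSE]))
}

## indicator matrix for summing raw columns into groups
.groupIndicator <- function(group, nGroups) {
  Matrix::sparseMatrix(i = seq_along(group), j = group, x = 1,
                       dims = c(length(group), nGroups))
}

#' Collapse raw provision/facility columns of a window
#'
#' Sums raw provision columns into their cluster columns and raw facility
#' columns into their catalog columns; appointment counts are conserved
#' exactly.
#'
#' @param window one raw window from [extractWindows()]; its matrices
#'   must carry the provision/facility ids as column names, or the column
#'   universes must be supplied.
#' @param clustering a [ProvisionClustering-class].
#' @param catalog a [FacilityCatalog-class].
#' @param provisionIds,facilityIds column universes if the matrices are
#'   unnamed.
#' @return list with dense matrices `P` (windowLen x k), `F` (windowLen x
#'   nColumns), `Ftilde` (horizon x nColumns) and `start`.
#' @export
collapseColumns <- function(window, clustering, catalog,
                            provisionIds = colnames(window$P),
                            facilityIds = colnames(window$F)) {
  if (is.null(provisionIds) || is.null(facilityIds))
    stop("provision/facility ids are required (column names or arguments)")
  pGrp <- clustering@assignment[provisionIds]
  if (anyNA(pGrp))
    stop("provision id not in the clustering: ",
         provisionIds[which(is.na(pGrp))[1]])
  fGrp <- catalog@columnOf[facilityIds]
  if (anyNA(fGrp))
    stop("facility id not in the catalog: ",
         facilityIds[which(is.na(fGrp))[1]])
  IP <- .groupIndicator(unname(pGrp), clustering@k)
  IF <- .groupIndicator(unname(fGrp), catalog@nColumns)
  list(start = window$start,
       P = as.matrix(window$P %*% IP),
       F = as.matrix(window$F %*% IF),
       Ftilde = as.matrix(window$Ftilde %*% IF))
}

#' Non-linear count scaling
#'
#' `phi(x) = 1 - lambda^(-x)` maps non-negative counts into `[0, 1)`,
#' emphasizing differences among small counts; with the default
#' `lambda = e/2`, `phi(1) = 0.264241` and successive differences shrink
#' monotonically.
#'
#' @param x non-negative numeric (vector, matrix or array).
#' @param config a [ScalingConfig-class] (or use `lambda` directly).
#' @param lambda scaling base, overriding `config`.
#' @return scaled values with the shape of `x`.
#' @export
scalePhi <- function(x, config = new("ScalingConfig"),
                     lambda = config@lambda) {
  if (any(x < 0, na.rm = TRUE)) stop("phi scaling requires x >= 0")
  1 - lambda^(-x)
}

#' Min-max age scaling
#'
#' Ages are clamped to `[ageMin, ageMax]` (default 0..120 years) and
#' mapped linearly to `[0, 1]`.
#'
#' @param ageYears numeric ages in years.
#' @param config a [ScalingConfig-class].
#' @return scaled ages in `[0, 1]`.
#' @export
scaleAge <- function(ageYears, config = new("ScalingConfig")) {
  a <- pmin(pmax(ageYears, config@ageMin), config@ageMax)
  (a - config@ageMin) / (config@ageMax - config@ageMin)
}

#' Label a window from its forecast matrix
#'
#' For `j` in `1..nTop`, `y_j = 1` iff column `j` of the forecast matrix
#' has a positive entry; the last label is 1 iff any of the remaining
#' columns (district groups and rest of the universe) has one.
#'
#' @param Ftilde forecast count matrix (horizon x nColumns), raw counts.
#' @param nTop number of individually-labeled facilities (default 10).
#' @return integer 0/1 vector of length `nTop + 1`.
#' @export
labelWindow <- function(Ftilde, nTop = 10) {
  if (ncol(Ftilde) <= nTop)
    stop("forecast matrix must have more than ", nTop, " columns")
  anyPos <- as.integer(colSums(Ftilde > 0) > 0)
  c(anyPos[seq_len(nTop)], as.integer(any(anyPos[-seq_len(nTop)] > 0)))
}

#' Rebalance a window set toward the positive labels
#'
#' Splits windows into those with at least one of the first `nTop` labels
#' set (all kept) and the rest — windows whose only activity in the
#' forecast period falls outside the top facilities — of which a uniform
#' random fraction `keepFraction` (rounded) is retained.
#'
#' @param ws a [WindowSet-class].
#' @param keepFraction fraction of last-label-only windows to keep
#'   (default 1/7).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return the rebalanced [WindowSet-class], original order preserved.
#' @export
rebalanceWindows <- function(ws, keepFraction = 1 / 7, seed = NULL) {
  y <- ws@y
  nTop <- ncol(y) - 1L
  posIdx <- which(rowSums(y[, seq_len(nTop), drop = FALSE]) > 0)
  restIdx <- setdiff(seq_len(nrow(y)), posIdx)
  nKeep <- round(length(restIdx) * keepFraction)
  kept <- if (nKeep >= length(restIdx)) restIdx else
    withSeed(seed, sort(sample(restIdx, nKeep)))
  ws[sort(c(posIdx, kept))]
}

#' Assemble a labeled WindowSet from cleaned records
#'
#' Runs the full featurization chain: per-patient weekly matrices,
#' provision feature clustering, sliding-window extraction, facility
#' ranking over the extracted forecast slices, column collapsing,
#' age-at-window computation and labeling.
#'
#' @param records cleaned bookings data.frame.
#' @param calendar a [WeekCalendar-class].
#' @param districtOf named character vector mapping facility ids to
#'   districts.
#' @param k number of provision clusters (default 8).
#' @param nTop number of target facilities (default 10).
#' @param windowLen,horizon,minActiveWeeks window extraction parameters.
#' @param maxWindows optional cap; if more windows are eligible, a
#'   seeded uniform subsample of this size is kept.
#' @param seed integer seed for clustering and subsampling.
#' @return list with `windows` (a [WindowSet-class]), `clustering`,
#'   `catalog` and `profiles`.
#' @export
prepareWindows <- function(records, calendar, districtOf, k = 8, nTop = 10,
                           windowLen = 52, horizon = 9, minActiveWeeks = 4,
                           maxWindows = NULL, seed = 1) {
  validateBookings(records)
  profiles <- buildProfiles(records)
  wm <- buildWeeklyMatrices(records, calendar)
  feats <- provisionFeatures(records, calendar)
  clustering <- clusterProvisions(feats, k = k, seed = seed)

  ## eligible start weeks per patient, from weekly totals
  startsOf <- lapply(wm$P, function(M)
    .keptStarts(Matrix::rowSums(M), windowLen, horizon, minActiveWeeks))
  keep <- lengths(startsOf) > 0

  ## facility ranking uses the raw (uncollapsed) forecast slices
  totals <- numeric(length(wm$facilityIds))
  for (p in which(keep)) {
    cs <- rbind(0, apply(as.matrix(wm$F[[p]]), 2, cumsum))
    for (w in startsOf[[p]])
      totals <- totals + (cs[w + windowLen + horizon, ] - cs[w + windowLen, ])
  }
  names(totals) <- wm$facilityIds
  catalog <- rankFacilities(totals, districtOf, nTop = nTop)

  ## flat (patient, start) index of all eligible windows; an optional
  ## seeded subsample caps the materialized set
  pIdx <- rep.int(which(keep), lengths(startsOf[keep]))
  wStart <- unlist(startsOf[keep], use.names = FALSE)
  n <- length(pIdx)
  if (n == 0L) stop("no eligible windows in the supplied records")
  if (!is.null(maxWindows) && n > maxWindows) {
    sel <- withSeed(seed, sort(sample(n, maxWindows)))
    pIdx <- pIdx[sel]; wStart <- wStart[sel]; n <- maxWindows
  }
  pid <- wm$patients[pIdx]; wid <- as.integer(wStart)

  ## collapse full matrices once, then slice
  IP <- .groupIndicator(unname(clustering@assignment[wm$provisionIds]),
                        clustering@k)
  IF <- .groupIndicator(unname(catalog@columnOf[wm$facilityIds]),
                        catalog@nColumns)
  P <- array(0L, c(windowLen, clustering@k, n))
  Fm <- array(0L, c(windowLen, catalog@nColumns, n))
  Ft <- array(0L, c(horizon, catalog@nColumns, n))
  for (p in unique(pIdx)) {
    Pc <- as.matrix(wm$P[[p]] %*% IP)
    Fc <- as.matrix(wm$F[[p]] %*% IF)
    for (i in which(pIdx == p)) {
      w <- wid[i]
      P[, , i] <- Pc[w:(w + windowLen - 1L), , drop = FALSE]
      Fm[, , i] <- Fc[w:(w + windowLen - 1L), , drop = FALSE]
      Ft[, , i] <- Fc[(w + windowLen):(w + windowLen + horizon - 1L), ,
                      drop = FALSE]
    }
  }
  y <- t(vapply(seq_len(n), function(i) labelWindow(Ft[, , i], nTop = nTop),
                integer(nTop + 1L)))
  prof <- profiles[match(pid, profiles$patient_id), ]
  windowYear <- as.integer(format(
    calendar@periodStart + (wid - 1L) * 7L, "%Y"))
  age <- pmax(windowYear - prof$birth_year, 0)
  windows <- new("WindowSet", P = P, F = Fm, Ftilde = Ft,
                 gender = as.numeric(prof$gender), age = as.numeric(age),
                 y = y, patientId = pid, windowId = wid, catalog = catalog)
  list(windows = windows, clustering = clustering, catalog = catalog,
       profiles = profiles)
}

#' Save / load a WindowSet
#'
#' Windows are stored as a single RDS container holding the arrays and
#' the catalog, so downstream stages can run without re-deriving
#' features.
#'
#' @param ws a [WindowSet-class].
#' @param path file path.
#' @export
saveWindowSet <- function(ws, path) {
  saveRDS(list(P = ws@P, F = ws@F, Ftilde = ws@Ftilde, gender = ws@gender,
               age = ws@age, y = ws@y, patientId = ws@patientId,
               windowId = ws@windowId, catalog = ws@catalog),
          path)
  invisible(path)
}

#' @rdname saveWindowSet
#' @export
loadWindowSet <- function(path) {
  x <- readRDS(path)
  new("WindowSet", P = x$P, F = x$F, Ftilde = x$Ftilde, gender = x$gender,
      age = x$age, y = x$y, patientId = x$patientId, windowId = x$windowId,
      catalog = x$catalog)
}
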