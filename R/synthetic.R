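#' Calibrate the provision-frequency exponent
#'
#' The generator draws provisions from a power-law (Zipf-like)
#' distribution with weights `rank^-s`. This utility solves for the
#' exponent `s` at which the top `topN` provisions carry a target share
#' of all bookings, so the synthetic heavy tail can be matched to an
#' observed cumulative-frequency table (the administrative data this
#' generator emulates has the top 50 of ~2,500 provisions carrying about
#' 59% of bookings).
#'
#' @param nProvisions size of the provision universe.
#' @param topN number of top provisions (default 50).
#' @param targetCumulative target cumulative frequency of the top `topN`
#'   (default 0.59).
#' @return the exponent, a positive real.
#' @export
calibrateProvisionExponent <- function(nProvisions, topN = 50,
                                       targetCumulative = 0.59) {
  if (topN >= nProvisions) stop("topN must be below nProvisions")
  f <- function(s) {
    w <- seq_len(nProvisions)^(-s)
    sum(w[seq_len(topN)]) / sum(w) - targetCumulative
  }
  if (f(0) >= 0) return(0)
  stats::uniroot(f, c(1e-9, 10), tol = 1e-10)$root
}

#' Synthetic booking generator configuration
#'
#' Collects every knob of the synthetic administrative-booking
#' generator. The defaults describe the `"ci"` preset: 2,000 patients
#' over three years with moderate facility loyalty, producing roughly
#' 60k bookings in seconds. The `"signal"` preset is the paper-shaped
#' setting used for end-to-end recovery experiments: a five-year period
#' with strong facility loyalty (0.9) and frequent follow-up bursts
#' (0.6), the temporal structure a temporal convolutional network should
#' exploit.
#'
#' @param preset `"ci"` or `"signal"`.
#' @param nPatients,nFacilities,nProvisions,nDistricts population sizes.
#'   Districts are assigned to facilities round-robin, so with the
#'   default 8 districts the most popular facilities span all of them.
#' @param periodStart,periodEnd observation period (ISO dates).
#' @param facilityPopularityExponent power-law skew of facility
#'   popularity (0 = uniform).
#' @param provisionFrequencyExponent power-law skew of provision
#'   frequencies; `NULL` calibrates it so the top 50 provisions carry
#'   59% of bookings (see [calibrateProvisionExponent()]).
#' @param patientRateShape,patientRateMean gamma parameters of the
#'   per-patient weekly booking intensity (mean is in bookings/week).
#' @param facilityLoyalty probability that a booking happens at the
#'   patient's home facility — the learnable signal.
#' @param revisitBurst probability that a booking spawns a follow-up at
#'   the same facility 4-12 weeks later.
#' @param invalidFraction,negativeWaitFraction,unknownIdFraction
#'   contamination rates: extra records with non-Valid status, negative
#'   waiting times, or blank facility ids, as fractions of the clean
#'   record count.
#' @param meanWaitDays mean prescription-to-appointment wait (geometric,
#'   days).
#' @param birthYearRange inclusive range of patient birth years.
#' @param seed integer seed; the generator output is fully determined by
#'   the configuration including this seed.
#' @return a validated configuration list of class `GeneratorConfig`.
#' @export
generatorConfig <- function(preset = c("ci", "signal"),
                            nPatients = NULL, nFacilities = 40,
                            nProvisions = 300, nDistricts = 8,
                            periodStart = NULL, periodEnd = NULL,
                            facilityPopularityExponent = 1.0,
                            provisionFrequencyExponent = NULL,
                            patientRateShape = 2,
                            patientRateMean = 0.19,
                            facilityLoyalty = NULL, revisitBurst = NULL,
                            invalidFraction = 0.05,
                            negativeWaitFraction = 0.02,
                            unknownIdFraction = 0.02,
                            meanWaitDays = 10,
                            birthYearRange = c(1930, 2010),
                            seed = 1) {
  preset <- match.arg(preset)
  if (preset == "ci") {
    if (is.null(nPatients)) nPatients <- 2000
    if (is.null(periodStart)) periodStart <- "2014-01-01"
    if (is.null(periodEnd)) periodEnd <- "2016-12-31"
    if (is.null(facilityLoyalty)) facilityLoyalty <- 0.8
    if (is.null(revisitBurst)) revisitBurst <- 0.3
  } else {
    if (is.null(nPatients)) nPatients <- 600
    if (is.null(periodStart)) periodStart <- "2014-01-01"
    if (is.null(periodEnd)) periodEnd <- "2018-12-31"
    if (is.null(facilityLoyalty)) facilityLoyalty <- 0.9
    if (is.null(revisitBurst)) revisitBurst <- 0.6
  }
  if (is.null(provisionFrequencyExponent))
    provisionFrequencyExponent <- calibrateProvisionExponent(nProvisions)
  cfg <- list(preset = preset, nPatients = as.integer(nPatients),
              nFacilities = as.integer(nFacilities),
              nProvisions = as.integer(nProvisions),
              nDistricts = as.integer(nDistricts),
              periodStart = as.Date(periodStart),
              periodEnd = as.Date(periodEnd),
              facilityPopularityExponent = facilityPopularityExponent,
              provisionFrequencyExponent = provisionFrequencyExponent,
              patientRateShape = patientRateShape,
              patientRateMean = patientRateMean,
              facilityLoyalty = facilityLoyalty,
              revisitBurst = revisitBurst,
              invalidFraction = invalidFraction,
              negativeWaitFraction = negativeWaitFraction,
              unknownIdFraction = unknownIdFraction,
              meanWaitDays = meanWaitDays,
              birthYearRange = as.integer(birthYearRange),
              seed = as.integer(seed))
  rates <- c(facilityLoyalty, revisitBurst, invalidFraction,
             negativeWaitFraction, unknownIdFraction)
  if (any(rates < 0 | rates > 1)) stop("rates must lie in [0, 1]")
  if (cfg$nFacilities < 12L)
    stop("nFacilities must be >= 12 so a top-10 plus remainder exists")
  if (cfg$periodEnd <= cfg$periodStart) stop("empty observation period")
  class(cfg) <- "GeneratorConfig"
  cfg
}

.facilityWeights <- function(cfg)
  seq_len(cfg$nFacilities)^(-cfg$facilityPopularityExponent)

#' Generate a synthetic patient population and facility metadata
#'
#' Genders are Bernoulli(0.5), birth years uniform over the configured
#' range; every patient gets a home facility drawn from the power-law
#' facility-popularity distribution, and inherits its district.
#' Facilities are partitioned among districts round-robin.
#'
#' @param config a [generatorConfig()].
#' @return list with `patients` (patient_id, gender, birth_year,
#'   home_facility, home_district) and `facilities` (facility_id,
#'   district_id).
#' @export
generatePopulation <- function(config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  fid <- .idMaker("F")(seq_len(config$nFacilities), config$nFacilities)
  did <- .idMaker("D")(
    ((seq_len(config$nFacilities) - 1L) %% config$nDistricts) + 1L,
    config$nDistricts)
  facilities <- data.frame(facility_id = fid, district_id = did,
                           stringsAsFactors = FALSE)
  withSeed(config$seed, {
    pid <- .idMaker("P")(seq_len(config$nPatients), config$nPatients)
    gender <- rbinom(config$nPatients, 1, 0.5)
    by <- sample(config$birthYearRange[1]:config$birthYearRange[2],
                 config$nPatients, replace = TRUE)
    home <- sample(fid, config$nPatients, replace = TRUE,
                   prob = .facilityWeights(config))
    patients <- data.frame(
      patient_id = pid, gender = gender, birth_year = by,
      home_facility = home,
      home_district = facilities$district_id[match(home, fid)],
      stringsAsFactors = FALSE)
  })
  list(patients = patients, facilities = facilities)
}

#' Generate synthetic booking records
#'
#' Per patient, weekly booking counts are Poisson with a gamma-drawn
#' rate; each booking is placed at the home facility with probability
#' `facilityLoyalty` (else a popularity-weighted draw), with a provision
#' from the heavy-tailed provision distribution and a geometric
#' prescription-to-appointment wait. With probability `revisitBurst` a
#' booking spawns a follow-up at the same facility 4-12 weeks later —
#' the temporal pattern a forecasting model can exploit. Contamination
#' records (non-Valid status, negative waits, blank facility ids) are
#' appended at the configured rates so the cleaning rules have work to
#' do.
#'
#' @param population from [generatePopulation()].
#' @param config the same [generatorConfig()].
#' @return a bookings data.frame (see [validateBookings()]), sorted by
#'   patient and appointment date; deterministic given the config seed.
#' @export
generateBookings <- function(population, config) {
  stopifnot(inherits(config, "GeneratorConfig"))
  cal <- weekCalendar(config$periodStart, config$periodEnd)
  T <- cal@nWeeks
  pts <- population$patients
  fid <- population$facilities$facility_id
  popW <- .facilityWeights(config)
  provIds <- .idMaker("S")(seq_len(config$nProvisions), config$nProvisions)
  provW <- seq_len(config$nProvisions)^(-config$provisionFrequencyExponent)
  geomProb <- 1 / (1 + config$meanWaitDays)

  withSeed(config$seed + 1L, {
    rate <- rgamma(nrow(pts), shape = config$patientRateShape,
                   scale = config$patientRateMean / config$patientRateShape)
    rows <- vector("list", nrow(pts))
    for (i in seq_len(nrow(pts))) {
      counts <- rpois(T, rate[i])
      n <- sum(counts)
      if (n == 0L) next
      wk <- rep.int(seq_len(T), counts)
      loyal <- runif(n) < config$facilityLoyalty
      fac <- character(n)
      fac[loyal] <- pts$home_facility[i]
      if (any(!loyal))
        fac[!loyal] <- sample(fid, sum(!loyal), replace = TRUE, prob = popW)
      ## follow-up bursts: same facility, 4-12 weeks later
      burst <- runif(n) < config$revisitBurst
      bw <- wk[burst] + sample(4:12, sum(burst), replace = TRUE)
      keepB <- bw <= T
      wk <- c(wk, bw[keepB]); fac <- c(fac, fac[burst][keepB])
      n <- length(wk)
      prov <- sample(provIds, n, replace = TRUE, prob = provW)
      day <- pmin(config$periodStart + (wk - 1L) * 7L + sample(0:6, n, TRUE),
                  config$periodEnd)
      wait <- rgeom(n, geomProb)
      presc <- day - wait
      age <- pmax(as.integer(format(presc, "%Y")) - pts$birth_year[i], 0L)
      rows[[i]] <- data.frame(
        patient_id = pts$patient_id[i], gender = pts$gender[i],
        age_at_prescription = age,
        practitioner_id = NA_character_,
        prescription_date = presc, appointment_date = day,
        status = "Valid", facility_id = fac, provision_id = prov,
        district_id = population$facilities$district_id[match(fac, fid)],
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    ## contamination: injected copies that the cleaning rules must remove
    contaminate <- function(nExtra, mutate) {
      if (nExtra == 0L || nrow(records) == 0L) return(NULL)
      idx <- sample(nrow(records), nExtra, replace = TRUE)
      mutate(records[idx, , drop = FALSE])
    }
    nRec <- nrow(records)
    bad <- list(
      contaminate(round(config$invalidFraction * nRec), function(d) {
        d$status <- sample(c("Cancelled", "Invalid"), nrow(d), TRUE); d
      }),
      contaminate(round(config$negativeWaitFraction * nRec), function(d) {
        d$prescription_date <- d$appointment_date + sample(1:30, nrow(d), TRUE)
        d
      }),
      contaminate(round(config$unknownIdFraction * nRec), function(d) {
        d$facility_id <- ""; d$district_id <- NA_character_; d
      }))
    records <- rbind(records, do.call(rbind, bad[!vapply(bad, is.null, TRUE)]))
  })
  ord <- order(records$patient_id, records$appointment_date,
               records$provision_id, records$facility_id, records$status)
  records <- records[ord, , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Generate a complete synthetic data set
#'
#' Convenience wrapper: population plus bookings, optionally written to
#' CSV (bookings and facility metadata).
#'
#' @param config a [generatorConfig()].
#' @param bookingsPath,facilitiesPath optional output CSV paths.
#' @return list with `bookings`, `patients`, `facilities`.
#' @export
generateDataset <- function(config, bookingsPath = NULL,
                            facilitiesPath = NULL) {
  pop <- generatePopulation(config)
  bookings <- generateBookings(pop, config)
  if (!is.null(bookingsPath)) writeBookings(bookings, bookingsPath)
  if (!is.null(facilitiesPath))
    write.csv(pop$facilities, facilitiesPath, row.names = FALSE, quote = FALSE)
  list(bookings = bookings, patients = pop$patients,
       facilities = pop$facilities)
}

#' Naive last-year attendance baseline
#'
#' Predicts that a patient will attend facility `j` in the forecast
#' period iff facility `j` was visited at least once during the 52 input
#' weeks (and analogously for the final other-facilities label). This is
#' the floor any trained model must beat on synthetic data with high
#' facility loyalty.
#'
#' @param ws a [WindowSet-class] (raw counts).
#' @return a [PredictionScores-class] with 0/1 scores and thresholds at
#'   0.5.
#' @export
naiveLastYearBaseline <- function(ws) {
  nTop <- length(ws@catalog@topFacilities)
  n <- nWindows(ws)
  visited <- t(vapply(seq_len(n), function(i)
    as.integer(colSums(ws@F[, , i, drop = FALSE][, , 1]) > 0),
    integer(dim(ws@F)[2])))
  yHat <- cbind(visited[, seq_len(nTop), drop = FALSE],
                as.integer(rowSums(
                  visited[, -seq_len(nTop), drop = FALSE]) > 0))
  new("PredictionScores", c = yHat + 0, theta = rep(0.5, nTop + 1L),
      yHat = yHat)
}
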