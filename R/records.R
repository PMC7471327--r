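## Booking records are kept as a plain data.frame with a fixed schema; the
## richer pipeline objects are S4. Required columns:
##   patient_id, gender, age_at_prescription, prescription_date,
##   appointment_date, status, facility_id, provision_id
## optional: practitioner_id, district_id.

.requiredColumns <- c("patient_id", "gender", "age_at_prescription",
                      "prescription_date", "appointment_date", "status",
                      "facility_id", "provision_id")

#' Validate a bookings data.frame
#'
#' Checks the schema and field invariants of a bookings table: required
#' columns present, dates of class `Date`, gender in \{0, 1\} and
#' non-negative ages (NA fields are allowed here; cleaning deals with
#' them).
#'
#' @param records a data.frame of booking records.
#' @return the records, invisibly; errors describe the first violation.
#' @export
validateBookings <- function(records) {
  missing <- setdiff(.requiredColumns, names(records))
  if (length(missing))
    stop("bookings table lacks required column(s): ",
         paste(missing, collapse = ", "))
  for (col in c("prescription_date", "appointment_date"))
    if (!inherits(records[[col]], "Date"))
      stop(col, " must be of class Date")
  g <- records$gender
  if (any(!is.na(g) & !(g %in% c(0, 1))))
    stop("gender must be coded 0 (male) or 1 (female)")
  a <- records$age_at_prescription
  if (any(!is.na(a) & a < 0)) stop("age_at_prescription must be >= 0")
  invisible(records)
}

#' Read booking records from a delimited file
#'
#' Reads a delimited text file with a header row into a validated
#' bookings data.frame. Rows whose dates do not parse as ISO-8601, or
#' whose gender/age violate the field invariants, are dropped, counted
#' and reported via attributes; a missing required column is a fatal
#' configuration error.
#'
#' @param path file to read.
#' @param sep field separator (default comma).
#' @param columnMap optional named character vector renaming file columns
#'   to schema columns, e.g. `c(patient_id = "PAT_ID")`.
#' @return a bookings data.frame with attributes `nMalformed` (count of
#'   skipped rows) and `malformedRows` (their original row numbers).
#' @export
readBookings <- function(path, sep = ",", columnMap = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- read.csv(path, sep = sep, colClasses = "character",
                  check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(columnMap))
    for (schema in names(columnMap)) {
      idx <- match(columnMap[[schema]], names(raw))
      if (!is.na(idx)) names(raw)[idx] <- schema
    }
  missing <- setdiff(.requiredColumns, names(raw))
  if (length(missing))
    stop("input file lacks required column(s): ",
         paste(missing, collapse = ", "))
  n <- nrow(raw)
  presc <- as.Date(raw$prescription_date, format = "%Y-%m-%d", optional = TRUE)
  appt <- suppressWarnings(
    as.Date(raw$appointment_date, format = "%Y-%m-%d", optional = TRUE))
  gender <- suppressWarnings(as.integer(raw$gender))
  age <- suppressWarnings(as.integer(raw$age_at_prescription))
  ## appointment_date may legitimately be blank (a defect the cleaning
  ## rules remove); a *non-blank* unparseable date is malformed input.
  apptBlank <- is.na(raw$appointment_date) |
    trimws(raw$appointment_date) == ""
  bad <- is.na(presc) |
    (is.na(appt) & !apptBlank) |
    is.na(gender) | !(gender %in% c(0L, 1L)) |
    is.na(age) | age < 0L
  records <- data.frame(
    patient_id = raw$patient_id,
    gender = gender,
    age_at_prescription = age,
    practitioner_id = if ("practitioner_id" %in% names(raw))
      raw$practitioner_id else NA_character_,
    prescription_date = presc,
    appointment_date = appt,
    status = raw$status,
    facility_id = raw$facility_id,
    provision_id = raw$provision_id,
    district_id = if ("district_id" %in% names(raw))
      raw$district_id else NA_character_,
    stringsAsFactors = FALSE)
  records <- records[!bad, , drop = FALSE]
  rownames(records) <- NULL
  if (n > 0 && any(bad))
    message(sum(bad), " malformed row(s) skipped while reading ", path)
  attr(records, "nMalformed") <- sum(bad)
  attr(records, "malformedRows") <- which(bad)
  validateBookings(records)
  records
}

#' Write booking records to a delimited file
#'
#' @param records a bookings data.frame.
#' @param path output file.
#' @param sep field separator.
#' @export
writeBookings <- function(records, path, sep = ",") {
  validateBookings(records)
  out <- records
  out$prescription_date <- format(out$prescription_date, "%Y-%m-%d")
  out$appointment_date <- format(out$appointment_date, "%Y-%m-%d")
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE,
              na = "")
  invisible(path)
}

.defaultUnknownIds <- c("", "UNKNOWN", "NA")

#' Clean booking records
#'
#' Applies the five cleaning rules of the administrative-booking
#' preprocessing, in order: (1) remove records with unknown/blank
#' patient, provision or facility identifiers (encoding errors); (2) keep
#' only appointments with status `"Valid"`; (3) keep only patients with
#' at least `minAppointments` surviving appointments over the reference
#' period; (4) remove invalid records with no appointment date; (5)
#' remove records with negative waiting time (appointment before
#' prescription).
#'
#' Rule 3 counts the records that survive the other four rules, so the
#' operation is idempotent: every patient in the output retains at least
#' `minAppointments` records and a second pass removes nothing. In the
#' report each removed record is attributed to the first rule, in the
#' stated order, whose condition it violates.
#'
#' @param records a bookings data.frame.
#' @param minAppointments minimum surviving appointments per patient
#'   (default 5).
#' @param unknownIds character vector of identifier values treated as
#'   encoding errors (besides `NA`).
#' @return a list with elements `records` (the survivors, original order
#'   preserved) and `report` (a [CleaningReport-class]).
#' @export
cleanRecords <- function(records, minAppointments = 5,
                         unknownIds = .defaultUnknownIds) {
  validateBookings(records)
  isUnknown <- function(x) is.na(x) | trimws(x) %in% unknownIds
  v1 <- isUnknown(records$patient_id) | isUnknown(records$provision_id) |
    isUnknown(records$facility_id)
  v2 <- is.na(records$status) | records$status != "Valid"
  v4 <- is.na(records$appointment_date)
  v5 <- !v4 & !is.na(records$prescription_date) &
    records$appointment_date < records$prescription_date
  survivesOther <- !(v1 | v2 | v4 | v5)
  counts <- table(records$patient_id[survivesOther])
  keepPatient <- names(counts)[counts >= minAppointments]
  v3 <- !(records$patient_id %in% keepPatient)
  keep <- survivesOther & !v3
  removed <- !keep
  firstRule <- rep(NA_integer_, nrow(records))
  ruleOrder <- list(v1, v2, v3, v4, v5)
  for (r in rev(seq_along(ruleOrder)))
    firstRule[removed & ruleOrder[[r]]] <- r
  ruleNames <- c("unknown_identifier", "non_valid_status",
                 "too_few_appointments", "missing_appointment_date",
                 "negative_waiting_time")
  removedPerRule <- vapply(seq_along(ruleNames),
                           function(r) sum(firstRule == r, na.rm = TRUE), 0L)
  names(removedPerRule) <- ruleNames
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  report <- new("CleaningReport",
                removedPerRule = removedPerRule,
                recordsIn = nrow(records), recordsOut = nrow(out),
                patientsIn = length(unique(records$patient_id)),
                patientsOut = length(unique(out$patient_id)))
  list(records = out, report = report)
}

#' Build per-patient profiles
#'
#' Derives one profile per patient from cleaned records: gender (the mode
#' across the patient's records, ties resolved to 0 with a warning) and
#' the estimated birth year, the minimum over the patient's records of
#' prescription year minus age at prescription.
#'
#' @param records cleaned bookings data.frame.
#' @return data.frame with columns `patient_id`, `gender`, `birth_year`.
#' @export
buildProfiles <- function(records) {
  validateBookings(records)
  if (nrow(records) == 0)
    return(data.frame(patient_id = character(), gender = integer(),
                      birth_year = integer()))
  py <- as.integer(format(records$prescription_date, "%Y"))
  birthCandidate <- py - records$age_at_prescription
  sp <- split(seq_len(nrow(records)), records$patient_id)
  conflicts <- 0L
  profiles <- lapply(sp, function(idx) {
    g <- records$gender[idx]
    tab <- table(g)
    if (length(tab) > 1L) {
      conflicts <<- conflicts + 1L
      g <- if (tab[["0"]] >= tab[["1"]]) 0L else 1L
    } else g <- g[1]
    c(gender = as.integer(g), birth_year = min(birthCandidate[idx]))
  })
  if (conflicts > 0L)
    warning(conflicts,
            " patient(s) had conflicting gender codes; mode taken (ties -> 0)")
  out <- data.frame(patient_id = names(sp),
                    gender = vapply(profiles, `[[`, 0L, "gender"),
                    birth_year = vapply(profiles, `[[`, 0L, "birth_year"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Descriptive entity summaries of a booking table
#'
#' Computes (a) the number of unique occurrences of each entity of
#' interest, (b) the relative frequency of every provision sorted
#' descending, (c) the cumulative frequency captured by the top-n
#' provisions for the requested `n`, and (d) monthly appointment counts.
#'
#' @param records bookings data.frame.
#' @param topN integer vector of n values for the cumulative-frequency
#'   table.
#' @return list with elements `entities`, `provisionFrequencies`,
#'   `cumulativeTopN`, `monthlyCounts`.
#' @export
summarizeEntities <- function(records, topN = c(50, 100, 150, 200)) {
  validateBookings(records)
  entities <- data.frame(
    entity = c("appointments", "patients", "provisions",
               "appointment_dates", "facilities"),
    count = c(nrow(records),
              length(unique(records$patient_id)),
              length(unique(records$provision_id)),
              length(unique(records$appointment_date[
                !is.na(records$appointment_date)])),
              length(unique(records$facility_id))))
  tab <- sort(table(records$provision_id), decreasing = TRUE)
  freq <- data.frame(provision_id = names(tab),
                     count = as.integer(tab),
                     frequency = as.numeric(tab) / max(1L, nrow(records)),
                     stringsAsFactors = FALSE)
  topN <- pmin(topN, nrow(freq))
  cumtab <- data.frame(
    n = topN,
    cumulative_frequency = vapply(topN, function(n)
      sum(freq$frequency[seq_len(n)]), 0))
  month <- format(records$appointment_date, "%Y-%m")
  mc <- table(month[!is.na(month)])
  monthly <- data.frame(month = names(mc), count = as.integer(mc),
                        stringsAsFactors = FALSE)
  list(entities = entities, provisionFrequencies = freq,
       cumulativeTopN = cumtab, monthlyCounts = monthly)
}

#' Serialize a cleaning report as JSON
#'
#' @param report a [CleaningReport-class].
#' @param path optional output file; if `NULL` the JSON string is
#'   returned.
#' @export
cleaningReportJSON <- function(report, path = NULL) {
  x <- list(records_in = report@recordsIn, records_out = report@recordsOut,
            patients_in = report@patientsIn,
            patients_out = report@patientsOut,
            removed_per_rule = as.list(report@removedPerRule))
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}
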