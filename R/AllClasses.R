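#' facast: facility attendance forecasting from medical booking histories
#'
#' Multi-label prediction of which medical facilities a patient will
#' attend in the next nine weeks from 52 weeks of administrative booking
#' history: record cleaning, weekly count matrices, provision clustering,
#' facility ranking, sliding-window extraction and labeling, a structured
#' temporal convolutional network trained with the BP-MLL ranking loss,
#' baselines, a full multi-label evaluation suite, and a seeded synthetic
#' booking generator. Start with [generateDataset()], [cleanRecords()],
#' [prepareWindows()], [trainTCNN()] and [evaluatePredictions()]; the
#' package vignette walks through the method.
#'
#' @import methods
#' @importFrom stats kmeans rnorm runif rgamma rpois rgeom rbinom sd
#' @importFrom utils read.csv write.csv write.table head
#' @useDynLib facast, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @keywords internal
"_PACKAGE"

#' Weekly calendar over an observation period
#'
#' Maps calendar dates to consecutive 1-based week indices. Weeks are
#' 7-day blocks anchored at `periodStart`; the number of weeks is
#' `ceiling((periodEnd - periodStart + 1) / 7)` so the final week may be
#' partial.
#'
#' @slot periodStart,periodEnd `Date` bounds of the observation period
#'   (inclusive).
#' @slot nWeeks integer number of weeks covered.
#' @export
setClass("WeekCalendar",
  representation(periodStart = "Date", periodEnd = "Date", nWeeks = "integer"),
  validity = function(object) {
    if (length(object@periodStart) != 1L || length(object@periodEnd) != 1L)
      return("periodStart and periodEnd must be single dates")
    if (is.na(object@periodStart) || is.na(object@periodEnd))
      return("calendar bounds must not be NA")
    if (object@periodEnd < object@periodStart)
      return("periodEnd must not precede periodStart")
    expect <- as.integer(ceiling(
      as.numeric(object@periodEnd - object@periodStart + 1L) / 7))
    if (object@nWeeks != expect)
      return(sprintf("nWeeks is %d but the period implies %d",
                     object@nWeeks, expect))
    TRUE
  })

#' Audit trail of record cleaning
#'
#' Records how many booking records each cleaning rule removed (a record
#' is attributed to the first rule, in the stated order, whose condition
#' it violates) together with record and patient totals before and after.
#'
#' @slot removedPerRule named integer vector, one entry per rule.
#' @slot recordsIn,recordsOut,patientsIn,patientsOut integer totals.
#' @export
setClass("CleaningReport",
  representation(removedPerRule = "integer", recordsIn = "integer",
                 recordsOut = "integer", patientsIn = "integer",
                 patientsOut = "integer"),
  validity = function(object) {
    if (object@recordsOut != object@recordsIn - sum(object@removedPerRule))
      return("recordsOut must equal recordsIn - sum(removedPerRule)")
    if (any(object@removedPerRule < 0L)) return("negative removal count")
    TRUE
  })

#' Partition of health-service provisions into clusters
#'
#' @slot assignment named integer vector mapping provision id to a
#'   cluster index in `1..k`.
#' @slot k integer number of clusters.
#' @slot centers cluster centers in standardized feature space.
#' @slot features the standardized per-provision feature matrix that was
#'   clustered.
#' @slot wcss total within-cluster sum of squares of the retained fit.
#' @export
setClass("ProvisionClustering",
  representation(assignment = "integer", k = "integer", centers = "matrix",
                 features = "matrix", wcss = "numeric"),
  validity = function(object) {
    if (is.null(names(object@assignment)))
      return("assignment must be named by provision id")
    if (any(object@assignment < 1L) || any(object@assignment > object@k))
      return("cluster indices must lie in 1..k")
    TRUE
  })

#' Facility ranking and column regrouping
#'
#' Holds the top facilities (ranked by appointment volume in the forecast
#' horizons of the extracted windows), and a total map from every facility
#' to a feature column: ranks `1..nTop` for the top facilities, one column
#' per district represented among them, and a final rest-of-the-universe
#' column.
#'
#' @slot topFacilities character vector of facility ids, best rank first.
#' @slot districtOf named character vector, facility id to district id.
#' @slot columnOf named integer vector, facility id to column in
#'   `1..nColumns`.
#' @slot districts character vector of the districts represented by the
#'   top facilities, in the order of their group columns.
#' @slot nColumns integer total number of facility columns.
#' @export
setClass("FacilityCatalog",
  representation(topFacilities = "character", districtOf = "character",
                 columnOf = "integer", districts = "character",
                 nColumns = "integer"),
  validity = function(object) {
    nTop <- length(object@topFacilities)
    if (object@nColumns != nTop + length(object@districts) + 1L)
      return("nColumns must be nTop + number of district groups + 1")
    if (any(object@columnOf < 1L) || any(object@columnOf > object@nColumns))
      return("columnOf values must lie in 1..nColumns")
    if (!all(object@topFacilities %in% names(object@columnOf)))
      return("every top facility needs a column")
    TRUE
  })

#' Feature scaling configuration
#'
#' `lambda` parameterizes the count map `phi(x) = 1 - lambda^(-x)`, which
#' compresses appointment counts into `[0, 1)` while emphasizing
#' differences among small counts; ages are min-max scaled over
#' `[ageMin, ageMax]`.
#'
#' @slot lambda positive real, strictly greater than 1; default `e/2`.
#' @slot ageMin,ageMax age bounds in years for min-max scaling.
#' @export
setClass("ScalingConfig",
  representation(lambda = "numeric", ageMin = "numeric", ageMax = "numeric"),
  prototype(lambda = exp(1) / 2, ageMin = 0, ageMax = 120),
  validity = function(object) {
    if (object@lambda <= 1) return("lambda must exceed 1")
    if (object@ageMax <= object@ageMin) return("ageMax must exceed ageMin")
    TRUE
  })

#' A set of labeled 52-week booking windows
#'
#' The central modeling container. Each of the `n` windows holds raw
#' (unscaled) weekly appointment counts: `P` over provision clusters,
#' `F` over facility columns for the 52 input weeks, and `Ftilde` over the
#' same facility columns for the 9 forecast weeks, together with the
#' patient's gender, age (in years, at the first week of the window) and
#' the 11-component label vector derived from `Ftilde`.
#'
#' @slot P integer array `52 x kP x n`.
#' @slot F integer array `52 x dF x n`.
#' @slot Ftilde integer array `9 x dF x n`.
#' @slot gender numeric length `n`, 0 = male, 1 = female.
#' @slot age numeric length `n`, years.
#' @slot y integer matrix `n x 11`.
#' @slot patientId character length `n`.
#' @slot windowId integer length `n`, the start week of the window.
#' @slot catalog the [FacilityCatalog-class] that defined the facility
#'   columns.
#' @export
setClass("WindowSet",
  representation(P = "array", F = "array", Ftilde = "array",
                 gender = "numeric", age = "numeric", y = "matrix",
                 patientId = "character", windowId = "integer",
                 catalog = "FacilityCatalog"),
  validity = function(object) {
    n <- dim(object@P)[3]
    if (dim(object@F)[3] != n || dim(object@Ftilde)[3] != n ||
        length(object@gender) != n || length(object@age) != n ||
        nrow(object@y) != n || length(object@patientId) != n ||
        length(object@windowId) != n)
      return("window counts disagree across slots")
    if (dim(object@F)[2] != dim(object@Ftilde)[2])
      return("F and Ftilde must share facility columns")
    if (ncol(object@y) != length(object@catalog@topFacilities) + 1L)
      return("y must have one column per top facility plus one")
    if (n > 0 && (min(object@P) < 0 || min(object@F) < 0 ||
                  min(object@Ftilde) < 0))
      return("counts must be non-negative")
    TRUE
  })

#' Trained temporal convolutional network
#'
#' @slot config the network configuration list (see [networkConfig()]).
#' @slot weights convolutional and dense weights as returned by training.
#' @slot thresholds per-label decision thresholds calibrated on the
#'   validation split.
#' @slot trainingLog data.frame with one row per epoch (train and
#'   validation loss).
#' @slot scaling the [ScalingConfig-class] applied to inputs.
#' @export
setClass("TCNNModel",
  representation(config = "list", weights = "list", thresholds = "numeric",
                 trainingLog = "data.frame", scaling = "ScalingConfig"))

#' Trained flat-input baseline (random forest or MLP)
#'
#' @slot kind `"rf"` or `"mlp"`.
#' @slot fit the underlying fitted object.
#' @slot thresholds per-label decision thresholds (MLP) or `NA` (RF,
#'   which predicts by most probable label combination).
#' @slot config fitting parameters.
#' @slot scaling the [ScalingConfig-class] applied to inputs.
#' @export
setClass("BaselineModel",
  representation(kind = "character", fit = "ANY", thresholds = "numeric",
                 config = "list", scaling = "ScalingConfig"))

#' Continuous scores, thresholds and binarized predictions
#'
#' @slot c numeric matrix `n x 11` of continuous model outputs.
#' @slot theta numeric length-11 per-label thresholds.
#' @slot yHat integer matrix `n x 11`; `yHat[i, j] = 1` iff
#'   `c[i, j] > theta[j]`.
#' @export
setClass("PredictionScores",
  representation(c = "matrix", theta = "numeric", yHat = "matrix"),
  validity = function(object) {
    if (!all(dim(object@c) == dim(object@yHat)))
      return("c and yHat must share dimensions")
    if (length(object@theta) != ncol(object@c))
      return("one threshold per label is required")
    ok <- object@yHat == (sweep(object@c, 2, object@theta, ">")) * 1L
    if (!all(ok)) return("yHat must equal c > theta elementwise")
    TRUE
  })

#' Multi-label evaluation report
#'
#' @slot meanHamming mean Hamming distance over the evaluated windows.
#' @slot exactAccuracy fraction of windows with all 11 labels correct.
#' @slot top10ExactAccuracy same with the last label ignored.
#' @slot perLabel data.frame of per-label accuracy, precision, recall,
#'   F1 and AUC.
#' @slot overall named numeric with micro- and macro-averaged precision,
#'   recall, F1 and AUC.
#' @slot firstAccess data.frame of first-access accuracy per facility.
#' @slot lowerBound data.frame of predicted vs actual positives per
#'   facility.
#' @slot n number of evaluated windows.
#' @slot flags character vector of degeneracy notes (undefined precision,
#'   constant labels, empty first-access subsets).
#' @export
setClass("MetricsReport",
  representation(meanHamming = "numeric", exactAccuracy = "numeric",
                 top10ExactAccuracy = "numeric", perLabel = "data.frame",
                 overall = "numeric", firstAccess = "data.frame",
                 lowerBound = "data.frame", n = "integer",
                 flags = "character"))
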