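#' @rdname WindowSet-class
#' @param x,object a `WindowSet`.
#' @export
setGeneric("nWindows", function(x) standardGeneric("nWindows"))

#' @rdname WindowSet-class
#' @export
setMethod("nWindows", "WindowSet", function(x) dim(x@P)[3])

#' @rdname WindowSet-class
#' @export
setGeneric("labels11", function(x) standardGeneric("labels11"))

#' @rdname WindowSet-class
#' @export
setMethod("labels11", "WindowSet", function(x) x@y)

#' @rdname FacilityCatalog-class
#' @param x a `FacilityCatalog`.
#' @export
setGeneric("topFacilities", function(x) standardGeneric("topFacilities"))

#' @rdname FacilityCatalog-class
#' @export
setMethod("topFacilities", "FacilityCatalog", function(x) x@topFacilities)

#' @rdname FacilityCatalog-class
#' @export
setGeneric("facilityColumn", function(x) standardGeneric("facilityColumn"))

#' @rdname FacilityCatalog-class
#' @export
setMethod("facilityColumn", "FacilityCatalog", function(x) x@columnOf)

#' @rdname ProvisionClustering-class
#' @param x a `ProvisionClustering`.
#' @export
setGeneric("clusterAssignment", function(x) standardGeneric("clusterAssignment"))

#' @rdname ProvisionClustering-class
#' @export
setMethod("clusterAssignment", "ProvisionClustering", function(x) x@assignment)

#' Subset a WindowSet
#'
#' @param x a `WindowSet`.
#' @param i integer or logical index over windows.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "WindowSet", function(x, i, j, ..., drop = FALSE) {
  if (is.logical(i)) i <- which(i)
  new("WindowSet",
      P = x@P[, , i, drop = FALSE], F = x@F[, , i, drop = FALSE],
      Ftilde = x@Ftilde[, , i, drop = FALSE],
      gender = x@gender[i], age = x@age[i],
      y = x@y[i, , drop = FALSE],
      patientId = x@patientId[i], windowId = x@windowId[i],
      catalog = x@catalog)
})

setMethod("show", "WeekCalendar", function(object) {
  cat(sprintf("WeekCalendar: %s .. %s (%d weeks)\n",
              format(object@periodStart), format(object@periodEnd),
              object@nWeeks))
})

setMethod("show", "CleaningReport", function(object) {
  cat(sprintf("CleaningReport: %d -> %d records (%d -> %d patients)\n",
              object@recordsIn, object@recordsOut,
              object@patientsIn, object@patientsOut))
  for (r in names(object@removedPerRule))
    cat(sprintf("  %-22s %d\n", r, object@removedPerRule[[r]]))
})

setMethod("show", "ProvisionClustering", function(object) {
  cat(sprintf("ProvisionClustering: %d provisions in %d clusters (WCSS %.3f)\n",
              length(object@assignment), object@k, object@wcss))
  print(table(object@assignment))
})

setMethod("show", "FacilityCatalog", function(object) {
  cat(sprintf(
    "FacilityCatalog: %d top facilities, %d district groups + rest (%d columns)\n",
    length(object@topFacilities), length(object@districts), object@nColumns))
  cat("  top:", paste(head(object@topFacilities, 5), collapse = ", "),
      if (length(object@topFacilities) > 5) "..." else "", "\n")
})

setMethod("show", "WindowSet", function(object) {
  d <- dim(object@P)
  cat(sprintf(
    "WindowSet: %d windows from %d patients (P %dx%d, F %dx%d, horizon %d)\n",
    nWindows(object), length(unique(object@patientId)),
    d[1], d[2], dim(object@F)[1], dim(object@F)[2], dim(object@Ftilde)[1]))
  if (nWindows(object) > 0)
    cat("  label prevalence:",
        paste(sprintf("%.2f", colMeans(object@y)), collapse = " "), "\n")
})

setMethod("show", "TCNNModel", function(object) {
  cat(sprintf("TCNNModel: %d kernel sizes x %d filters, hidden %s, %d labels\n",
              length(object@config$kernelSizes), object@config$nFilters,
              paste(object@config$hidden, collapse = "/"),
              object@config$nLabels))
  if (nrow(object@trainingLog) > 0)
    cat(sprintf("  trained %d epochs, best validation loss %.5f\n",
                nrow(object@trainingLog), min(object@trainingLog$valLoss)))
})

setMethod("show", "PredictionScores", function(object) {
  cat(sprintf("PredictionScores: %d windows x %d labels, %.3f mean positives/row\n",
              nrow(object@c), ncol(object@c), mean(rowSums(object@yHat))))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport on %d windows\n", object@n))
  cat(sprintf("  mean Hamming distance  %.5f\n", object@meanHamming))
  cat(sprintf("  exact accuracy         %.5f\n", object@exactAccuracy))
  cat(sprintf("  top-10 exact accuracy  %.5f\n", object@top10ExactAccuracy))
  ov <- object@overall
  cat(sprintf("  micro P/R/F1/AUC       %.4f %.4f %.4f %.4f\n",
              ov["microPrecision"], ov["microRecall"], ov["microF1"],
              ov["microAUC"]))
  cat(sprintf("  macro P/R/F1/AUC       %.4f %.4f %.4f %.4f\n",
              ov["macroPrecision"], ov["macroRecall"], ov["macroF1"],
              ov["macroAUC"]))
  if (length(object@flags)) cat("  flags:", length(object@flags), "\n")
})
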