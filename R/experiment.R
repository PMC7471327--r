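#' Split window indices into train/validation/test
#'
#' Shuffles the windows and splits at the window level. Fractions must
#' sum to 1; the neural models default to 72/18/10 and the random
#' forest to 90/10 (no validation). A `byPatient` option keeps every
#' patient's windows in a single partition, preventing the leakage that
#' window-level splitting permits.
#'
#' @param ws a [WindowSet-class] (or an integer count for plain index
#'   splitting).
#' @param fractions numeric vector of 2 (train, test) or 3 (train,
#'   validation, test) fractions summing to 1.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param byPatient split whole patients instead of windows.
#' @return list with integer elements `train`, `val` (possibly empty)
#'   and `test`; disjoint and exhaustive.
#' @export
splitWindows <- function(ws, fractions = c(0.72, 0.18, 0.10), seed = NULL,
                         byPatient = FALSE) {
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  if (!length(fractions) %in% c(2L, 3L))
    stop("provide 2 (train/test) or 3 (train/val/test) fractions")
  n <- if (is(ws, "WindowSet")) nWindows(ws) else as.integer(ws)
  if (byPatient) {
    if (!is(ws, "WindowSet")) stop("byPatient splitting needs a WindowSet")
    patients <- unique(ws@patientId)
    perm <- withSeed(seed, sample(patients))
    cut <- round(cumsum(fractions) * length(perm))
    grp <- rep.int(seq_along(fractions), diff(c(0L, cut)))
    groupOf <- grp[match(ws@patientId, perm)]
  } else {
    perm <- withSeed(seed, sample(n))
    cut <- round(cumsum(fractions) * n)
    groupOf <- integer(n)
    groupOf[perm] <- rep.int(seq_along(fractions),
                             diff(c(0L, cut)))
  }
  if (length(fractions) == 2L)
    list(train = which(groupOf == 1L), val = integer(0),
         test = which(groupOf == 2L))
  else
    list(train = which(groupOf == 1L), val = which(groupOf == 2L),
         test = which(groupOf == 3L))
}

#' Run the full repeated-evaluation experiment
#'
#' For each run `r` in `1..nRuns` (seeded `baseSeed + r`): rebalance the
#' windows (keeping all windows with a top-facility label and a
#' `keepFraction` sample of the rest), split at the window level, train
#' the selected method, calibrate thresholds where applicable, and
#' evaluate on the test split. Metrics are aggregated as mean and
#' standard deviation over runs.
#'
#' @param ws a [WindowSet-class] of labeled windows.
#' @param method `"tcnn"`, `"mlp"` or `"rf"`.
#' @param nRuns number of repeated runs (the reference protocol uses
#'   15).
#' @param fractions split fractions; default 72/18/10 for the neural
#'   models and 90/10 for the random forest.
#' @param keepFraction rebalancing fraction for last-label-only windows
#'   (default 1/7).
#' @param config optional [networkConfig()] or RF config list.
#' @param scaling a [ScalingConfig-class].
#' @param baseSeed integer base seed.
#' @param byPatient split whole patients instead of windows.
#' @param verbose print per-epoch training progress.
#' @return list with `runs` (per-run [MetricsReport-class]s), `rows`
#'   (one data.frame row per run), and `summary` (mean and sd per
#'   metric).
#' @export
runExperiment <- function(ws, method = c("tcnn", "mlp", "rf"), nRuns = 2,
                          fractions = NULL, keepFraction = 1 / 7,
                          config = NULL, scaling = new("ScalingConfig"),
                          baseSeed = 1, byPatient = FALSE,
                          verbose = FALSE) {
  method <- match.arg(method)
  if (is.null(fractions))
    fractions <- if (method == "rf") c(0.90, 0.10) else c(0.72, 0.18, 0.10)
  runs <- list(); rows <- NULL
  for (r in seq_len(nRuns)) {
    seed <- baseSeed + r
    rws <- rebalanceWindows(ws, keepFraction = keepFraction, seed = seed)
    sp <- splitWindows(rws, fractions, seed = seed, byPatient = byPatient)
    report <- tryCatch({
      model <- switch(method,
        tcnn = trainTCNN(rws, sp$train, sp$val, config = config,
                         scaling = scaling, seed = seed,
                         verbose = verbose),
        mlp = fitBaseline("mlp", rws, sp$train, sp$val, config = config,
                          scaling = scaling, seed = seed),
        rf = fitBaseline("rf", rws, sp$train, config = config,
                         scaling = scaling, seed = seed))
      pred <- predictScores(model, rws, sp$test)
      evaluatePredictions(rws, pred, sp$test)
    }, error = function(e) {
      warning("run ", r, " failed: ", conditionMessage(e))
      NULL
    })
    if (is.null(report)) next
    runs[[length(runs) + 1L]] <- report
    rows <- rbind(rows, cbind(run = r, metricsRow(report)))
  }
  if (is.null(rows)) stop("all runs failed")
  num <- rows[, setdiff(names(rows), "run"), drop = FALSE]
  summary <- data.frame(
    metric = names(num),
    mean = vapply(num, mean, 0, na.rm = TRUE),
    sd = if (nrow(num) >= 2) vapply(num, sd, 0, na.rm = TRUE)
    else NA_real_,
    row.names = NULL)
  list(runs = runs, rows = rows, summary = summary)
}
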