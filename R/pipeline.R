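#' Run the full synthetic pipeline end to end
#'
#' Convenience wrapper chaining the stages on a synthetic cohort:
#' simulate spectra, build the crop/threshold feature matrix, run the
#' cross-validated (or hold-out) comparison, and assemble the evaluation
#' report. Fully determined by the design seed and the config seed.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param config a \code{\link{modelConfig}}.
#' @param window analyte \linkS4class{CropWindow}; defaults to
#'   \code{\link{defaultCropWindow}(design)}.
#' @param backgroundRegion background region(s); defaults to
#'   \code{\link{defaultBackgroundRegion}(design)}.
#' @param binSize feature bin edge (see \code{\link{buildFeatureMatrix}}).
#' @param comparison report label; defaults to "G0 vs G1".
#' @return list with \code{cohort} (see \code{\link{simulateCohort}}),
#'   \code{features} (\linkS4class{FeatureMatrix}), \code{predictionSet}
#'   (\linkS4class{PredictionSet}) and \code{report} (data.frame).
#' @examples
#' \donttest{
#' d <- cohortDesign(nPerGroup = c(8, 8), shape = c(60, 50),
#'                   ripDriftIndex = 12, nSharedPeaks = 10, seed = 3)
#' out <- runPipeline(d, modelConfig(nFeatures = 20, nFolds = 4,
#'                                   classifiers = "SVM"))
#' out$report
#' }
#' @export
runPipeline <- function(design, config = modelConfig(), window = NULL,
                        backgroundRegion = NULL, binSize = 1L,
                        comparison = "G0 vs G1") {
  if (is.null(window)) window <- defaultCropWindow(design)
  if (is.null(backgroundRegion))
    backgroundRegion <- defaultBackgroundRegion(design)
  cohort <- simulateCohort(design)
  fm <- buildFeatureMatrix(cohort$spectra, window, backgroundRegion,
                           binSize = binSize,
                           labels = paste0("G", cohort$labels))
  ps <- if (config$mode == "HOLDOUT") runHoldout(fm, config = config)
        else runCV(fm, config = config)
  report <- buildReport(ps, comparison = comparison)
  list(cohort = cohort, features = fm, predictionSet = ps, report = report)
}

#' Write held-out predictions / a report to CSV
#'
#' Plain-text serializations used by the reporting layer; both are exact
#' (\code{read.csv} restores the values used to build the report, so a
#' report regenerated from the file equals the in-run report).
#'
#' @param x a \linkS4class{PredictionSet} (for predictions) or a report
#'   data.frame.
#' @param path destination CSV path.
#' @return the path, invisibly.
#' @export
writePredictions <- function(x, path) {
  if (is(x, "PredictionSet")) x <- x@predictions
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writePredictions
#' @export
writeReport <- function(x, path) {
  write.csv(x, path, row.names = FALSE)
  invisible(path)
}
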