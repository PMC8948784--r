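#' @import methods
#' @importFrom stats rnorm runif sd qnorm pnorm pwilcox var rbeta optim
#' @importFrom utils combn read.csv write.csv
#' @useDynLib vocims, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

## ---------------------------------------------------------------------------
## GCIMSSpectrum: one sample's dense 2-D intensity map. Rows follow the GC
## retention axis, columns the IMS drift axis.
## ---------------------------------------------------------------------------

#' GCIMSSpectrum: a single GC-IMS measurement
#'
#' Container for the dense two-dimensional intensity matrix produced by a
#' gas chromatography-ion mobility spectrometry run, together with its axis
#' metadata. Rows are indexed by GC retention time (seconds), columns by IMS
#' drift time (milliseconds or RIP-relative units). All downstream
#' processing is index-based; the axes are carried for plotting and
#' reporting only.
#'
#' @slot sampleId single character identifier.
#' @slot intensities numeric matrix, rows = retention, columns = drift;
#'   all values must be finite.
#' @slot retentionAxis strictly increasing numeric vector, one entry per row.
#' @slot driftAxis strictly increasing numeric vector, one entry per column.
#' @slot meta free-form named list (instrument, run date, units, ...).
#'
#' @aliases GCIMSSpectrum-class
#' @exportClass GCIMSSpectrum
setClass("GCIMSSpectrum",
  slots = c(
    sampleId      = "character",
    intensities   = "matrix",
    retentionAxis = "numeric",
    driftAxis     = "numeric",
    meta          = "list"
  )
)

setValidity("GCIMSSpectrum", function(object) {
  msg <- character(0)
  m <- object@intensities
  if (length(object@sampleId) != 1L || is.na(object@sampleId))
    msg <- c(msg, "'sampleId' must be a single non-missing string")
  if (!is.numeric(m))
    msg <- c(msg, "'intensities' must be numeric")
  if (nrow(m) != length(object@retentionAxis))
    msg <- c(msg, sprintf(
      "row count (%d) must equal length of retentionAxis (%d)",
      nrow(m), length(object@retentionAxis)))
  if (ncol(m) != length(object@driftAxis))
    msg <- c(msg, sprintf(
      "column count (%d) must equal length of driftAxis (%d)",
      ncol(m), length(object@driftAxis)))
  if (anyNA(m) || !all(is.finite(m)))
    msg <- c(msg, "all intensities must be finite (no NA/NaN/Inf)")
  if (length(object@retentionAxis) > 1 &&
      any(diff(object@retentionAxis) <= 0))
    msg <- c(msg, "retentionAxis must be strictly increasing")
  if (length(object@driftAxis) > 1 && any(diff(object@driftAxis) <= 0))
    msg <- c(msg, "driftAxis must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a GCIMSSpectrum
#'
#' @param intensities numeric matrix (retention rows x drift columns).
#' @param retentionAxis numeric vector of retention times (seconds); defaults
#'   to the row index.
#' @param driftAxis numeric vector of drift times; defaults to the column
#'   index.
#' @param sampleId sample identifier.
#' @param meta named list of free-form metadata.
#' @return a validated \linkS4class{GCIMSSpectrum}.
#' @examples
#' sp <- GCIMSSpectrum(matrix(runif(12), 3, 4))
#' dim(intensities(sp))
#' @export
GCIMSSpectrum <- function(intensities,
                          retentionAxis = seq_len(nrow(intensities)),
                          driftAxis = seq_len(ncol(intensities)),
                          sampleId = "sample", meta = list()) {
  new("GCIMSSpectrum",
      sampleId = as.character(sampleId),
      intensities = as.matrix(intensities),
      retentionAxis = as.numeric(retentionAxis),
      driftAxis = as.numeric(driftAxis),
      meta = meta)
}

setMethod("show", "GCIMSSpectrum", function(object) {
  m <- object@intensities
  cat("GCIMSSpectrum '", object@sampleId, "'\n", sep = "")
  cat(sprintf("  %d retention x %d drift points (%s datapoints)\n",
              nrow(m), ncol(m), format(length(m), big.mark = ",")))
  cat(sprintf("  intensity range [%.4g, %.4g]\n", min(m), max(m)))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), collapse = ", "), "\n")
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## CropWindow: a rectangular index window, 1-based inclusive on both axes.
## ---------------------------------------------------------------------------

#' CropWindow: rectangular index window on a spectrum
#'
#' 1-based inclusive row/column bounds selecting a rectangular region of a
#' \linkS4class{GCIMSSpectrum}. Used both for the analyte crop and for
#' background-estimation regions.
#'
#' @slot rows integer vector \code{c(lo, hi)}, inclusive retention rows.
#' @slot cols integer vector \code{c(lo, hi)}, inclusive drift columns.
#' @aliases CropWindow-class
#' @exportClass CropWindow
setClass("CropWindow", slots = c(rows = "integer", cols = "integer"))

setValidity("CropWindow", function(object) {
  msg <- character(0)
  for (ax in c("rows", "cols")) {
    b <- slot(object, ax)
    if (length(b) != 2L || anyNA(b))
      msg <- c(msg, sprintf("'%s' must be two non-missing integers", ax))
    else if (b[1] < 1L || b[1] > b[2])
      msg <- c(msg, sprintf("'%s' must satisfy 1 <= lo <= hi (got %d, %d)",
                            ax, b[1], b[2]))
  }
  if (length(msg)) msg else TRUE
})

#' @param rows,cols length-2 vectors \code{c(lo, hi)}, 1-based inclusive.
#' @return a validated \linkS4class{CropWindow}.
#' @rdname CropWindow-class
#' @examples
#' cropWindow(c(3, 5), c(4, 7))   # a 3 x 4 window
#' @export
cropWindow <- function(rows, cols) {
  new("CropWindow", rows = as.integer(rows), cols = as.integer(cols))
}

setMethod("show", "CropWindow", function(object) {
  cat(sprintf("CropWindow rows [%d, %d] x cols [%d, %d] (%d cells)\n",
              object@rows[1], object@rows[2], object@cols[1], object@cols[2],
              windowSize(object)))
  invisible(NULL)
})

#' Number of cells in a crop window
#' @param window a \linkS4class{CropWindow}.
#' @return integer cell count.
#' @export
windowSize <- function(window) {
  as.integer(diff(window@rows) + 1L) * as.integer(diff(window@cols) + 1L)
}

## ---------------------------------------------------------------------------
## BackgroundModel: mean/SD of the chemically empty region and the derived
## noise-removal threshold tau = mean + 2 * SD.
## ---------------------------------------------------------------------------

#' BackgroundModel: background noise level of one spectrum
#'
#' Sample mean and standard deviation (n - 1 denominator) of the intensity
#' in a chemically empty region, and the noise threshold defined as two
#' standard deviations above the mean background value.
#'
#' @slot mean background mean.
#' @slot sd background sample standard deviation (>= 0).
#' @slot threshold exactly \code{mean + 2 * sd}.
#' @slot region human-readable description of the cells used.
#' @aliases BackgroundModel-class
#' @exportClass BackgroundModel
setClass("BackgroundModel",
  slots = c(mean = "numeric", sd = "numeric", threshold = "numeric",
            region = "character"))

setValidity("BackgroundModel", function(object) {
  msg <- character(0)
  if (object@sd < 0) msg <- c(msg, "'sd' must be >= 0")
  if (!identical(object@threshold, object@mean + 2 * object@sd))
    msg <- c(msg, "'threshold' must equal mean + 2 * sd exactly")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackgroundModel", function(object) {
  cat(sprintf(
    "BackgroundModel: mean %.6g, sd %.6g -> threshold %.6g\n  region: %s\n",
    object@mean, object@sd, object@threshold, object@region))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## FeatureMatrix: stacked per-sample feature vectors plus the inverse map
## from flat feature index back to (retention, drift) cells.
## ---------------------------------------------------------------------------

#' FeatureMatrix: per-sample feature vectors with spatial locations
#'
#' The flattened (row-major over the crop window) per-sample feature
#' vectors fed to classification, together with the bijective map from
#' feature index back to original spectrum coordinates, so that selected
#' features can be replotted onto a raw spectrum.
#'
#' @slot values numeric matrix, samples x features.
#' @slot sampleIds character, one per row.
#' @slot locations data.frame with columns \code{feature},
#'   \code{retention}, \code{drift} (original-spectrum 1-based indices),
#'   one row per feature column.
#' @slot window the \linkS4class{CropWindow} the features came from.
#' @slot binSize integer bin edge used for mean-pooling (1 = raw cells).
#' @slot labels optional character group codes, one per sample (may be
#'   empty).
#' @slot backgrounds data.frame of per-sample background mean/sd/threshold.
#' @aliases FeatureMatrix-class
#' @exportClass FeatureMatrix
setClass("FeatureMatrix",
  slots = c(values = "matrix", sampleIds = "character",
            locations = "data.frame", window = "CropWindow",
            binSize = "integer", labels = "character",
            backgrounds = "data.frame"))

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  if (ncol(object@values) != nrow(object@locations))
    msg <- c(msg, "column count of 'values' must equal rows of 'locations'")
  if (nrow(object@values) != length(object@sampleIds))
    msg <- c(msg, "row count of 'values' must equal length of 'sampleIds'")
  if (length(object@labels) &&
      length(object@labels) != length(object@sampleIds))
    msg <- c(msg, "'labels', when set, must have one entry per sample")
  if (!all(c("feature", "retention", "drift") %in% names(object@locations)))
    msg <- c(msg, "'locations' needs columns feature, retention, drift")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d samples x %d features (bin size %d)\n",
              nrow(object@values), ncol(object@values), object@binSize))
  if (length(object@labels))
    print(table(labels = object@labels))
  invisible(NULL)
})

## ---------------------------------------------------------------------------
## PredictionSet: held-out class-1 probabilities plus per-fold selections.
## ---------------------------------------------------------------------------

#' PredictionSet: held-out probabilities from cross-validation or hold-out
#'
#' Output of \code{\link{runCV}} / \code{\link{runHoldout}}: one held-out
#' class-1 probability per sample per classifier, the fold assignment, and
#' the per-fold selected features with their rank-sum p-values.
#'
#' @slot predictions data.frame with columns \code{sample_id},
#'   \code{true_label}, \code{y} (0/1), one \code{prob_svm} /
#'   \code{prob_rf} column per fitted classifier, and \code{fold}.
#' @slot folds list of per-fold records (fold index, test ids, selected
#'   feature table).
#' @slot config the \code{\link{modelConfig}} list used.
#' @slot mode "CV" or "HOLDOUT".
#' @slot positiveClass label mapped to class 1.
#' @aliases PredictionSet-class
#' @exportClass PredictionSet
setClass("PredictionSet",
  slots = c(predictions = "data.frame", folds = "list", config = "list",
            mode = "character", positiveClass = "character"))

setValidity("PredictionSet", function(object) {
  msg <- character(0)
  pr <- object@predictions
  need <- c("sample_id", "true_label", "y", "fold")
  if (!all(need %in% names(pr)))
    msg <- c(msg, paste("'predictions' needs columns",
                        paste(need, collapse = ", ")))
  pc <- grep("^prob_", names(pr), value = TRUE)
  for (cc in pc)
    if (any(pr[[cc]] < 0 | pr[[cc]] > 1, na.rm = TRUE))
      msg <- c(msg, sprintf("probabilities in '%s' must lie in [0, 1]", cc))
  if (!object@mode %in% c("CV", "HOLDOUT"))
    msg <- c(msg, "'mode' must be \"CV\" or \"HOLDOUT\"")
  if (length(msg)) msg else TRUE
})

setMethod("show", "PredictionSet", function(object) {
  pr <- object@predictions
  cat(sprintf("PredictionSet (%s): %d held-out samples, classifiers: %s\n",
              object@mode, nrow(pr),
              paste(sub("^prob_", "", grep("^prob_", names(pr),
                                           value = TRUE)),
                    collapse = ", ")))
  cat(sprintf("  positive class: %s\n", object@positiveClass))
  invisible(NULL)
})
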