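#' Accessors for vocims S4 containers
#'
#' Accessor generics for \linkS4class{GCIMSSpectrum},
#' \linkS4class{FeatureMatrix} and \linkS4class{PredictionSet}; slot access
#' by users is discouraged.
#'
#' @param object an object of the relevant class.
#' @return the requested component.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intensities", function(object) standardGeneric("intensities"))
#' @rdname accessors
#' @export
setMethod("intensities", "GCIMSSpectrum", function(object) object@intensities)

#' @rdname accessors
#' @export
setGeneric("retentionAxis", function(object) standardGeneric("retentionAxis"))
#' @rdname accessors
#' @export
setMethod("retentionAxis", "GCIMSSpectrum",
          function(object) object@retentionAxis)

#' @rdname accessors
#' @export
setGeneric("driftAxis", function(object) standardGeneric("driftAxis"))
#' @rdname accessors
#' @export
setMethod("driftAxis", "GCIMSSpectrum", function(object) object@driftAxis)

#' @rdname accessors
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname accessors
#' @export
setMethod("sampleId", "GCIMSSpectrum", function(object) object@sampleId)

#' @rdname accessors
#' @export
setGeneric("spectrumMeta", function(object) standardGeneric("spectrumMeta"))
#' @rdname accessors
#' @export
setMethod("spectrumMeta", "GCIMSSpectrum", function(object) object@meta)

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))
#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setGeneric("featureLocations",
           function(object) standardGeneric("featureLocations"))
#' @rdname accessors
#' @export
setMethod("featureLocations", "FeatureMatrix",
          function(object) object@locations)

#' @rdname accessors
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setMethod("sampleIds", "FeatureMatrix", function(object) object@sampleIds)
#' @rdname accessors
#' @export
setMethod("sampleIds", "PredictionSet",
          function(object) object@predictions$sample_id)

#' @rdname accessors
#' @export
setGeneric("featureLabels", function(object) standardGeneric("featureLabels"))
#' @rdname accessors
#' @export
setMethod("featureLabels", "FeatureMatrix", function(object) object@labels)

#' @rdname accessors
#' @export
setGeneric("predictions", function(object) standardGeneric("predictions"))
#' @rdname accessors
#' @export
setMethod("predictions", "PredictionSet",
          function(object) object@predictions)

#' @rdname accessors
#' @export
setGeneric("foldDetails", function(object) standardGeneric("foldDetails"))
#' @rdname accessors
#' @export
setMethod("foldDetails", "PredictionSet", function(object) object@folds)

#' Predict class-1 probabilities from a fitted classifier
#'
#' S3 generic implemented by the internal SVM and random-forest model
#' objects returned by \code{\link{fitClassifier}}.
#'
#' @param model a fitted model from \code{\link{fitClassifier}}.
#' @param x numeric matrix of samples x features on the training feature
#'   scale (raw values; the SVM applies its stored standardization).
#' @return numeric vector of probabilities in \code{[0, 1]}.
#' @export
predictProbability <- function(model, x) UseMethod("predictProbability")
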