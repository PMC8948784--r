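## Leakage-safe supervised comparison of two transition groups. Everything
## that looks at labels -- feature ranking, top-k selection, classifier
## fitting -- happens inside the training part of each fold; the held-out
## samples only ever receive predictions. Fold assignment is stratified,
## seeded, and keyed by sample id (rows are canonically ordered first), so
## results are invariant to input row order.

#' Modelling configuration
#'
#' @param nFeatures number of features selected per fold (default 100).
#' @param nFolds cross-validation folds (default 10).
#' @param mode \code{"CV"} (default) or \code{"HOLDOUT"} (single stratified
#'   70/30 split, the variant reported alongside the cross-validation).
#' @param holdoutTrainFraction training fraction for hold-out mode.
#' @param classifiers character subset of \code{c("SVM", "RF")}.
#' @param seed integer seed controlling fold assignment and classifier
#'   randomness.
#' @param groupFoldsByPatient keep all samples of one patient in the same
#'   fold when patient ids are supplied (avoids twin-sample leakage).
#' @param selectionScope \code{"fold"} (leakage-safe, default) ranks
#'   features on training rows only; \code{"all"} ranks once on the full
#'   data set. The latter deliberately leaks test information into
#'   selection and exists solely as a sentinel to demonstrate, in the test
#'   suite, that the guard matters. Never use it for reported results.
#' @param svm,rf named lists of classifier hyperparameters (see
#'   \code{\link{fitClassifier}}).
#' @return a list of class \code{ModelConfig}.
#' @export
modelConfig <- function(nFeatures = 100L, nFolds = 10L,
                        mode = c("CV", "HOLDOUT"),
                        holdoutTrainFraction = 0.70,
                        classifiers = c("SVM", "RF"), seed = 1L,
                        groupFoldsByPatient = TRUE,
                        selectionScope = c("fold", "all"),
                        svm = list(), rf = list()) {
  mode <- match.arg(mode)
  selectionScope <- match.arg(selectionScope)
  classifiers <- match.arg(classifiers, c("SVM", "RF"), several.ok = TRUE)
  if (holdoutTrainFraction <= 0 || holdoutTrainFraction >= 1)
    stop("validation error: holdoutTrainFraction must be in (0, 1)")
  structure(list(nFeatures = as.integer(nFeatures),
                 nFolds = as.integer(nFolds), mode = mode,
                 holdoutTrainFraction = holdoutTrainFraction,
                 classifiers = classifiers, seed = as.integer(seed),
                 groupFoldsByPatient = isTRUE(groupFoldsByPatient),
                 selectionScope = selectionScope, svm = svm, rf = rf),
            class = "ModelConfig")
}

## Stratified fold assignment at the unit level (units = patients when
## grouping is on, samples otherwise). Uses the current RNG stream.
.assignUnitFolds <- function(units, y, k) {
  uy <- tapply(y, units, function(v) round(mean(v)))
  ids <- names(uy)
  fold_of_unit <- integer(length(ids))
  names(fold_of_unit) <- ids
  for (cls in unique(uy)) {
    idx <- which(uy == cls)
    idx <- idx[sample.int(length(idx))]
    fold_of_unit[idx] <- rep_len(seq_len(k), length(idx))
  }
  unname(fold_of_unit[as.character(units)])
}

.extractFeatures <- function(features, labels) {
  if (is(features, "FeatureMatrix")) {
    x <- features@values
    ids <- features@sampleIds
    if (is.null(labels)) labels <- features@labels
    loc <- features@locations
  } else {
    x <- as.matrix(features)
    ids <- rownames(x) %||% sprintf("S%03d", seq_len(nrow(x)))
    loc <- data.frame(feature = seq_len(ncol(x)),
                      retention = NA_integer_, drift = NA_integer_)
  }
  if (is.null(labels) || !length(labels))
    stop("validation error: labels are required")
  list(x = x, ids = ids, labels = labels, loc = loc)
}

.fitFold <- function(x, y, train, test, config, loc) {
  if (length(unique(y[train])) < 2L)
    stop("single-class training data in a fold; use fewer folds")
  rankRows <- if (config$selectionScope == "all") seq_len(nrow(x))
              else train
  ranked <- rankFeaturesWilcoxon(x[rankRows, , drop = FALSE], y[rankRows])
  sel <- selectTopK(ranked, config$nFeatures)
  sel$retention <- loc$retention[sel$feature]
  sel$drift <- loc$drift[sel$feature]
  probs <- list()
  for (cl in config$classifiers) {
    fit <- fitClassifier(cl, x[train, sel$feature, drop = FALSE], y[train],
                         params = if (cl == "SVM") config$svm
                                  else config$rf)
    probs[[tolower(cl)]] <-
      predictProbability(fit, x[test, sel$feature, drop = FALSE])
  }
  list(selected = sel, probs = probs)
}

#' Cross-validated comparison of two groups
#'
#' Stratified seeded k-fold cross-validation: within each fold, features
#' are ranked by Wilcoxon rank-sum p-value on the training samples only,
#' the top \code{nFeatures} are selected, each classifier is fitted on the
#' training rows of the selected columns, and class-1 probabilities are
#' emitted for the fold's held-out samples. The fold test sets partition
#' the cohort, so every sample receives exactly one out-of-fold
#' probability per classifier.
#'
#' @param features a \linkS4class{FeatureMatrix} or numeric matrix
#'   (samples x features; rownames used as sample ids).
#' @param labels two-level vector (group codes); defaults to the
#'   \code{FeatureMatrix} labels. The positive class is the second factor
#'   level.
#' @param config a \code{\link{modelConfig}}.
#' @param patients optional per-sample patient ids; with
#'   \code{groupFoldsByPatient} (default) all samples of a patient share a
#'   fold.
#' @return a \linkS4class{PredictionSet}.
#' @examples
#' set.seed(7)
#' x <- rbind(matrix(rnorm(200, 0), 10), matrix(rnorm(200, 2), 10))
#' ps <- runCV(x, rep(c("B1", "B2"), each = 10),
#'             modelConfig(nFeatures = 5, nFolds = 5, classifiers = "SVM"))
#' head(predictions(ps))
#' @export
runCV <- function(features, labels = NULL, config = modelConfig(),
                  patients = NULL) {
  fx <- .extractFeatures(features, labels)
  ord <- order(fx$ids)
  x <- fx$x[ord, , drop = FALSE]
  ids <- fx$ids[ord]
  lab <- fx$labels[ord]
  patients <- if (!is.null(patients)) patients[ord] else NULL
  cl <- .coerceLabels(lab)
  y <- cl$y
  k <- config$nFolds
  if (k > length(y))
    stop("validation error: nFolds exceeds the number of samples")
  set.seed(config$seed)
  units <- if (config$groupFoldsByPatient && !is.null(patients)) patients
           else ids
  fold <- .assignUnitFolds(units, y, k)
  pr <- data.frame(sample_id = ids, true_label = as.character(lab),
                   y = y, fold = fold, stringsAsFactors = FALSE)
  for (cc in config$classifiers) pr[[paste0("prob_", tolower(cc))]] <-
    NA_real_
  folds <- vector("list", k)
  for (fi in seq_len(k)) {
    test <- which(fold == fi)
    if (!length(test)) next
    train <- which(fold != fi)
    res <- .fitFold(x, y, train, test, config, fx$loc)
    for (cc in names(res$probs))
      pr[test, paste0("prob_", cc)] <- res$probs[[cc]]
    folds[[fi]] <- list(fold = fi, test_ids = ids[test],
                        selected = res$selected)
  }
  pr <- pr[, c("sample_id", "true_label", "y",
               paste0("prob_", tolower(config$classifiers)), "fold")]
  new("PredictionSet", predictions = pr, folds = folds,
      config = unclass(config), mode = "CV", positiveClass = cl$positive)
}

#' Single stratified hold-out comparison
#'
#' One seeded stratified train/test split (70/30 by default); feature
#' ranking, selection and classifier fitting use the training partition
#' only, and probabilities are emitted for the test samples only.
#'
#' @inheritParams runCV
#' @return a \linkS4class{PredictionSet} covering the test partition.
#' @export
runHoldout <- function(features, labels = NULL, config = modelConfig(),
                       patients = NULL) {
  fx <- .extractFeatures(features, labels)
  ord <- order(fx$ids)
  x <- fx$x[ord, , drop = FALSE]
  ids <- fx$ids[ord]
  lab <- fx$labels[ord]
  patients <- if (!is.null(patients)) patients[ord] else NULL
  cl <- .coerceLabels(lab)
  y <- cl$y
  set.seed(config$seed)
  units <- if (config$groupFoldsByPatient && !is.null(patients)) patients
           else ids
  uy <- tapply(y, units, function(v) round(mean(v)))
  trainUnits <- character(0)
  for (cls in unique(uy)) {
    u <- names(uy)[uy == cls]
    u <- u[sample.int(length(u))]
    trainUnits <- c(trainUnits,
                    u[seq_len(round(config$holdoutTrainFraction *
                                      length(u)))])
  }
  train <- which(as.character(units) %in% trainUnits)
  test <- setdiff(seq_along(y), train)
  if (length(unique(y[train])) < 2L || length(unique(y[test])) < 2L)
    stop("class absent after the stratified split; adjust fractions")
  res <- .fitFold(x, y, train, test, config, fx$loc)
  pr <- data.frame(sample_id = ids[test], true_label = as.character(lab)[test],
                   y = y[test], stringsAsFactors = FALSE)
  for (cc in names(res$probs)) pr[[paste0("prob_", cc)]] <- res$probs[[cc]]
  pr$fold <- NA_integer_
  new("PredictionSet", predictions = pr,
      folds = list(list(fold = NA_integer_, test_ids = ids[test],
                        selected = res$selected)),
      config = unclass(config), mode = "HOLDOUT",
      positiveClass = cl$positive)
}

#' Feature selection frequency across folds
#'
#' Counts, over all folds of a \linkS4class{PredictionSet} (or a list of
#' them, e.g. across repeated seeds), how often each feature was among the
#' selected top k; the modal consensus set used by the recovery analyses.
#'
#' @param x a \linkS4class{PredictionSet} or list of them.
#' @return data.frame \code{feature}, \code{retention}, \code{drift},
#'   \code{count}, sorted by decreasing count then ascending feature index.
#' @export
selectionFrequency <- function(x) {
  if (is(x, "PredictionSet")) x <- list(x)
  sel <- do.call(rbind, unlist(lapply(x, function(ps)
    lapply(ps@folds, function(f) f$selected[, c("feature", "retention",
                                                "drift")])),
    recursive = FALSE))
  cnt <- table(sel$feature)
  out <- merge(data.frame(feature = as.integer(names(cnt)),
                          count = as.integer(cnt)),
               sel[!duplicated(sel$feature), ], by = "feature")
  out <- out[order(-out$count, out$feature),
             c("feature", "retention", "drift", "count")]
  rownames(out) <- NULL
  out
}
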