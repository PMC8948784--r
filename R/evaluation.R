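## ROC-based evaluation of held-out probabilities: AUC by the Mann-Whitney
## identity, DeLong 95% confidence intervals, Youden-optimal cut-off with
## sensitivity/specificity/PPV/NPV from the implied integer confusion
## matrix, and a two-sided rank-sum p-value comparing the probability
## distributions of the two classes.

#' Area under the ROC curve
#'
#' Mann-Whitney identity: the fraction of (case, control) pairs whose
#' probabilities are correctly ordered, ties counted one half.
#'
#' @param prob numeric scores/probabilities.
#' @param y labels; coerced to 0/1 via the two-level convention of the
#'   package (second factor level = case).
#' @return AUC in \code{[0, 1]}.
#' @export
computeAUC <- function(prob, y) {
  y <- .coerceLabels(y)$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("validation error: both classes must be present")
  r <- rank(prob)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' DeLong confidence interval for the AUC
#'
#' Variance of the AUC from the case and control placement values (DeLong
#' et al. 1988), turned into an interval on the logit scale by the delta
#' method and transformed back (the logit form keeps close-to-nominal
#' coverage at the small, imbalanced group sizes this pipeline sees, where
#' the plain Wald interval undercovers near AUC = 1). With degenerate
#' variance (all probabilities equal, or perfect separation) the interval
#' collapses to the point estimate with a warning.
#'
#' @inheritParams computeAUC
#' @param level confidence level (default 0.95).
#' @return named numeric \code{c(ci_low, ci_high)}.
#' @export
aucCI <- function(prob, y, level = 0.95) {
  y <- .coerceLabels(y)$y
  cases <- prob[y == 1L]; controls <- prob[y == 0L]
  n1 <- length(cases); n0 <- length(controls)
  if (n1 < 2L || n0 < 2L)
    stop("validation error: need >= 2 samples per class for a CI")
  psi <- outer(cases, controls,
               function(a, b) (a > b) + 0.5 * (a == b))
  auc <- mean(psi)
  v10 <- rowMeans(psi)  # placement of each case among controls
  v01 <- colMeans(psi)  # placement of each control among cases
  se <- sqrt(var(v10) / n1 + var(v01) / n0)
  if (!is.finite(se) || se == 0 || auc <= 0 || auc >= 1) {
    warning("degenerate AUC variance; interval collapses to the estimate")
    return(c(ci_low = auc, ci_high = auc))
  }
  z <- qnorm(1 - (1 - level) / 2)
  seLogit <- se / (auc * (1 - auc))
  ci <- stats::plogis(stats::qlogis(auc) + c(-1, 1) * z * seLogit)
  c(ci_low = ci[1], ci_high = ci[2])
}

#' Youden-optimal cut-off and confusion-matrix metrics
#'
#' Sweeps every observed probability value as a candidate cut-off
#' (predicted positive = probability >= cut-off) and returns the one
#' maximizing Youden's J = sensitivity + specificity - 1; ties are broken
#' by higher sensitivity, then by lower cut-off. PPV/NPV come from the
#' same confusion matrix and are \code{NaN} when undefined (no predicted
#' positives/negatives).
#'
#' @inheritParams computeAUC
#' @return list \code{cutoff}, \code{sensitivity}, \code{specificity},
#'   \code{ppv}, \code{npv}, \code{youden}.
#' @export
optimalCutoff <- function(prob, y) {
  y <- .coerceLabels(y)$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("validation error: both classes must be present")
  cuts <- sort(unique(prob))
  best <- NULL
  for (cut in cuts) {
    pos <- prob >= cut
    tp <- sum(pos & y == 1L); fp <- sum(pos & y == 0L)
    tn <- n0 - fp; fn <- n1 - tp
    sens <- tp / n1; spec <- tn / n0
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12 ||
        (abs(J - best$youden) <= 1e-12 &&
         (sens > best$sensitivity + 1e-12 ||
          (abs(sens - best$sensitivity) <= 1e-12 && cut < best$cutoff)))) {
      best <- list(cutoff = cut, sensitivity = sens, specificity = spec,
                   ppv = tp / (tp + fp), npv = tn / (tn + fn), youden = J)
    }
  }
  best
}

#' Two-sided rank-sum p-value between class probability distributions
#'
#' Default method: two-sided Mann-Whitney U test on the held-out
#' probabilities of cases versus controls, sharing the exact/approximate
#' policy of \code{\link{wilcoxonTests}} (the U statistic relates to the
#' AUC by U = AUC * n1 * n0). The permutation alternative recomputes the
#' AUC under label permutations.
#'
#' @inheritParams computeAUC
#' @param method \code{"wilcoxon"} (default) or \code{"permutation"}.
#' @param nPermutations permutation count for the permutation method.
#' @return p-value in \code{(0, 1]}.
#' @export
comparisonPvalue <- function(prob, y, method = c("wilcoxon", "permutation"),
                             nPermutations = 2000L) {
  method <- match.arg(method)
  yy <- .coerceLabels(y)$y
  if (length(unique(yy)) < 2L)
    stop("validation error: both classes must be present")
  if (method == "wilcoxon")
    return(wilcoxonTests(matrix(prob, ncol = 1), yy, enumMax = 12L)$p)
  obs <- abs(computeAUC(prob, yy) - 0.5)
  hits <- 0L
  for (i in seq_len(nPermutations)) {
    pa <- abs(computeAUC(prob, sample(yy)) - 0.5)
    if (pa >= obs - 1e-12) hits <- hits + 1L
  }
  (1 + hits) / (1 + nPermutations)
}

#' ROC curve points
#'
#' @inheritParams computeAUC
#' @return data.frame \code{threshold}, \code{fpr}, \code{tpr}, from
#'   (0, 0) to (1, 1).
#' @export
rocCurve <- function(prob, y) {
  y <- .coerceLabels(y)$y
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  cuts <- c(Inf, sort(unique(prob), decreasing = TRUE))
  data.frame(threshold = cuts,
             fpr = vapply(cuts, function(ct) sum(prob >= ct & y == 0L) / n0,
                          numeric(1)),
             tpr = vapply(cuts, function(ct) sum(prob >= ct & y == 1L) / n1,
                          numeric(1)))
}

.REPORT_COLS <- c("comparison", "classifier", "mode", "auc", "ci_low",
                  "ci_high", "cutoff", "sensitivity", "specificity", "ppv",
                  "npv", "p_value", "n_cases", "n_controls")

#' Evaluate one probability vector into a report row
#'
#' @inheritParams computeAUC
#' @param classifier,comparison,mode annotation strings for the row.
#' @return one-row data.frame in the report schema.
#' @export
evaluateROC <- function(prob, y, classifier = "", comparison = "",
                        mode = "") {
  yy <- .coerceLabels(y)$y
  ci <- suppressWarnings(aucCI(prob, yy))
  oc <- optimalCutoff(prob, yy)
  data.frame(comparison = comparison, classifier = classifier, mode = mode,
             auc = computeAUC(prob, yy), ci_low = unname(ci[1]),
             ci_high = unname(ci[2]), cutoff = oc$cutoff,
             sensitivity = oc$sensitivity, specificity = oc$specificity,
             ppv = oc$ppv, npv = oc$npv,
             p_value = comparisonPvalue(prob, yy),
             n_cases = sum(yy == 1L), n_controls = sum(yy == 0L),
             stringsAsFactors = FALSE)
}

#' Build the per-comparison evaluation report
#'
#' Turns held-out probabilities into the reporting schema: one row per
#' (comparison, classifier, mode) with AUC and its 95% CI, the
#' Youden-optimal cut-off with sensitivity, specificity, PPV and NPV, the
#' rank-sum p-value and the class sizes. ROC curve points for each row are
#' attached as the \code{"roc"} attribute.
#'
#' @param x a \linkS4class{PredictionSet}, a list of them, or a
#'   plain predictions data.frame as written by
#'   \code{\link{writePredictions}} (columns \code{sample_id},
#'   \code{true_label}, \code{y}, \code{prob_*}, \code{fold}).
#' @param comparison label for the comparison, e.g. \code{"B1 vs B2"};
#'   when \code{NULL} it is derived from the observed labels.
#' @param mode annotation when \code{x} is a plain data.frame.
#' @return data.frame in the report schema (zero rows for empty input).
#' @export
buildReport <- function(x, comparison = NULL, mode = "CV") {
  if (is(x, "PredictionSet")) {
    return(buildReport(x@predictions, comparison = comparison,
                       mode = x@mode))
  }
  if (is.list(x) && !is.data.frame(x)) {
    out <- lapply(x, buildReport, comparison = comparison, mode = mode)
    res <- do.call(rbind, lapply(out, function(d) d))
    attr(res, "roc") <- do.call(c, lapply(out, attr, "roc"))
    return(res)
  }
  if (is.null(x) || nrow(x) == 0L) {
    res <- as.data.frame(stats::setNames(
      rep(list(character(0)), length(.REPORT_COLS)), .REPORT_COLS))
    attr(res, "roc") <- list()
    return(res)
  }
  if (is.null(comparison)) {
    lv <- sort(unique(x$true_label))
    comparison <- paste(lv, collapse = " vs ")
  }
  pcols <- grep("^prob_", names(x), value = TRUE)
  rows <- list(); rocs <- list()
  for (cc in pcols) {
    cl <- toupper(sub("^prob_", "", cc))
    rows[[cc]] <- evaluateROC(x[[cc]], x$y, classifier = cl,
                              comparison = comparison, mode = mode)
    rocs[[paste(comparison, cl, mode, sep = " | ")]] <-
      rocCurve(x[[cc]], x$y)
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "roc") <- rocs
  res
}
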