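## Two-sided Wilcoxon rank-sum tests, vectorized over the columns of a
## feature matrix. P-value policy (fixed for reproducibility):
##   - no ties and both groups <= 25: exact via the null rank-sum
##     distribution (pwilcox);
##   - ties with total n <= 10: exact by complete enumeration of all
##     choose(n, n1) group assignments (two-sided around the null mean);
##   - otherwise: normal approximation with tie correction and continuity
##     correction (the wilcox.test large-sample formula).

#' Column-wise Wilcoxon rank-sum tests
#'
#' Two-sided rank-sum test of group 1 versus group 0 for every column of
#' \code{x}, vectorized for use inside cross-validation folds. A constant
#' column carries no discriminatory information and gets p = 1.
#'
#' @param x numeric matrix, samples x features.
#' @param groups 0/1 vector (or logical), one entry per row; both classes
#'   must be present with at least one sample each.
#' @param exactMax largest per-group size for the exact no-ties path.
#' @param enumMax largest total sample size for the exact enumeration path
#'   used when ties are present.
#' @return data.frame \code{feature}, \code{statistic} (Mann-Whitney U of
#'   group 1), \code{p}.
#' @export
wilcoxonTests <- function(x, groups, exactMax = 25L, enumMax = 10L) {
  x <- as.matrix(x)
  g <- as.integer(as.logical(groups))
  if (length(g) != nrow(x))
    stop("validation error: 'groups' must have one entry per row")
  n1 <- sum(g == 1L); n0 <- sum(g == 0L)
  if (n1 < 1L || n0 < 1L)
    stop("validation error: both classes must be present")
  n <- n1 + n0
  rk <- col_ranks_ties(x)
  w1 <- colSums(rk$ranks[g == 1L, , drop = FALSE])
  u <- w1 - n1 * (n1 + 1) / 2
  p <- numeric(ncol(x))

  exact_ok <- !rk$has_ties & n1 <= exactMax & n0 <= exactMax
  if (any(exact_ok)) {
    uu <- u[exact_ok]
    lower <- 2 * pwilcox(uu, n1, n0)
    upper <- 2 * pwilcox(uu - 1, n1, n0, lower.tail = FALSE)
    p[exact_ok] <- pmin(1, ifelse(uu > n1 * n0 / 2, upper, lower))
  }

  enum_ok <- rk$has_ties & n <= enumMax
  if (any(enum_ok)) {
    subsets <- combn(n, n1)
    ew <- n1 * (n + 1) / 2
    for (j in which(enum_ok)) {
      r <- rk$ranks[, j]
      wdist <- colSums(matrix(r[subsets], nrow = n1))
      p[j] <- mean(abs(wdist - ew) >= abs(w1[j] - ew) - 1e-9)
    }
  }

  approx_ok <- !exact_ok & !enum_ok
  if (any(approx_ok)) {
    uu <- u[approx_ok]
    z <- uu - n1 * n0 / 2
    sigma <- sqrt((n1 * n0 / 12) *
                    ((n + 1) - rk$tie_term[approx_ok] / (n * (n - 1))))
    z <- (z - sign(z) * 0.5) / sigma
    pj <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
    pj[!is.finite(z)] <- 1  # constant column: sigma = 0, no information
    p[approx_ok] <- pmin(1, pj)
  }

  data.frame(feature = seq_len(ncol(x)), statistic = u, p = p)
}

#' Rank features by discriminatory information
#'
#' Runs a two-sided Wilcoxon rank-sum test per feature on the supplied
#' (training) samples only and returns the features sorted by ascending
#' p-value, ties broken by ascending feature index. This is the per-fold
#' selection step; calling it on anything but the training rows of a fold
#' leaks test information into the selection (see
#' \code{\link{runCV}}'s \code{selectionScope} sentinel).
#'
#' @param object a \linkS4class{FeatureMatrix} or plain numeric matrix
#'   (samples x features).
#' @param labels 0/1 (or two-level) vector; for a \code{FeatureMatrix}
#'   defaults to its stored labels.
#' @param ... passed to \code{\link{wilcoxonTests}}.
#' @return data.frame \code{feature}, \code{statistic}, \code{p} (plus
#'   \code{retention}, \code{drift} when locations are available), sorted
#'   ascending by p.
#' @export
rankFeaturesWilcoxon <- function(object, labels = NULL, ...) {
  if (is(object, "FeatureMatrix")) {
    x <- object@values
    if (is.null(labels)) labels <- object@labels
    loc <- object@locations
  } else {
    x <- as.matrix(object)
    loc <- NULL
  }
  y <- .coerceLabels(labels)$y
  if (length(unique(y)) < 2L)
    stop("validation error: single-class training set")
  if (min(table(y)) < 2L)
    stop("validation error: need >= 2 samples per class")
  res <- wilcoxonTests(x, y, ...)
  if (!is.null(loc)) {
    res$retention <- loc$retention[res$feature]
    res$drift <- loc$drift[res$feature]
  }
  res[order(res$p, res$feature), , drop = FALSE]
}

#' Select the top k ranked features
#'
#' @param ranked data.frame from \code{\link{rankFeaturesWilcoxon}}
#'   (already sorted).
#' @param k number of features to keep.
#' @return the first \code{k} rows of \code{ranked}.
#' @export
selectTopK <- function(ranked, k) {
  if (k > nrow(ranked))
    stop("validation error: k (", k, ") exceeds available features (",
         nrow(ranked), ")")
  ranked[seq_len(k), , drop = FALSE]
}

## Map an arbitrary two-level label vector onto {0, 1}; the positive class
## (mapped to 1) is the second factor level, i.e. the lexicographically
## later group code ("B2" in "B1 vs B2").
.coerceLabels <- function(labels) {
  if (is.numeric(labels) && all(labels %in% c(0, 1)))
    return(list(y = as.integer(labels), positive = "1",
                original = as.character(labels)))
  f <- factor(labels)
  if (nlevels(f) > 2L)
    stop("validation error: more than two classes")
  list(y = as.integer(f) - 1L, positive = levels(f)[nlevels(f)],
       original = as.character(labels))
}
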