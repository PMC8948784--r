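## Classifier backends. The surrounding pipeline needs exactly two things
## from a classifier: fit on a training matrix and emit class-1
## probabilities for new samples. The environment ships no SVM or random
## forest, so both are implemented here: a radial-basis C-SVC trained by
## SMO with Platt sigmoid calibration, and a CART/gini random forest with
## vote-fraction probabilities (compiled code in src/). Both consume R's
## RNG stream, so results are reproducible under set.seed().

.rbfKernel <- function(a, b, gamma) {
  an <- rowSums(a * a); bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  exp(-gamma * pmax(d2, 0))
}

## Platt (1999) sigmoid fit with the Lin/Weng/et-al. Newton iteration:
## P(y = 1 | f) = 1 / (1 + exp(A f + B)), regularized targets
## t1 = (n1 + 1)/(n1 + 2), t0 = 1/(n0 + 2).
.plattFit <- function(f, y, maxIter = 100L) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  t <- ifelse(y == 1L, (n1 + 1) / (n1 + 2), 1 / (n0 + 2))
  A <- 0; B <- log((n0 + 1) / (n1 + 1))
  obj <- function(A, B) {
    z <- A * f + B
    sum(ifelse(z >= 0, t * z + log1p(exp(-z)), (t - 1) * z + log1p(exp(z))))
  }
  val <- obj(A, B)
  for (it in seq_len(maxIter)) {
    z <- A * f + B
    p <- 1 / (1 + exp(z))
    ## gradient and Hessian of the cross-entropy in (A, B)
    d1 <- t - p
    gA <- sum(f * d1); gB <- sum(d1)
    w <- p * (1 - p)
    hAA <- sum(f * f * w) + 1e-12
    hAB <- sum(f * w)
    hBB <- sum(w) + 1e-12
    det <- hAA * hBB - hAB * hAB
    if (abs(det) < 1e-300) break
    dA <- -(hBB * gA - hAB * gB) / det
    dB <- -(-hAB * gA + hAA * gB) / det
    if (max(abs(gA), abs(gB)) < 1e-8) break
    step <- 1
    repeat {
      newVal <- obj(A + step * dA, B + step * dB)
      if (newVal < val + 1e-12 || step < 1e-8) break
      step <- step / 2
    }
    if (newVal > val + 1e-12) break  # no decrease possible; converged
    A <- A + step * dA; B <- B + step * dB
    val <- newVal
  }
  c(A = A, B = B)
}

.stratifiedFolds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Fit a probability-emitting classifier
#'
#' Internal contract used by \code{\link{runCV}} / \code{\link{runHoldout}}:
#' fit on training samples, then call \code{\link{predictProbability}} on
#' new data.
#'
#' SVM: radial-basis C-SVC (SMO), features standardized with training
#' statistics, \code{gamma = 1/ncol(x)} and \code{cost = 1} by default;
#' probabilities via Platt sigmoid calibration fitted on 3-fold
#' cross-validated decision values (in-sample decision values when a class
#' has fewer than 3 training members). RF: 500 CART trees on bootstrap
#' samples, gini impurity, \code{mtry = floor(sqrt(ncol(x)))}, grown to
#' purity; probability = fraction of trees voting class 1.
#'
#' @param kind \code{"SVM"} or \code{"RF"}.
#' @param x numeric training matrix, samples x features.
#' @param y two-level labels (0/1, logical, factor or character).
#' @param params named list overriding defaults: SVM \code{cost},
#'   \code{gamma}, \code{calibFolds}; RF \code{ntree}, \code{mtry},
#'   \code{minNode}.
#' @return an object of class \code{vocSVM} or \code{vocRF}.
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 3), 10))
#' fit <- fitClassifier("SVM", x, rep(0:1, each = 10))
#' range(predictProbability(fit, x))
#' @export
fitClassifier <- function(kind = c("SVM", "RF"), x, y, params = list()) {
  kind <- match.arg(kind)
  x <- as.matrix(x)
  y <- .coerceLabels(y)$y
  if (length(unique(y)) < 2L)
    stop("validation error: labels are constant; need both classes")
  if (min(table(y)) < 2L)
    stop("validation error: need >= 2 training samples per class")
  if (kind == "SVM") .fitSVM(x, y, params) else .fitRF(x, y, params)
}

.fitSVM <- function(x, y, params) {
  cost <- params$cost %||% 1
  gamma <- params$gamma %||% (1 / ncol(x))
  calibFolds <- params$calibFolds %||% 3L
  center <- colMeans(x)
  scale <- apply(x, 2L, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  xs <- sweep(sweep(x, 2L, center), 2L, scale, "/")
  ys <- ifelse(y == 1L, 1, -1)
  K <- .rbfKernel(xs, xs, gamma)
  fit <- smo_train(K, ys, cost, 1e-3, 10L)
  ## calibration decision values: cross-validated when the minority class
  ## allows it, otherwise in-sample (documented fallback)
  if (min(table(y)) >= calibFolds) {
    fold <- .stratifiedFolds(y, calibFolds)
    dv <- numeric(length(y))
    for (fi in seq_len(calibFolds)) {
      tr <- fold != fi
      sub <- smo_train(K[tr, tr, drop = FALSE], ys[tr], cost, 1e-3, 10L)
      dv[!tr] <- drop(K[!tr, tr, drop = FALSE] %*%
                        (sub$alpha * ys[tr])) + sub$b
    }
  } else {
    dv <- drop(K %*% (fit$alpha * ys)) + fit$b
  }
  platt <- .plattFit(dv, y)
  structure(list(alphaY = fit$alpha * ys, b = fit$b, xtrain = xs,
                 center = center, scale = scale, gamma = gamma,
                 platt = platt),
            class = "vocSVM")
}

.fitRF <- function(x, y, params) {
  ntree <- params$ntree %||% 500L
  mtry <- params$mtry %||% max(1L, floor(sqrt(ncol(x))))
  minNode <- params$minNode %||% 1L
  forest <- rf_grow(x, as.integer(y), as.integer(ntree), as.integer(mtry),
                    as.integer(minNode))
  structure(list(forest = forest, p = ncol(x)), class = "vocRF")
}

#' @export
predictProbability.vocSVM <- function(model, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2L, model$center), 2L, model$scale, "/")
  K <- .rbfKernel(xs, model$xtrain, model$gamma)
  f <- drop(K %*% model$alphaY) + model$b
  p <- 1 / (1 + exp(model$platt["A"] * f + model$platt["B"]))
  unname(pmin(1, pmax(0, p)))
}

#' @export
predictProbability.vocRF <- function(model, x) {
  x <- as.matrix(x)
  stopifnot(ncol(x) == model$p)
  rf_predict(model$forest, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
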