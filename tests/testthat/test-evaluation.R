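test_that("AUC follows the Mann-Whitney identity", {
  expect_equal(computeAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  # 2 of 4 (case, control) pairs concordant
  expect_equal(computeAUC(c(0.9, 0.1, 0.8, 0.2), c(1, 1, 0, 0)), 0.5)
  # label swap mirrors the AUC
  p <- c(0.9, 0.7, 0.65, 0.3, 0.2)
  y <- c(1, 0, 1, 1, 0)
  expect_equal(computeAUC(p, y), 1 - computeAUC(p, 1 - y))
  expect_error(computeAUC(p, rep(1, 5)), "both classes")

  # exhaustive all-pairs oracle on small inputs, ties included
  set.seed(20)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    pr <- sample(seq(0, 1, by = 0.25), n, replace = TRUE)  # forces ties
    expect_equal(computeAUC(pr, y), oracleAUC(pr, y))
  }

  # invariance under strictly monotone transforms (rank-based throughout)
  pr <- runif(20); y <- rep(0:1, 10)
  expect_equal(computeAUC(qlogis(pr / 2 + 0.25), y), computeAUC(pr, y))
})

test_that("DeLong intervals behave like 95% intervals", {
  set.seed(21)
  pr <- c(rnorm(30, 1), rnorm(40, 0))
  y <- rep(c(1, 0), c(30, 40))
  ci <- aucCI(pr, y)
  auc <- computeAUC(pr, y)
  expect_true(ci[1] <= auc && auc <= ci[2])
  expect_true(ci[1] >= 0 && ci[2] <= 1)

  # degenerate variance collapses with a warning
  expect_warning(ci0 <- aucCI(rep(0.5, 10), rep(0:1, 5)), "degenerate")
  expect_equal(unname(ci0), c(0.5, 0.5))
  expect_warning(ci1 <- aucCI(c(1, 1, 1, 0, 0, 0), c(1, 1, 1, 0, 0, 0)),
                 "degenerate")
  expect_equal(unname(ci1), c(1, 1))

  # coverage study at the cohort's imbalanced group sizes (41 vs 8):
  # the true AUC for N(1,1) vs N(0,1) is pnorm(1/sqrt(2))
  trueAUC <- pnorm(1 / sqrt(2))
  set.seed(22)
  cover <- mean(vapply(1:2000, function(i) {
    pr <- c(rnorm(8, 1), rnorm(41, 0))
    y <- rep(c(1, 0), c(8, 41))
    ci <- aucCI(pr, y)
    ci[1] <= trueAUC && trueAUC <= ci[2]
  }, logical(1)))
  # nominal band 93-97%, padded by ~2 Monte-Carlo SD at 2000 replicates
  expect_gte(cover, 0.92)
  expect_lte(cover, 0.98)
})

test_that("the Youden-optimal cut-off matches the exhaustive sweep", {
  oc <- optimalCutoff(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_equal(oc$sensitivity, 1)
  expect_equal(oc$specificity, 1)
  expect_equal(oc$ppv, 1)
  expect_equal(oc$npv, 1)
  expect_true(oc$cutoff > 0.2 && oc$cutoff <= 0.8)

  # perfect specificity forces perfect PPV when anything is predicted
  # positive: zero false positives force PPV = 1
  set.seed(23)
  for (i in 1:30) {
    n <- sample(6:14, 1)
    y <- sample(c(0, 1), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    pr <- sample(seq(0, 1, by = 0.2), n, replace = TRUE)
    oc <- optimalCutoff(pr, y)
    expect_equal(oc$youden, oracleBestJ(pr, y))         # exhaustive max
    if (oc$specificity == 1 && !is.nan(oc$ppv))
      expect_equal(oc$ppv, 1)
    # integer confusion matrix consistency
    expect_equal(oc$sensitivity * sum(y == 1) -
                   round(oc$sensitivity * sum(y == 1)), 0, tolerance = 1e-9)
    expect_equal(oc$specificity * sum(y == 0) -
                   round(oc$specificity * sum(y == 0)), 0, tolerance = 1e-9)
  }
})

test_that("comparison p-values are exact rank-sum probabilities", {
  # fully separated 6 vs 6: exact two-sided p = 2 / C(12,6) = 2/924
  pr <- c(7:12, 1:6) / 12
  y <- rep(c(1, 0), each = 6)
  expect_equal(comparisonPvalue(pr, y), 2 / choose(12, 6),
               tolerance = 1e-12)

  # U = AUC * n1 * n0 cross-check
  set.seed(24)
  pr <- runif(30); y <- rep(0:1, 15)
  u <- wilcoxonTests(matrix(pr, ncol = 1), y)$statistic
  expect_equal(u, computeAUC(pr, y) * 15 * 15)

  # permutation mode agrees in order of magnitude on separated data
  set.seed(25)
  pperm <- comparisonPvalue(c(7:12, 1:6) / 12, rep(c(1, 0), each = 6),
                            method = "permutation", nPermutations = 500)
  expect_lt(pperm, 0.02)

  # type-I error under the null: uniform p-values
  set.seed(26)
  pv <- vapply(1:200, function(i)
    comparisonPvalue(runif(40), rep(0:1, 20)), numeric(1))
  expect_gte(mean(pv < 0.05), 0.02)
  expect_lte(mean(pv < 0.05), 0.09)
})

test_that("reports carry the full metric schema and are pure", {
  # empty input: header only
  emptyRep <- buildReport(NULL)
  expect_equal(nrow(emptyRep), 0)
  expect_true(all(c("comparison", "classifier", "auc", "p_value") %in%
                    names(emptyRep)))

  # two classifiers x four comparisons = eight rows
  set.seed(27)
  mk <- function(cmp) {
    data.frame(sample_id = sprintf("%s%02d", cmp, 1:20),
               true_label = rep(c("x", "y"), 10), y = rep(0:1, 10),
               prob_svm = runif(20), prob_rf = runif(20), fold = 1L)
  }
  reports <- lapply(paste0("C", 1:4), function(cmp)
    buildReport(mk(cmp), comparison = cmp))
  full <- do.call(rbind, reports)
  expect_equal(nrow(full), 8)
  expect_equal(sort(unique(full$classifier)), c("RF", "SVM"))

  # regenerating the report from a written predictions.csv reproduces it
  d <- smallDesign(nPerGroup = c(5, 5), seed = 6)
  out <- runPipeline(d, modelConfig(nFeatures = 20, nFolds = 5, seed = 2))
  path <- file.path(tempdir(), "predictions.csv")
  writePredictions(out$predictionSet, path)
  rt <- read.csv(path, stringsAsFactors = FALSE)
  rep2 <- buildReport(rt, comparison = "G0 vs G1")
  expect_equal(rep2, out$report, tolerance = 1e-12,
               ignore_attr = TRUE)

  # ROC curve attribute spans (0,0) to (1,1)
  roc <- attr(out$report, "roc")[[1]]
  expect_equal(roc$fpr[1], 0); expect_equal(roc$tpr[1], 0)
  expect_equal(roc$fpr[nrow(roc)], 1); expect_equal(roc$tpr[nrow(roc)], 1)
  expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
})
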