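# Independent brute-force oracles used to pin expected values. These stay
# deliberately naive (complete enumeration / all-pairs loops) and never call
# the package code paths they check.

# Exact two-sided rank-sum p by complete enumeration of all group
# assignments (midranks; two-sided around the null mean of the rank sum).
oracleWilcoxP <- function(x1, x2) {
  n1 <- length(x1)
  n <- n1 + length(x2)
  r <- rank(c(x1, x2))
  ew <- n1 * (n + 1) / 2
  wobs <- sum(r[seq_len(n1)])
  subsets <- utils::combn(n, n1)
  wdist <- colSums(matrix(r[subsets], nrow = n1))
  mean(abs(wdist - ew) >= abs(wobs - ew) - 1e-9)
}

# AUC as the literal all-(case, control)-pairs concordance count.
oracleAUC <- function(prob, y) {
  cases <- prob[y == 1]
  controls <- prob[y == 0]
  s <- 0
  for (a in cases) for (b in controls) s <- s + (a > b) + 0.5 * (a == b)
  s / (length(cases) * length(controls))
}

# Best Youden J over every observed threshold (predicted positive at
# prob >= threshold), by exhaustive sweep.
oracleBestJ <- function(prob, y) {
  best <- -Inf
  for (ct in unique(prob)) {
    sens <- mean(prob[y == 1] >= ct)
    spec <- mean(prob[y == 0] < ct)
    best <- max(best, sens + spec - 1)
  }
  best
}

# Small fast cohort design shared across tests.
smallDesign <- function(nPerGroup = c(6, 6), shape = c(60, 50),
                        seed = 1, ...) {
  cohortDesign(nPerGroup = nPerGroup, shape = shape, ripDriftIndex = 12L,
               nSharedPeaks = 10L, nEffectPeaks = 3L, seed = seed, ...)
}

emptyPeaks <- function() peakSpec(1, 1, 1)[0, ]
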