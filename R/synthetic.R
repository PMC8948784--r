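## Synthetic GC-IMS cohort generator. Emulates the features of real runs
## that the pipeline depends on: a high-intensity reactant-ion-peak (RIP)
## ridge at a fixed drift column, Gaussian analyte blobs concentrated at
## early retention times, additive homoscedastic Gaussian noise, and
## group-dependent multiplicative intensity shifts at a planted set of
## "effect" peaks whose footprints serve as ground truth for recovery tests.

#' CohortDesign: parameters of a synthetic GC-IMS cohort
#'
#' @slot nPerGroup integer(2), samples in group 0 and group 1 (each >= 2).
#' @slot shape integer(2), matrix dimensions (retention rows, drift cols).
#' @slot ripDriftIndex drift column of the RIP ridge.
#' @slot ripAmplitude,ripSigma RIP ridge height and drift-direction width.
#' @slot sharedPeaks,effectPeaks data.frames with columns
#'   \code{retention}, \code{drift}, \code{amplitude},
#'   \code{sigma_retention}, \code{sigma_drift}. Effect peaks are scaled by
#'   \code{effectMultiplier} in group 1 only.
#' @slot effectMultiplier multiplicative group-1 amplitude factor (>= 0).
#' @slot noiseSd additive Gaussian noise SD (>= 0).
#' @slot baseline constant background offset.
#' @slot seed integer master seed for \code{\link{simulateCohort}}.
#' @aliases CohortDesign-class
#' @exportClass CohortDesign
setClass("CohortDesign",
  slots = c(nPerGroup = "integer", shape = "integer",
            ripDriftIndex = "integer", ripAmplitude = "numeric",
            ripSigma = "numeric", sharedPeaks = "data.frame",
            effectPeaks = "data.frame", effectMultiplier = "numeric",
            noiseSd = "numeric", baseline = "numeric", seed = "integer"))

.peakCols <- c("retention", "drift", "amplitude", "sigma_retention",
               "sigma_drift")

setValidity("CohortDesign", function(object) {
  msg <- character(0)
  if (length(object@nPerGroup) != 2L || any(object@nPerGroup < 2L))
    msg <- c(msg, "'nPerGroup' must be two integers >= 2")
  if (length(object@shape) != 2L || any(object@shape < 4L))
    msg <- c(msg, "'shape' must be two integers >= 4")
  if (object@ripDriftIndex < 1L || object@ripDriftIndex > object@shape[2])
    msg <- c(msg, "'ripDriftIndex' outside matrix bounds")
  for (nm in c("sharedPeaks", "effectPeaks")) {
    pk <- slot(object, nm)
    if (nrow(pk)) {
      if (!all(.peakCols %in% names(pk)))
        msg <- c(msg, sprintf("'%s' needs columns %s", nm,
                              paste(.peakCols, collapse = ", ")))
      else {
        if (any(pk$retention < 1 | pk$retention > object@shape[1] |
                pk$drift < 1 | pk$drift > object@shape[2]))
          msg <- c(msg, sprintf("'%s' centers outside matrix bounds", nm))
        if (any(pk$sigma_retention <= 0 | pk$sigma_drift <= 0))
          msg <- c(msg, sprintf("'%s' sigmas must be > 0", nm))
        if (any(pk$amplitude <= 0))
          msg <- c(msg, sprintf("'%s' amplitudes must be > 0", nm))
      }
    }
  }
  if (object@effectMultiplier < 0)
    msg <- c(msg, "'effectMultiplier' must be >= 0")
  if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
  if (object@baseline < 0) msg <- c(msg, "'baseline' must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Describe one Gaussian analyte peak
#'
#' @param retention,drift integer center indices (row, column).
#' @param amplitude peak height above baseline (> 0).
#' @param sigmaRetention,sigmaDrift Gaussian widths in cells (> 0).
#' @return one-row data.frame usable in \code{\link{cohortDesign}} peak
#'   lists.
#' @export
peakSpec <- function(retention, drift, amplitude,
                     sigmaRetention = 2.5, sigmaDrift = 2.5) {
  data.frame(retention = as.integer(retention), drift = as.integer(drift),
             amplitude = amplitude, sigma_retention = sigmaRetention,
             sigma_drift = sigmaDrift)
}

## Run code with a private RNG stream, restoring the caller's state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Early-retention-biased random peak layout, kept clear of the RIP ridge,
## of the pre-RIP drift columns and of the last quarter of retention rows
## (so the default background regions stay chemical-free by construction).
.randomPeaks <- function(n, shape, ripDriftIndex, amplitudes) {
  rmax <- max(6L, floor(0.75 * shape[1]))
  rows <- pmin(rmax, pmax(6L, as.integer(round(6 + rbeta(n, 1.2, 3.5) *
                                                 (rmax - 6)))))
  clo <- min(ripDriftIndex + 8L, shape[2] - 2L)
  chi <- max(clo, shape[2] - 8L)
  cols <- as.integer(round(runif(n, clo, chi)))
  data.frame(retention = rows, drift = cols, amplitude = amplitudes,
             sigma_retention = runif(n, 1.8, 3.2),
             sigma_drift = runif(n, 1.8, 3.2))
}

#' Construct a synthetic cohort design
#'
#' Defaults describe the desk-scale stated world used throughout the test
#' suite: 200 x 150 matrices (30,000 cells standing in for the instrument's
#' ~11 million), a RIP ridge at drift column 30, 60 shared analyte peaks
#' biased to early retention times, 5 planted effect peaks whose amplitude
#' is multiplied by 3 in group 1, baseline 50 and noise SD 10 so that the
#' two-standard-deviation background threshold is exercised.
#'
#' Peak layouts are drawn deterministically from \code{seed} unless
#' explicit peak tables are supplied.
#'
#' @param nPerGroup integer(2) group sizes.
#' @param shape integer(2) matrix dimensions.
#' @param ripDriftIndex,ripAmplitude,ripSigma RIP ridge parameters.
#' @param nSharedPeaks,nEffectPeaks peak counts when layouts are drawn.
#' @param effectAmplitude base amplitude of planted effect peaks.
#' @param effectMultiplier group-1 amplitude multiplier (1 = null cohort).
#' @param noiseSd,baseline noise standard deviation and constant offset.
#' @param seed master seed.
#' @param sharedPeaks,effectPeaks optional explicit peak data.frames (see
#'   \code{\link{peakSpec}}).
#' @return a validated \linkS4class{CohortDesign}.
#' @examples
#' d <- cohortDesign(nPerGroup = c(5, 5), shape = c(60, 50),
#'                   ripDriftIndex = 12, nSharedPeaks = 10)
#' d
#' @export
cohortDesign <- function(nPerGroup = c(40L, 40L), shape = c(200L, 150L),
                         ripDriftIndex = 30L, ripAmplitude = 5000,
                         ripSigma = 1.8, nSharedPeaks = 60L,
                         nEffectPeaks = 5L, effectAmplitude = 150,
                         effectMultiplier = 3, noiseSd = 10, baseline = 50,
                         seed = 1L, sharedPeaks = NULL, effectPeaks = NULL) {
  if (is.null(sharedPeaks) || is.null(effectPeaks)) {
    drawn <- .withSeed(as.integer(seed) + 1L, {
      sh <- .randomPeaks(nSharedPeaks, shape, ripDriftIndex,
                         exp(runif(nSharedPeaks, log(150), log(1500))))
      ef <- .randomPeaks(nEffectPeaks, shape, ripDriftIndex,
                         rep(effectAmplitude, nEffectPeaks))
      ## keep effect peaks apart so their 2-sigma footprints are distinct
      for (i in seq_len(nrow(ef))[-1]) {
        tries <- 0L
        while (any(abs(ef$retention[seq_len(i - 1)] - ef$retention[i]) < 12 &
                   abs(ef$drift[seq_len(i - 1)] - ef$drift[i]) < 12) &&
               tries < 100L) {
          repl <- .randomPeaks(1L, shape, ripDriftIndex, effectAmplitude)
          ef$retention[i] <- repl$retention
          ef$drift[i] <- repl$drift
          tries <- tries + 1L
        }
      }
      list(sh = sh, ef = ef)
    })
    if (is.null(sharedPeaks)) sharedPeaks <- drawn$sh
    if (is.null(effectPeaks)) effectPeaks <- drawn$ef
  }
  new("CohortDesign", nPerGroup = as.integer(nPerGroup),
      shape = as.integer(shape), ripDriftIndex = as.integer(ripDriftIndex),
      ripAmplitude = ripAmplitude, ripSigma = ripSigma,
      sharedPeaks = sharedPeaks, effectPeaks = effectPeaks,
      effectMultiplier = effectMultiplier, noiseSd = noiseSd,
      baseline = baseline, seed = as.integer(seed))
}

setMethod("show", "CohortDesign", function(object) {
  cat(sprintf(
    "CohortDesign: %d + %d samples, %d x %d matrix, RIP at drift %d\n",
    object@nPerGroup[1], object@nPerGroup[2], object@shape[1],
    object@shape[2], object@ripDriftIndex))
  cat(sprintf(
    "  %d shared peaks, %d effect peaks (multiplier %.3g), noise SD %.3g\n",
    nrow(object@sharedPeaks), nrow(object@effectPeaks),
    object@effectMultiplier, object@noiseSd))
  invisible(NULL)
})

## Add one Gaussian blob onto a local patch of m (in place semantics by
## returning the patched matrix).
.addPeak <- function(m, r0, c0, amp, sr, sc) {
  ri <- max(1L, floor(r0 - 4 * sr)):min(nrow(m), ceiling(r0 + 4 * sr))
  ci <- max(1L, floor(c0 - 4 * sc)):min(ncol(m), ceiling(c0 + 4 * sc))
  m[ri, ci] <- m[ri, ci] + amp * exp(-0.5 * ((ri - r0) / sr)^2) %o%
    exp(-0.5 * ((ci - c0) / sc)^2)
  m
}

#' Simulate one GC-IMS spectrum
#'
#' Deterministic structure (baseline + full-height RIP ridge + shared
#' Gaussian peaks + group-scaled effect peaks) plus i.i.d. Gaussian noise;
#' the result is truncated at zero so every intensity is non-negative.
#' Consumes the caller's RNG stream; seed via \code{set.seed} or use
#' \code{\link{simulateCohort}}.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param group 0 or 1; group 1 gets effect-peak amplitudes multiplied by
#'   \code{effectMultiplier}.
#' @param sampleId identifier for the resulting spectrum.
#' @return a \linkS4class{GCIMSSpectrum}.
#' @export
simulateSpectrum <- function(design, group, sampleId = "sim") {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  if (!group %in% c(0, 1)) stop("'group' must be 0 or 1")
  nr <- design@shape[1]; nc <- design@shape[2]
  rip <- design@ripAmplitude *
    exp(-0.5 * ((seq_len(nc) - design@ripDriftIndex) / design@ripSigma)^2)
  m <- matrix(design@baseline, nr, nc) + rep(rip, each = nr)
  for (pk in list(design@sharedPeaks, design@effectPeaks)) {
    mult <- if (identical(pk, design@effectPeaks) && group == 1)
      design@effectMultiplier else 1
    if (nrow(pk))
      for (i in seq_len(nrow(pk)))
        m <- .addPeak(m, pk$retention[i], pk$drift[i],
                      mult * pk$amplitude[i], pk$sigma_retention[i],
                      pk$sigma_drift[i])
  }
  if (design@noiseSd > 0)
    m <- m + rnorm(length(m), 0, design@noiseSd)
  m <- pmax(m, 0)
  GCIMSSpectrum(m,
                retentionAxis = seq_len(nr) * 2.4,
                driftAxis = 5 + seq_len(nc) * 0.08,
                sampleId = sampleId,
                meta = list(instrument = "synthetic GC-IMS",
                            retention_unit = "s", drift_unit = "ms",
                            group = group))
}

#' Simulate a two-group GC-IMS cohort with ground truth
#'
#' Generates \code{nPerGroup[1]} group-0 and \code{nPerGroup[2]} group-1
#' spectra from the design's master seed (bit-reproducible), together with
#' the ground-truth effect footprint: every cell within two standard
#' deviations of an effect-peak center, the set recovery tests score
#' selected features against.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @return list with elements \code{spectra} (list of
#'   \linkS4class{GCIMSSpectrum}), \code{labels} (integer 0/1 vector),
#'   \code{sampleIds}, and \code{groundTruth} (data.frame \code{peak},
#'   \code{retention}, \code{drift}).
#' @examples
#' d <- cohortDesign(nPerGroup = c(3, 3), shape = c(40, 30),
#'                   ripDriftIndex = 8, nSharedPeaks = 5, seed = 7)
#' coh <- simulateCohort(d)
#' table(coh$labels)
#' @export
simulateCohort <- function(design) {
  stopifnot(is(design, "CohortDesign"))
  validObject(design)
  labels <- rep(c(0L, 1L), design@nPerGroup)
  ids <- sprintf("G%d_S%03d", labels,
                 c(seq_len(design@nPerGroup[1]),
                   seq_len(design@nPerGroup[2])))
  spectra <- .withSeed(design@seed, {
    lapply(seq_along(labels), function(i)
      simulateSpectrum(design, labels[i], sampleId = ids[i]))
  })
  list(spectra = spectra, labels = labels, sampleIds = ids,
       groundTruth = effectFootprint(design))
}

#' Ground-truth effect footprint of a design
#'
#' @param design a \linkS4class{CohortDesign}.
#' @param nSigma footprint radius in peak standard deviations (default 2).
#' @return data.frame \code{peak}, \code{retention}, \code{drift}: all
#'   cells within \code{nSigma} standard deviations (elliptical) of an
#'   effect-peak center.
#' @export
effectFootprint <- function(design, nSigma = 2) {
  pk <- design@effectPeaks
  out <- lapply(seq_len(nrow(pk)), function(i) {
    sr <- pk$sigma_retention[i]; sc <- pk$sigma_drift[i]
    ri <- max(1L, floor(pk$retention[i] - nSigma * sr)):
      min(design@shape[1], ceiling(pk$retention[i] + nSigma * sr))
    ci <- max(1L, floor(pk$drift[i] - nSigma * sc)):
      min(design@shape[2], ceiling(pk$drift[i] + nSigma * sc))
    g <- expand.grid(retention = ri, drift = ci)
    d2 <- ((g$retention - pk$retention[i]) / sr)^2 +
      ((g$drift - pk$drift[i]) / sc)^2
    cbind(peak = i, g[d2 <= nSigma^2, ])
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

.GROUP_CODES <- c("A1", "A2", "A3", "A4", "B1", "B2", "B3", "B4")

#' Simulate paired clinical metadata for a transition group
#'
#' Generates \code{nPairs} patients with two consecutive sample records
#' whose fecal calprotectin (B codes) or activity score (A codes) values
#' fall inside the defining ranges of the requested transition-group code,
#' so that \code{\link{pairSamples}} labels every pair with that code.
#' Remission FCP is drawn uniformly from [0, 100), active FCP from
#' [250, 1000]; HBI remission from {0..3}, active from {5..16}; SCCAI
#' remission from {0..2}, active from {3..19}. Consumes the caller's RNG
#' stream.
#'
#' @param code transition-group code, one of A1-A4 (clinical) or B1-B4
#'   (biochemical). Digit: 1 = remission to remission, 2 = remission to
#'   active, 3 = active to active, 4 = active to remission.
#' @param nPairs number of patients (one pair each).
#' @param subtype disease subtype for all patients; clinical codes use HBI
#'   for "CD" and SCCAI for "UC"/"IBDU".
#' @param prefix patient-id prefix.
#' @return sample-record data.frame (two rows per patient) in the layout of
#'   \code{\link{readMetadataTable}}.
#' @export
simulateMetadata <- function(code, nPairs, subtype = "CD",
                             prefix = paste0("P", code)) {
  if (!code %in% .GROUP_CODES)
    stop("validation error: unknown transition-group code: ", code)
  if (!subtype %in% .SUBTYPES)
    stop("validation error: unknown subtype: ", subtype)
  digit <- as.integer(substr(code, 2, 2))
  states <- switch(digit, c("R", "R"), c("R", "A"), c("A", "A"),
                   c("A", "R"))
  family <- if (substr(code, 1, 1) == "A") "CLINICAL" else "BIOCHEMICAL"
  n <- 2L * nPairs
  st <- rep(states, nPairs)
  fcp <- rep(NA_real_, n); hbi <- rep(NA_integer_, n)
  sccai <- rep(NA_integer_, n)
  if (family == "BIOCHEMICAL") {
    fcp <- ifelse(st == "R", runif(n, 0, 100 - 1e-9),
                  runif(n, 250, 1000))
  } else if (subtype == "CD") {
    hbi <- ifelse(st == "R", sample(0:3, n, replace = TRUE),
                  sample(5:16, n, replace = TRUE))
  } else {
    sccai <- ifelse(st == "R", sample(0:2, n, replace = TRUE),
                    sample(3:19, n, replace = TRUE))
  }
  pid <- rep(sprintf("%s_%03d", prefix, seq_len(nPairs)), each = 2L)
  seq_index <- rep(1:2, nPairs)
  data.frame(patient_id = pid,
             sample_id = paste0(pid, "_T", seq_index),
             seq_index = seq_index, fcp = fcp, hbi = as.integer(hbi),
             sccai = as.integer(sccai), subtype = subtype,
             stringsAsFactors = FALSE)
}
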