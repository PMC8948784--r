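## Disease-activity state machine and longitudinal pairing. Two label
## families: BIOCHEMICAL (fecal calprotectin, FCP) and CLINICAL (HBI for
## Crohn's disease, SCCAI for ulcerative colitis / IBD-unclassified).
## Values falling in a definitional gap (FCP in [100, 250), HBI = 4) are
## INDETERMINATE and excluded from pairing.

#' Disease-activity thresholds
#'
#' Configuration object holding the activity/remission cut-offs with the
#' study defaults: biochemical active disease FCP >= 250 mg/g, remission
#' FCP < 100 mg/g; clinical active disease HBI >= 5 (CD) or SCCAI >= 3
#' (UC/IBD-U), clinical remission HBI < 4 or SCCAI <= 2. The literature
#' uses endoscopy-correlated FCP cut-offs of 200-250 mg/g, so the bounds
#' are parameters, not constants.
#'
#' @param fcpActive lower inclusive FCP bound for ACTIVE (mg/g).
#' @param fcpRemission exclusive FCP upper bound for REMISSION (mg/g).
#' @param hbiActive lower inclusive HBI bound for ACTIVE.
#' @param hbiRemission exclusive HBI upper bound for REMISSION.
#' @param sccaiActive lower inclusive SCCAI bound for ACTIVE.
#' @param sccaiRemission inclusive SCCAI upper bound for REMISSION.
#' @return a named list of class \code{StateThresholds}.
#' @export
stateThresholds <- function(fcpActive = 250, fcpRemission = 100,
                            hbiActive = 5L, hbiRemission = 4L,
                            sccaiActive = 3L, sccaiRemission = 2L) {
  if (fcpRemission > fcpActive)
    stop("validation error: fcpRemission must be <= fcpActive")
  if (hbiRemission > hbiActive || sccaiRemission > sccaiActive)
    stop("validation error: remission bounds must lie below active bounds")
  structure(list(fcpActive = fcpActive, fcpRemission = fcpRemission,
                 hbiActive = hbiActive, hbiRemission = hbiRemission,
                 sccaiActive = sccaiActive,
                 sccaiRemission = sccaiRemission),
            class = "StateThresholds")
}

.STATES <- c("REMISSION", "INDETERMINATE", "ACTIVE")

#' Biochemical activity state from fecal calprotectin
#'
#' ACTIVE iff FCP >= 250 mg/g, REMISSION iff FCP < 100 mg/g,
#' INDETERMINATE in the definitional gap [100, 250) (at default
#' thresholds). Vectorized.
#'
#' @param fcp non-negative FCP values (mg/g); must be present.
#' @param thresholds a \code{\link{stateThresholds}} object.
#' @return character vector in \code{REMISSION}, \code{INDETERMINATE},
#'   \code{ACTIVE}.
#' @examples
#' classifyBiochemical(c(250, 99.9, 150))
#' @export
classifyBiochemical <- function(fcp, thresholds = stateThresholds()) {
  if (anyNA(fcp))
    stop("labelling error: missing FCP value for the BIOCHEMICAL family")
  if (any(fcp < 0)) stop("validation error: negative FCP")
  ifelse(fcp >= thresholds$fcpActive, "ACTIVE",
         ifelse(fcp < thresholds$fcpRemission, "REMISSION",
                "INDETERMINATE"))
}

#' Clinical activity state from HBI or SCCAI
#'
#' Crohn's disease uses the Harvey Bradshaw Index: ACTIVE iff HBI >= 5,
#' REMISSION iff HBI < 4, HBI = 4 INDETERMINATE (no definition applies).
#' UC/IBD-U use the Simple Clinical Colitis Activity Index: ACTIVE iff
#' SCCAI >= 3, REMISSION iff SCCAI <= 2 (no gap). Vectorized over records.
#'
#' @param subtype character vector in \code{CD}, \code{UC}, \code{IBDU}.
#' @param hbi,sccai integer scores (NA where not applicable).
#' @param thresholds a \code{\link{stateThresholds}} object.
#' @return character state vector.
#' @examples
#' classifyClinical("CD", hbi = 4)     # INDETERMINATE
#' classifyClinical("UC", sccai = 2)   # REMISSION
#' @export
classifyClinical <- function(subtype, hbi = NA_integer_,
                             sccai = NA_integer_,
                             thresholds = stateThresholds()) {
  n <- max(length(subtype), length(hbi), length(sccai))
  subtype <- rep_len(subtype, n); hbi <- rep_len(hbi, n)
  sccai <- rep_len(sccai, n)
  if (any(!subtype %in% .SUBTYPES))
    stop("validation error: unknown subtype")
  isCD <- subtype == "CD"
  if (any(isCD & is.na(hbi)) || any(!isCD & is.na(sccai)))
    stop("labelling error: missing activity score for the CLINICAL family")
  if (any(isCD & !is.na(sccai)) || any(!isCD & !is.na(hbi)))
    stop("labelling error: activity score inconsistent with subtype")
  out <- character(n)
  out[isCD] <- ifelse(hbi[isCD] >= thresholds$hbiActive, "ACTIVE",
                      ifelse(hbi[isCD] < thresholds$hbiRemission,
                             "REMISSION", "INDETERMINATE"))
  out[!isCD] <- ifelse(sccai[!isCD] >= thresholds$sccaiActive, "ACTIVE",
                       ifelse(sccai[!isCD] <= thresholds$sccaiRemission,
                              "REMISSION", "INDETERMINATE"))
  out
}

## State of every record under one family; returns NA-safe "MISSING" for
## records that cannot be labelled instead of raising, so pairing can log
## the exclusion.
.recordStates <- function(records, family, thresholds) {
  vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    res <- tryCatch({
      if (family == "BIOCHEMICAL") classifyBiochemical(r$fcp, thresholds)
      else classifyClinical(r$subtype, r$hbi, r$sccai, thresholds)
    }, error = function(e) "MISSING")
    res
  }, character(1))
}

.GROUP_DIGIT <- c("RR" = 1L, "RA" = 2L, "AA" = 3L, "AR" = 4L)

#' Pair consecutive same-patient samples into transition groups
#'
#' For each patient (records ordered by \code{seq_index}), every pair of
#' adjacently collected samples in which BOTH members have a determinate
#' state under the requested family becomes a transition pair: the first
#' sample carries the VOC information used to predict the state at the
#' second collection. The group code combines the family letter (A =
#' clinical, B = biochemical) with the state transition digit: 1 =
#' remission to remission, 2 = remission to active, 3 = active to active,
#' 4 = active to remission. A middle sample may close one pair and open the
#' next. Excluded pairs are reported in the \code{"dropped"} attribute, not
#' raised.
#'
#' @param records sample-record data.frame (see
#'   \code{\link{readMetadataTable}}).
#' @param family \code{"BIOCHEMICAL"} or \code{"CLINICAL"}.
#' @param thresholds a \code{\link{stateThresholds}} object.
#' @return data.frame with columns \code{patient_id},
#'   \code{first_sample_id}, \code{second_sample_id}, \code{family},
#'   \code{group}, \code{state_first}, \code{state_second}; attribute
#'   \code{dropped} holds the exclusion log.
#' @examples
#' md <- simulateMetadata("B2", nPairs = 3)
#' pairSamples(md, "BIOCHEMICAL")$group
#' @export
pairSamples <- function(records, family = c("BIOCHEMICAL", "CLINICAL"),
                        thresholds = stateThresholds()) {
  family <- match.arg(family)
  records <- validateSampleRecords(records)
  letter <- if (family == "CLINICAL") "A" else "B"
  out <- list(); dropped <- list()
  for (pid in unique(records$patient_id)) {
    rec <- records[records$patient_id == pid, , drop = FALSE]
    rec <- rec[order(rec$seq_index), , drop = FALSE]
    if (nrow(rec) < 2L) next
    st <- .recordStates(rec, family, thresholds)
    for (i in seq_len(nrow(rec) - 1L)) {
      s1 <- st[i]; s2 <- st[i + 1L]
      if (s1 %in% c("REMISSION", "ACTIVE") &&
          s2 %in% c("REMISSION", "ACTIVE")) {
        digit <- .GROUP_DIGIT[paste0(substr(s1, 1, 1), substr(s2, 1, 1))]
        out[[length(out) + 1L]] <- data.frame(
          patient_id = pid, first_sample_id = rec$sample_id[i],
          second_sample_id = rec$sample_id[i + 1L], family = family,
          group = paste0(letter, digit), state_first = s1,
          state_second = s2, stringsAsFactors = FALSE)
      } else {
        why <- if ("MISSING" %in% c(s1, s2)) "missing score"
               else "indeterminate state"
        dropped[[length(dropped) + 1L]] <- data.frame(
          patient_id = pid, first_sample_id = rec$sample_id[i],
          second_sample_id = rec$sample_id[i + 1L], reason = why,
          stringsAsFactors = FALSE)
      }
    }
  }
  empty <- data.frame(patient_id = character(0),
                      first_sample_id = character(0),
                      second_sample_id = character(0),
                      family = character(0), group = character(0),
                      state_first = character(0),
                      state_second = character(0))
  res <- if (length(out)) do.call(rbind, out) else empty
  attr(res, "dropped") <- if (length(dropped)) do.call(rbind, dropped)
    else data.frame(patient_id = character(0),
                    first_sample_id = character(0),
                    second_sample_id = character(0), reason = character(0))
  res
}

#' Count pairs per transition group
#'
#' @param pairs data.frame from \code{\link{pairSamples}}.
#' @return named integer vector over all eight codes A1-A4, B1-B4; codes
#'   absent from the input are reported as 0, not omitted.
#' @export
groupCounts <- function(pairs) {
  counts <- table(factor(pairs$group, levels = .GROUP_CODES))
  stats::setNames(as.integer(counts), .GROUP_CODES)
}
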