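## Open interchange format for GC-IMS spectra: a headerless dense CSV matrix
## (rows = retention index ascending) plus a JSON sidecar of the same
## basename carrying sample_id, both axes and free-form metadata. Vendor
## binary formats are converted upstream; they are not parsed here.

.sidecarPath <- function(path) sub("\\.csv$", ".json", path)

#' Read a GC-IMS spectrum from the interchange format
#'
#' Reads \code{<basename>.csv} (dense intensity matrix, no header) and its
#' required JSON sidecar \code{<basename>.json} (keys \code{sample_id},
#' \code{retention_axis}, \code{drift_axis}, \code{meta}) and returns a
#' validated \linkS4class{GCIMSSpectrum}.
#'
#' @param path path to the matrix \code{.csv} file.
#' @return a \linkS4class{GCIMSSpectrum}.
#' @seealso \code{\link{writeSpectrum}} for the exact inverse.
#' @export
readSpectrum <- function(path) {
  if (!file.exists(path))
    stop("spectrum matrix file not found: ", path)
  sidecar <- .sidecarPath(path)
  if (identical(sidecar, path) || !file.exists(sidecar))
    stop("format error: missing JSON sidecar for ", path)
  meta <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  for (key in c("sample_id", "retention_axis", "drift_axis"))
    if (is.null(meta[[key]]))
      stop("format error: sidecar lacks key '", key, "'")
  m <- as.matrix(data.table::fread(path, header = FALSE, sep = ","))
  dimnames(m) <- NULL
  GCIMSSpectrum(m,
                retentionAxis = as.numeric(meta$retention_axis),
                driftAxis = as.numeric(meta$drift_axis),
                sampleId = meta$sample_id,
                meta = if (is.null(meta$meta)) list() else as.list(meta$meta))
}

#' Write a GC-IMS spectrum in the interchange format
#'
#' Writes the intensity matrix as a headerless CSV and the axis metadata as
#' a JSON sidecar. Numbers are serialized with 17 significant digits so the
#' round trip \code{readSpectrum(writeSpectrum(x, p))} reproduces
#' intensities and axes bit-exactly. Existing files are overwritten.
#'
#' @param spectrum a \linkS4class{GCIMSSpectrum}.
#' @param path destination \code{.csv} path; the sidecar is written next to
#'   it.
#' @return the matrix path, invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
  stopifnot(is(spectrum, "GCIMSSpectrum"))
  validObject(spectrum)
  if (!dir.exists(dirname(path)))
    stop("I/O error: parent directory does not exist: ", dirname(path))
  m <- spectrum@intensities
  txt <- matrix(sprintf("%.17g", m), nrow = nrow(m))
  writeLines(apply(txt, 1L, paste, collapse = ","), path)
  sidecar <- list(
    sample_id = spectrum@sampleId,
    retention_axis = spectrum@retentionAxis,
    drift_axis = spectrum@driftAxis,
    meta = spectrum@meta
  )
  writeLines(jsonlite::toJSON(sidecar, digits = I(17), auto_unbox = TRUE),
             .sidecarPath(path))
  invisible(path)
}

.SUBTYPES <- c("CD", "UC", "IBDU")

#' Read a per-sample clinical metadata table
#'
#' Reads a CSV with header
#' \code{patient_id,sample_id,seq_index,fcp,hbi,sccai,subtype} into a
#' sample-record data.frame. Blank cells become \code{NA}; fecal
#' calprotectin (\code{fcp}, mg/g) and the activity scores are optional at
#' load time and only required when the corresponding label family is
#' requested. Validation enforces known subtypes, unique
#' \code{(patient_id, seq_index)}, score/subtype consistency (HBI is a
#' Crohn's-disease score, SCCAI an ulcerative-colitis score) and
#' non-negative values.
#'
#' @param path CSV path.
#' @return data.frame with one row per sample record.
#' @export
readMetadataTable <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = c(
    patient_id = "character", sample_id = "character",
    seq_index = "integer", fcp = "numeric", hbi = "integer",
    sccai = "integer", subtype = "character"))
  need <- c("patient_id", "sample_id", "seq_index", "fcp", "hbi", "sccai",
            "subtype")
  if (!identical(names(df), need))
    stop("format error: metadata header must be ",
         paste(need, collapse = ","))
  validateSampleRecords(df)
}

#' Validate a sample-record table
#'
#' @param df data.frame in the layout of \code{\link{readMetadataTable}}.
#' @return the validated data.frame (invisibly usable in pipelines).
#' @export
validateSampleRecords <- function(df) {
  if (nrow(df) == 0L) return(df)
  bad <- setdiff(unique(df$subtype), .SUBTYPES)
  if (length(bad))
    stop("validation error: unknown subtype code(s): ",
         paste(bad, collapse = ", "))
  key <- paste(df$patient_id, df$seq_index, sep = "\r")
  if (anyDuplicated(key))
    stop("validation error: duplicate (patient_id, seq_index): ",
         paste(unique(sub("\r", "/", key[duplicated(key)])), collapse = ", "))
  if (any(!is.na(df$hbi) & df$subtype != "CD"))
    stop("validation error: HBI recorded for a non-CD sample")
  if (any(!is.na(df$sccai) & df$subtype == "CD"))
    stop("validation error: SCCAI recorded for a CD sample")
  for (col in c("fcp", "hbi", "sccai"))
    if (any(df[[col]] < 0, na.rm = TRUE))
      stop("validation error: negative ", col)
  df
}
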