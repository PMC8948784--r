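## Crop-and-threshold preprocessing: every sample is cropped with the same
## window, a per-sample noise threshold of two standard deviations above the
## mean background value is applied (sub-threshold cells are zeroed), and
## the window is flattened row-major into a feature vector with a bijective
## map back to (retention, drift) coordinates.

#' Crop a spectrum to a rectangular window
#'
#' Pure slicing: returns the sub-matrix covered by \code{window} without
#' modifying any value.
#'
#' @param spectrum a \linkS4class{GCIMSSpectrum} (or a plain matrix).
#' @param window a \linkS4class{CropWindow} within the spectrum bounds.
#' @return numeric sub-matrix of dimension \code{rows x cols} of the
#'   window.
#' @export
cropSpectrum <- function(spectrum, window) {
  m <- if (is(spectrum, "GCIMSSpectrum")) spectrum@intensities
       else as.matrix(spectrum)
  validObject(window)
  if (window@rows[2] > nrow(m) || window@cols[2] > ncol(m))
    stop("validation error: crop window exceeds spectrum bounds (",
         nrow(m), " x ", ncol(m), ")")
  m[window@rows[1]:window@rows[2], window@cols[1]:window@cols[2],
    drop = FALSE]
}

#' Estimate the background noise model of one spectrum
#'
#' Computes mean and sample standard deviation (n - 1 denominator) of the
#' intensities in a chemically empty region and derives the noise threshold
#' as two standard deviations above the mean background value.
#'
#' @param spectrum a \linkS4class{GCIMSSpectrum} or matrix.
#' @param region a \linkS4class{CropWindow} or a list of them (cells are
#'   pooled); should be disjoint from the analyte crop window.
#' @return a \linkS4class{BackgroundModel}.
#' @examples
#' sp <- GCIMSSpectrum(matrix(c(8, 12, 8, 12), 2, 2))
#' estimateBackground(sp, cropWindow(c(1, 2), c(1, 1)))  # threshold 15.66
#' @export
estimateBackground <- function(spectrum, region) {
  m <- if (is(spectrum, "GCIMSSpectrum")) spectrum@intensities
       else as.matrix(spectrum)
  if (is(region, "CropWindow")) region <- list(region)
  cells <- unlist(lapply(region, function(w) as.vector(cropSpectrum(m, w))))
  if (length(cells) < 2L)
    stop("validation error: background region must contain >= 2 cells")
  mu <- mean(cells)
  s <- sd(cells)
  desc <- paste(vapply(region, function(w)
    sprintf("rows %d:%d x cols %d:%d", w@rows[1], w@rows[2], w@cols[1],
            w@cols[2]), character(1)), collapse = " + ")
  new("BackgroundModel", mean = mu, sd = s, threshold = mu + 2 * s,
      region = desc)
}

#' Zero sub-threshold cells
#'
#' Cells strictly below the threshold are set to 0; cells at or above it
#' are left unchanged.
#'
#' @param m numeric matrix (typically the cropped sub-matrix).
#' @param model a \linkS4class{BackgroundModel} or a single numeric
#'   threshold.
#' @return matrix of the same shape.
#' @export
applyThreshold <- function(m, model) {
  thr <- if (is(model, "BackgroundModel")) model@threshold else model
  stopifnot(is.numeric(thr), length(thr) == 1L, is.finite(thr))
  m[m < thr] <- 0
  m
}

#' Flatten a cropped matrix into a feature vector with locations
#'
#' Row-major flattening of the cropped (and thresholded) sub-matrix; the
#' returned location table is the exact inverse map from flat feature index
#' to original-spectrum (retention, drift) cell indices. Two spectra
#' processed with the same window always share the same location table.
#'
#' @param m the cropped sub-matrix.
#' @param window the \linkS4class{CropWindow} that produced it.
#' @return list with \code{values} (numeric vector, length = cells of the
#'   window) and \code{locations} (data.frame \code{feature},
#'   \code{retention}, \code{drift}).
#' @export
vectorizeSpectrum <- function(m, window) {
  nr <- nrow(m); nc <- ncol(m)
  if (nr != diff(window@rows) + 1L || nc != diff(window@cols) + 1L)
    stop("validation error: matrix shape disagrees with window")
  list(values = as.vector(t(m)),
       locations = data.frame(
         feature = seq_len(nr * nc),
         retention = rep(window@rows[1]:window@rows[2], each = nc),
         drift = rep(window@cols[1]:window@cols[2], times = nr)))
}

#' Reassemble a window matrix from a feature vector
#'
#' Inverse of \code{\link{vectorizeSpectrum}}.
#'
#' @param values numeric feature vector.
#' @param window the \linkS4class{CropWindow}.
#' @return numeric matrix.
#' @export
unvectorizeSpectrum <- function(values, window) {
  nr <- diff(window@rows) + 1L; nc <- diff(window@cols) + 1L
  stopifnot(length(values) == nr * nc)
  matrix(values, nr, nc, byrow = TRUE)
}

## Mean-pool complete b x b blocks; the ragged remainder is dropped.
## Returns the pooled matrix plus the (row, col) center cell of each block
## in the coordinates of the input matrix.
.binMatrix <- function(m, b) {
  nr <- floor(nrow(m) / b); nc <- floor(ncol(m) / b)
  if (nr < 1L || nc < 1L)
    stop("validation error: bin size larger than the cropped matrix")
  mm <- m[seq_len(nr * b), seq_len(nc * b), drop = FALSE]
  pooled <- matrix(0, nr, nc)
  for (i in seq_len(b)) for (j in seq_len(b))
    pooled <- pooled + mm[seq(i, by = b, length.out = nr),
                          seq(j, by = b, length.out = nc), drop = FALSE]
  list(values = pooled / (b * b),
       rowCenter = (seq_len(nr) - 1L) * b + 1L + (b %/% 2L),
       colCenter = (seq_len(nc) - 1L) * b + 1L + (b %/% 2L))
}

#' Default crop window and background regions for a synthetic design
#'
#' The analyte crop keeps early retention rows and the post-RIP drift
#' columns; the background is estimated from the pre-RIP drift columns plus
#' the last 10 percent of retention rows (clear of the RIP ridge), both
#' chemical-free by construction of the generator.
#'
#' @param design a \linkS4class{CohortDesign}.
#' @return \code{defaultCropWindow}: a \linkS4class{CropWindow};
#'   \code{defaultBackgroundRegion}: a list of two windows.
#' @export
defaultCropWindow <- function(design) {
  cropWindow(c(4L, floor(0.8 * design@shape[1])),
             c(design@ripDriftIndex + 6L, design@shape[2] - 4L))
}

#' @rdname defaultCropWindow
#' @export
defaultBackgroundRegion <- function(design) {
  nr <- design@shape[1]; nc <- design@shape[2]
  region <- list(cropWindow(c(ceiling(0.9 * nr) + 1L, nr),
                            c(design@ripDriftIndex + 8L, nc)))
  if (design@ripDriftIndex - 10L >= 2L)  # pre-RIP columns, if any exist
    region <- c(list(cropWindow(c(1L, nr),
                                c(1L, design@ripDriftIndex - 10L))),
                region)
  region
}

#' Build the cohort feature matrix
#'
#' Applies the full preprocessing chain to every spectrum independently:
#' per-sample background estimation over \code{backgroundRegion}, crop to
#' the shared \code{window}, zeroing of sub-threshold cells, optional
#' mean-pooling into \code{binSize x binSize} bins, and row-major
#' flattening. Rows are stacked in input order; a spectrum whose crop is
#' entirely sub-threshold yields an all-zero row (retained, not dropped).
#'
#' @param spectra list of \linkS4class{GCIMSSpectrum} sharing one matrix
#'   shape.
#' @param window shared \linkS4class{CropWindow}.
#' @param backgroundRegion \linkS4class{CropWindow} or list of windows for
#'   per-sample background estimation.
#' @param binSize integer bin edge (default 1 = single-cell features).
#' @param labels optional character group codes, one per spectrum.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
buildFeatureMatrix <- function(spectra, window, backgroundRegion,
                               binSize = 1L, labels = character(0)) {
  stopifnot(length(spectra) >= 1L)
  dims <- vapply(spectra, function(s) dim(s@intensities), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("validation error: spectra have heterogeneous shapes")
  binSize <- as.integer(binSize)
  ids <- vapply(spectra, sampleId, character(1))
  rows <- vector("list", length(spectra))
  bgs <- data.frame(sample_id = ids, mean = NA_real_, sd = NA_real_,
                    threshold = NA_real_)
  locations <- NULL
  for (i in seq_along(spectra)) {
    bg <- estimateBackground(spectra[[i]], backgroundRegion)
    bgs$mean[i] <- bg@mean; bgs$sd[i] <- bg@sd
    bgs$threshold[i] <- bg@threshold
    sub <- applyThreshold(cropSpectrum(spectra[[i]], window), bg)
    if (binSize > 1L) {
      pooled <- .binMatrix(sub, binSize)
      vec <- as.vector(t(pooled$values))
      if (is.null(locations))
        locations <- data.frame(
          feature = seq_along(vec),
          retention = rep(window@rows[1] - 1L + pooled$rowCenter,
                          each = length(pooled$colCenter)),
          drift = rep(window@cols[1] - 1L + pooled$colCenter,
                      times = length(pooled$rowCenter)))
    } else {
      v <- vectorizeSpectrum(sub, window)
      vec <- v$values
      if (is.null(locations)) locations <- v$locations
    }
    rows[[i]] <- vec
  }
  new("FeatureMatrix", values = do.call(rbind, rows), sampleIds = ids,
      locations = locations, window = window, binSize = binSize,
      labels = as.character(labels), backgrounds = bgs)
}

#' Map selected features back onto a spectrum
#'
#' Returns overlay markers (one per selected feature) in both index and
#' axis coordinates, suitable for replotting discriminatory locations onto
#' the original instrument output. Pure function of its inputs.
#'
#' @param spectrum a \linkS4class{GCIMSSpectrum}.
#' @param selected data.frame with columns \code{retention} and
#'   \code{drift} (as in \code{featureLocations}); an optional \code{rank}
#'   column is propagated, otherwise ranks follow row order.
#' @return data.frame \code{retention_index}, \code{drift_index},
#'   \code{retention_time}, \code{drift_time}, \code{rank}.
#' @export
replotFeatures <- function(spectrum, selected) {
  stopifnot(is(spectrum, "GCIMSSpectrum"))
  if (nrow(selected) == 0L)
    return(data.frame(retention_index = integer(0), drift_index = integer(0),
                      retention_time = numeric(0), drift_time = numeric(0),
                      rank = integer(0)))
  if (any(selected$retention < 1 |
          selected$retention > nrow(spectrum@intensities) |
          selected$drift < 1 | selected$drift > ncol(spectrum@intensities)))
    stop("validation error: feature location outside spectrum bounds")
  data.frame(
    retention_index = as.integer(selected$retention),
    drift_index = as.integer(selected$drift),
    retention_time = spectrum@retentionAxis[selected$retention],
    drift_time = spectrum@driftAxis[selected$drift],
    rank = if ("rank" %in% names(selected)) selected$rank
           else seq_len(nrow(selected)))
}

#' Plot a spectrum with optional feature overlay
#'
#' Heat-map rendering of a spectrum (drift time on x, retention time on y,
#' as instrument software draws it) with optional markers from
#' \code{\link{replotFeatures}}.
#'
#' @param spectrum a \linkS4class{GCIMSSpectrum}.
#' @param overlay optional data.frame from \code{\link{replotFeatures}}.
#' @param ... passed to \code{\link[graphics]{image}}.
#' @return invisibly, the overlay.
#' @export
plotSpectrum <- function(spectrum, overlay = NULL, ...) {
  m <- spectrum@intensities
  graphics::image(x = spectrum@driftAxis, y = spectrum@retentionAxis,
                  z = t(log1p(m)), xlab = "drift time",
                  ylab = "retention time", main = spectrum@sampleId, ...)
  if (!is.null(overlay) && nrow(overlay))
    graphics::points(overlay$drift_time, overlay$retention_time, pch = 21,
                     bg = "white")
  invisible(overlay)
}
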