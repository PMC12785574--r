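# Preprocessing: mass calibration, ROI extraction, peak integration,
# TIC normalisation, and the study-level driver producing the peak table.

#' Internally calibrate the mass axis against reference ions
#'
#' Locates each reference species as the strongest channel of the mean
#' spectrum within +/- \code{tolerance} Th of its expected position and
#' fits a least-squares polynomial from observed to expected positions in
#' sqrt(m/z) space (time-of-flight physics: flight time is proportional to
#' sqrt(m/z)). The fitted map is applied to the whole axis. Fewer than two
#' detectable references skips calibration with a warning flag; any
#' post-fit residual above \code{maxResidualPpm} marks the image as failing
#' validation (the mass-accuracy contract is 300 ppm).
#'
#' @param image a \linkS4class{SpectralImage}.
#' @param refs named numeric vector of expected reference m/z positions.
#' @param tolerance search half-window around each reference (Th).
#' @param degree polynomial degree of the fit in sqrt(m/z) space (1 covers
#'   multiplicative drift; 2 available for larger distortions).
#' @param maxResidualPpm residual threshold for the validation flag.
#' @return A list with \code{image} (calibrated; metadata fields
#'   \code{calibration_skipped}, \code{calibration_failed},
#'   \code{calibration_residual_ppm} filled in) and \code{residualPpm}
#'   (named per-reference post-fit residuals).
#' @export
calibrateMassAxis <- function(image, refs = defaultCalibrationRefs(),
                              tolerance = 0.5, degree = 1L,
                              maxResidualPpm = 300) {
  stopifnot(is(image, "SpectralImage"), degree %in% c(1L, 2L))
  mz <- mzAxis(image)
  meanSpec <- apply(counts(image), 3L, sum)
  observed <- expected <- numeric(0)
  for (i in seq_along(refs)) {
    cand <- which(abs(mz - refs[[i]]) <= tolerance)
    cand <- cand[meanSpec[cand] > 0]
    if (!length(cand)) next
    observed <- c(observed, mz[cand[which.max(meanSpec[cand])]])
    expected <- c(expected, refs[[i]])
    names(expected)[length(expected)] <- names(refs)[i]
  }
  md <- imageMetadata(image)
  if (length(observed) < 2L) {
    warning("fewer than 2 calibration references detected; calibration skipped")
    md$calibration_skipped <- TRUE
    imageMetadata(image) <- md
    return(list(image = image, residualPpm = stats::setNames(
      rep(NA_real_, length(refs)), names(refs))))
  }
  so <- sqrt(observed)
  fit <- if (degree == 1L) stats::lm(sqrt(expected) ~ so)
         else stats::lm(sqrt(expected) ~ so + I(so^2))
  remap <- function(m) {
    s <- sqrt(m)
    p <- stats::coef(fit)
    out <- p[[1L]] + p[[2L]] * s
    if (degree == 2L) out <- out + p[[3L]] * s^2
    out^2
  }
  residualPpm <- stats::setNames(
    (remap(observed) - expected) / expected * 1e6, names(expected))
  mzAxis(image) <- remap(mz)
  md$calibration_skipped <- FALSE
  md$calibration_failed <- max(abs(residualPpm)) > maxResidualPpm
  md$calibration_residual_ppm <- residualPpm
  imageMetadata(image) <- md
  if (md$calibration_failed)
    warning("calibration residual exceeds ", maxResidualPpm, " ppm")
  list(image = image, residualPpm = residualPpm)
}

#' @describeIn extractROI centred square crop of
#'   \code{round(roiSizeUm / pixelSizeUm)} pixels per side, offset
#'   \code{floor((width - roi)/2)} from the image origin (round-to-nearest
#'   side length, floored offset, so results are bit-reproducible). A
#'   150 um ROI on a 128 px / 250 um image is the 77 x 77 px block starting
#'   at zero-based pixel (25, 25).
#' @export
setMethod("extractROI", "SpectralImage", function(x, roiSizeUm = 150, ...) {
  d <- dim(counts(x))
  roiPx <- round(roiSizeUm / pixelSizeUm(x))
  if (roiPx < 1L)
    stop("ROI smaller than one pixel")
  if (roiPx > d[1L] || roiPx > d[2L])
    stop("ROI of ", roiSizeUm, " um (", roiPx,
         " px) exceeds the image extent")
  ox <- floor((d[1L] - roiPx) / 2)
  oy <- floor((d[2L] - roiPx) / 2)
  md <- imageMetadata(x)
  md$roi_offset_px <- c(x = ox, y = oy)
  md$roi_size_px <- roiPx
  SpectralImage(counts(x)[ox + seq_len(roiPx), oy + seq_len(roiPx), ,
                          drop = FALSE],
                mz = mzAxis(x), pixelSizeUm = pixelSizeUm(x),
                polarity = polarity(x), metadata = md)
})

# per-ion channel windows; overlapping windows are truncated at the
# midpoint between the two target positions (left ion keeps channels
# <= midpoint, right ion channels > midpoint: no double counting)
ionWindows <- function(targetMz, window, windowMode) {
  half <- switch(windowMode, absolute = rep(window, length(targetMz)),
                 ppm = targetMz * window * 1e-6)
  lo <- targetMz - half
  hi <- targetMz + half
  ord <- order(targetMz)
  for (k in seq_len(length(ord) - 1L)) {
    i <- ord[k]; j <- ord[k + 1L]
    if (hi[i] >= lo[j]) {
      mid <- (targetMz[i] + targetMz[j]) / 2
      hi[i] <- mid
      lo[j] <- mid
    }
  }
  list(lo = lo, hi = hi, open_left = ord[-1L][hi[ord[-length(ord)]] ==
                                              lo[ord[-1L]]])
}

#' @describeIn integratePeaks sum of counts over all pixels and all
#'   channels within the integration window of each target ion
#'   (+/- \code{window} Th in \code{"absolute"} mode, +/- \code{window} ppm
#'   in \code{"ppm"} mode).
#' @param window half-width of the integration window.
#' @param windowMode \code{"absolute"} (Th) or \code{"ppm"}.
#' @export
setMethod("integratePeaks", "SpectralImage",
          function(x, ions, window = 0.05,
                   windowMode = c("absolute", "ppm"), ...) {
  windowMode <- match.arg(windowMode)
  mz <- mzAxis(x)
  outside <- which(ions$mz < min(mz) - window | ions$mz > max(mz) + window)
  if (length(outside))
    stop("ion m/z ", paste(ions$mz[outside], collapse = ", "),
         " outside the acquired mass axis")
  wins <- ionWindows(ions$mz, window, windowMode)
  chanSum <- apply(counts(x), 3L, sum)
  out <- numeric(nrow(ions))
  for (i in seq_len(nrow(ions))) {
    inWin <- mz >= wins$lo[i] & mz <= wins$hi[i]
    if (i %in% wins$open_left)
      inWin <- mz > wins$lo[i] & mz <= wins$hi[i]
    out[i] <- sum(chanSum[inWin])
  }
  stats::setNames(out, formatMz(ions$mz))
})

#' Normalise integrated peak intensities to the total ion count
#'
#' Divides each raw per-ion count by the total ion count of the same ROI
#' (the sum over all channels, not only the target panel), yielding
#' dimensionless relative intensities and cancelling dose and global
#' ionisation-efficiency scale.
#'
#' @param raw numeric vector of integrated per-ion counts.
#' @param totalIonCount total counts over all channels of the ROI.
#' @return \code{raw / totalIonCount}.
#' @export
ticNormalize <- function(raw, totalIonCount) {
  if (!is.finite(totalIonCount) || totalIonCount < 0)
    stop("total ion count must be finite and non-negative")
  if (totalIonCount == 0)
    stop("zero total ion count: cannot normalise")
  raw / totalIonCount
}

#' Preprocess a set of images into a TIC-normalised peak table
#'
#' Per image: optional mass calibration, central ROI crop, window
#' integration of the target panel, TIC normalisation. The result is a
#' replicate-level \linkS4class{PeakTable} whose metadata holds the
#' per-image calibration report (residual ppm, pass/fail).
#'
#' @param images named list of \linkS4class{SpectralImage}s (names =
#'   sample ids) or a directory containing \code{samples.csv} plus imzML
#'   files as written by \code{\link{writeStudy}}.
#' @param ions target ion panel.
#' @param samples sample metadata data.frame (required when \code{images}
#'   is a list; columns sample_id, group, animal, replicate).
#' @param roiSizeUm ROI edge length (um).
#' @param window,windowMode integration window (see
#'   \code{\link{integratePeaks}}).
#' @param calibrate run mass calibration before integration.
#' @param calibrationRefs reference species for calibration.
#' @return A replicate-level \linkS4class{PeakTable};
#'   \code{metadata(x)$calibration} is the calibration report.
#' @export
preprocessStudy <- function(images, ions = referenceIons(), samples = NULL,
                            roiSizeUm = 150, window = 0.05,
                            windowMode = "absolute", calibrate = TRUE,
                            calibrationRefs = defaultCalibrationRefs()) {
  if (is.character(images)) {
    dir <- images
    csv <- file.path(dir, "samples.csv")
    if (!file.exists(csv))
      stop("expected sample metadata file not found: ", csv)
    samples <- utils::read.csv(csv, stringsAsFactors = FALSE)
    images <- lapply(stats::setNames(samples$file, samples$sample_id),
                     function(f) readImzML(file.path(dir, f)))
  }
  if (is.null(samples))
    stop("'samples' metadata is required when passing images directly")
  stopifnot(all(samples$sample_id %in% names(images)))
  vals <- matrix(NA_real_, nrow(ions), nrow(samples))
  calReport <- vector("list", nrow(samples))
  for (i in seq_len(nrow(samples))) {
    img <- images[[samples$sample_id[i]]]
    if (calibrate) {
      cal <- calibrateMassAxis(img, refs = calibrationRefs)
      img <- cal$image
      calReport[[i]] <- data.frame(
        sample_id = samples$sample_id[i],
        max_abs_residual_ppm = suppressWarnings(max(abs(cal$residualPpm),
                                                    na.rm = TRUE)),
        skipped = isTRUE(imageMetadata(img)$calibration_skipped),
        passed = !isTRUE(imageMetadata(img)$calibration_failed),
        stringsAsFactors = FALSE)
    }
    roi <- extractROI(img, roiSizeUm = roiSizeUm)
    raw <- integratePeaks(roi, ions, window = window, windowMode = windowMode)
    vals[, i] <- ticNormalize(raw, sum(counts(roi)))
  }
  pt <- PeakTable(vals, ions[c("mz", "annotation", "ion_class")],
                  samples[metaCols])
  if (calibrate)
    S4Vectors::metadata(pt)$calibration <-
      do.call(rbind, c(calReport, make.row.names = FALSE))
  pt
}
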