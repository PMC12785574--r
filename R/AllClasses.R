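#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' SpectralImage: a pixel grid of ion counts on a common m/z axis
#'
#' Container for one hyperspectral secondary-ion image: a
#' \code{width x height x channels} array of non-negative ion counts, the
#' shared m/z axis (channel centres, Thomson), the physical pixel size and
#' the acquisition polarity.
#'
#' @slot counts numeric array, \code{dim = c(width_px, height_px, n_channels)},
#'   all values \code{>= 0}.
#' @slot mz strictly increasing numeric vector of channel centres (Th).
#' @slot pixelSizeUm physical edge length of one pixel in micrometres.
#' @slot polarity \code{"negative"} or \code{"positive"}.
#' @slot metadata free-form list (instrument, sample identity, seeds,
#'   calibration diagnostics, ...).
#'
#' @examples
#' img <- SpectralImage(array(1, c(4, 4, 2)), mz = c(100, 200),
#'                      pixelSizeUm = 2)
#' imageDim(img)
#' @export
setClass("SpectralImage",
  representation(
    counts = "array",
    mz = "numeric",
    pixelSizeUm = "numeric",
    polarity = "character",
    metadata = "list"
  )
)

setValidity("SpectralImage", function(object) {
  msg <- NULL
  d <- dim(object@counts)
  if (length(d) != 3L)
    msg <- c(msg, "'counts' must be a 3-d array (width x height x channels)")
  else {
    if (d[3L] != length(object@mz))
      msg <- c(msg, "third dimension of 'counts' must match length of 'mz'")
    if (d[3L] < 1L)
      msg <- c(msg, "image must have at least one m/z channel")
  }
  if (length(object@mz) > 1L && any(diff(object@mz) <= 0))
    msg <- c(msg, "'mz' must be strictly increasing")
  if (anyNA(object@counts) || any(object@counts < 0))
    msg <- c(msg, "'counts' must be finite and non-negative")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0)
    msg <- c(msg, "'pixelSizeUm' must be a single positive number")
  if (!object@polarity %in% c("negative", "positive"))
    msg <- c(msg, "'polarity' must be 'negative' or 'positive'")
  if (is.null(msg)) TRUE else msg
})

#' @param counts numeric array \code{width x height x channels}.
#' @param mz numeric vector of channel centres (Th).
#' @param pixelSizeUm pixel edge length in micrometres.
#' @param polarity acquisition polarity.
#' @param metadata list of free-form metadata.
#' @rdname SpectralImage-class
#' @export
SpectralImage <- function(counts, mz, pixelSizeUm, polarity = "negative",
                          metadata = list()) {
  new("SpectralImage", counts = counts, mz = as.numeric(mz),
      pixelSizeUm = as.numeric(pixelSizeUm), polarity = polarity,
      metadata = metadata)
}

#' StudyDesign: group/animal/replicate structure of an imaging study
#'
#' The default design mirrors a three-arm rodent study: a lean healthy
#' control arm (LEAN, n = 4), a diabetic control arm (P1, n = 8) and a
#' metformin-treated diabetic arm (P2, n = 8), three technical replicate
#' acquisitions per animal, each a 128 x 128 pixel image over a
#' 250 x 250 um field of view.
#'
#' @slot groups character vector of unique group names.
#' @slot animalsPerGroup named integer vector, animals per group.
#' @slot technicalReplicates integer, acquisitions per animal.
#' @slot imageWidthPx,imageHeightPx image size in pixels.
#' @slot fieldOfViewUm physical edge length of the imaged field (um).
#' @slot seed integer base seed for study generation.
#' @export
setClass("StudyDesign",
  representation(
    groups = "character",
    animalsPerGroup = "integer",
    technicalReplicates = "integer",
    imageWidthPx = "integer",
    imageHeightPx = "integer",
    fieldOfViewUm = "numeric",
    seed = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- NULL
  if (anyDuplicated(object@groups))
    msg <- c(msg, "group names must be unique")
  if (!setequal(names(object@animalsPerGroup), object@groups))
    msg <- c(msg, "'animalsPerGroup' must be named by the group names")
  if (any(object@animalsPerGroup < 1L))
    msg <- c(msg, "every group needs at least one animal")
  if (object@technicalReplicates < 1L)
    msg <- c(msg, "'technicalReplicates' must be >= 1")
  if (object@imageWidthPx < 1L || object@imageHeightPx < 1L)
    msg <- c(msg, "image dimensions must be >= 1 pixel")
  if (!is.finite(object@fieldOfViewUm) || object@fieldOfViewUm <= 0)
    msg <- c(msg, "'fieldOfViewUm' must be positive")
  if (is.null(msg)) TRUE else msg
})

#' @param groups character vector of group names.
#' @param animalsPerGroup integer vector (recycled against \code{groups} by
#'   position if unnamed).
#' @param technicalReplicates acquisitions per animal.
#' @param imageWidthPx,imageHeightPx image size in pixels.
#' @param fieldOfViewUm field of view edge length (um).
#' @param seed integer base seed.
#' @rdname StudyDesign-class
#' @export
StudyDesign <- function(groups = c("LEAN", "P1", "P2"),
                        animalsPerGroup = c(LEAN = 4L, P1 = 8L, P2 = 8L),
                        technicalReplicates = 3L,
                        imageWidthPx = 128L, imageHeightPx = 128L,
                        fieldOfViewUm = 250, seed = 1L) {
  apg <- as.integer(animalsPerGroup)
  names(apg) <- if (is.null(names(animalsPerGroup))) groups
                else names(animalsPerGroup)
  new("StudyDesign", groups = groups, animalsPerGroup = apg[groups],
      technicalReplicates = as.integer(technicalReplicates),
      imageWidthPx = as.integer(imageWidthPx),
      imageHeightPx = as.integer(imageHeightPx),
      fieldOfViewUm = as.numeric(fieldOfViewUm), seed = as.integer(seed))
}

#' NoiseModel: stochastic acquisition model for the study generator
#'
#' Counting noise is Poisson at pixel level (static-SIMS detection is
#' counting-statistics dominated). The per-replicate total-ion-count (TIC)
#' budget and a smooth multiplicative spatial texture field emulate dose
#' fluctuation and lobular tissue heterogeneity; a per-animal log-normal
#' scale on each target ion provides between-animal biological variance.
#'
#' @slot ticPerPixelMean expected total counts per pixel.
#' @slot ticCv coefficient of variation of the per-replicate TIC budget.
#' @slot textureLengthUm correlation length of the spatial texture (um).
#' @slot textureCv amplitude (CV) of the mean-1 texture field.
#' @slot driftPpm multiplicative m/z axis miscalibration injected (ppm).
#' @slot animalCv CV of the per-animal log-normal scale per ion.
#' @export
setClass("NoiseModel",
  representation(
    ticPerPixelMean = "numeric",
    ticCv = "numeric",
    textureLengthUm = "numeric",
    textureCv = "numeric",
    driftPpm = "numeric",
    animalCv = "numeric"
  )
)

setValidity("NoiseModel", function(object) {
  vals <- c(object@ticPerPixelMean, object@ticCv, object@textureLengthUm,
            object@textureCv, object@animalCv)
  if (any(!is.finite(vals)) || any(vals < 0))
    "all noise parameters except 'driftPpm' must be finite and >= 0"
  else if (!is.finite(object@driftPpm))
    "'driftPpm' must be finite"
  else TRUE
})

#' @param ticPerPixelMean expected total counts per pixel.
#' @param ticCv CV of the per-replicate TIC budget.
#' @param textureLengthUm texture correlation length (um).
#' @param textureCv texture amplitude (CV of the mean-1 field).
#' @param driftPpm injected multiplicative mass miscalibration (ppm).
#' @param animalCv CV of the per-animal per-ion log-normal scale.
#' @rdname NoiseModel-class
#' @export
NoiseModel <- function(ticPerPixelMean = 2000, ticCv = 0.05,
                       textureLengthUm = 30, textureCv = 0.08,
                       driftPpm = 0, animalCv = 0.10) {
  new("NoiseModel", ticPerPixelMean = ticPerPixelMean, ticCv = ticCv,
      textureLengthUm = textureLengthUm, textureCv = textureCv,
      driftPpm = driftPpm, animalCv = animalCv)
}

#' A noise-free acquisition model
#'
#' All coefficients of variation set to zero and no mass drift; combined
#' with \code{sampleCounts = FALSE} in the generator this yields the exact
#' expectation of every pixel, so the full pipeline must return the
#' reference group means to numerical precision.
#'
#' @param ticPerPixelMean expected total counts per pixel.
#' @return A \linkS4class{NoiseModel}.
#' @export
noiseFreeModel <- function(ticPerPixelMean = 2000) {
  NoiseModel(ticPerPixelMean = ticPerPixelMean, ticCv = 0, textureCv = 0,
             driftPpm = 0, animalCv = 0)
}

#' PeakTable: samples-by-ions matrix of TIC-normalised ROI intensities
#'
#' Extends \link[SummarizedExperiment]{SummarizedExperiment}: rows are
#' target ions (rowData columns \code{mz}, \code{annotation},
#' \code{ion_class}), columns are samples (colData columns
#' \code{sample_id}, \code{group}, \code{animal}, \code{replicate}) and the
#' single assay \code{"intensity"} holds dimensionless TIC-normalised
#' ROI-averaged intensities in [0, 1].
#'
#' @export
setClass("PeakTable", contains = "SummarizedExperiment")

setValidity("PeakTable", function(object) {
  msg <- NULL
  if (!"intensity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'intensity' is required")
  else {
    a <- SummarizedExperiment::assay(object, "intensity")
    if (anyNA(a) || any(!is.finite(a)))
      msg <- c(msg, "intensities must be finite")
    else if (any(a < 0) || any(a > 1))
      msg <- c(msg, "intensities must lie in [0, 1]")
  }
  rd <- SummarizedExperiment::rowData(object)
  for (col in c("mz", "annotation", "ion_class"))
    if (!col %in% colnames(rd))
      msg <- c(msg, sprintf("rowData column '%s' is required", col))
  cd <- SummarizedExperiment::colData(object)
  for (col in c("sample_id", "group", "animal", "replicate"))
    if (!col %in% colnames(cd))
      msg <- c(msg, sprintf("colData column '%s' is required", col))
  if ("sample_id" %in% colnames(cd) && anyDuplicated(cd$sample_id))
    msg <- c(msg, "duplicate sample_id")
  if ("ion_class" %in% colnames(rd) &&
      !all(rd$ion_class %in% c("lipid", "amino_acid", "other")))
    msg <- c(msg, "ion_class must be one of 'lipid', 'amino_acid', 'other'")
  if (is.null(msg)) TRUE else msg
})

#' @param intensity numeric matrix, ions in rows and samples in columns.
#' @param ions data.frame with columns \code{mz}, \code{annotation},
#'   \code{ion_class} (one row per ion).
#' @param samples data.frame with columns \code{sample_id}, \code{group},
#'   \code{animal}, \code{replicate} (one row per sample).
#' @rdname PeakTable-class
#' @export
PeakTable <- function(intensity, ions, samples) {
  intensity <- as.matrix(intensity)
  rownames(intensity) <- formatMz(ions$mz)
  colnames(intensity) <- samples$sample_id
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(intensity = intensity),
    rowData = S4Vectors::DataFrame(ions),
    colData = S4Vectors::DataFrame(samples, row.names = samples$sample_id))
  new("PeakTable", se)
}

# canonical printed form of an m/z value, used for row names and headers
formatMz <- function(mz) formatC(mz, format = "fg", digits = 12)
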