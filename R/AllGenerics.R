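#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("mzAxis", function(x) standardGeneric("mzAxis"))

#' @export
setGeneric("mzAxis<-", function(x, value) standardGeneric("mzAxis<-"))

#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' @export
setGeneric("polarity", function(x) standardGeneric("polarity"))

#' @export
setGeneric("imageDim", function(x) standardGeneric("imageDim"))

#' @export
setGeneric("imageMetadata", function(x) standardGeneric("imageMetadata"))

#' @export
setGeneric("imageMetadata<-",
           function(x, value) standardGeneric("imageMetadata<-"))

#' @export
setGeneric("extractROI",
           function(x, roiSizeUm = 150, ...) standardGeneric("extractROI"))

#' @export
setGeneric("integratePeaks",
           function(x, ions, ...) standardGeneric("integratePeaks"))

#' @export
setGeneric("ionMap", function(x, mz, ...) standardGeneric("ionMap"))

#' Accessors for SpectralImage
#'
#' \code{mzAxis} returns the channel centres; \code{counts} the raw count
#' array; \code{pixelSizeUm} the physical pixel size; \code{polarity} the
#' acquisition polarity; \code{imageDim} the \code{c(width, height,
#' channels)} dimensions; \code{imageMetadata} the metadata list.
#'
#' @param x,object a \linkS4class{SpectralImage}.
#' @param value replacement value.
#' @name SpectralImage-accessors
#' @aliases mzAxis counts pixelSizeUm polarity imageDim imageMetadata
NULL

#' @rdname SpectralImage-accessors
#' @export
setMethod("mzAxis", "SpectralImage", function(x) x@mz)

#' @rdname SpectralImage-accessors
#' @export
setReplaceMethod("mzAxis", "SpectralImage", function(x, value) {
  x@mz <- as.numeric(value)
  validObject(x)
  x
})

#' @rdname SpectralImage-accessors
#' @export
setMethod("counts", "SpectralImage", function(object) object@counts)

#' @rdname SpectralImage-accessors
#' @export
setMethod("pixelSizeUm", "SpectralImage", function(x) x@pixelSizeUm)

#' @rdname SpectralImage-accessors
#' @export
setMethod("polarity", "SpectralImage", function(x) x@polarity)

#' @rdname SpectralImage-accessors
#' @export
setMethod("imageDim", "SpectralImage", function(x) dim(x@counts))

#' @rdname SpectralImage-accessors
#' @export
setMethod("imageMetadata", "SpectralImage", function(x) x@metadata)

#' @rdname SpectralImage-accessors
#' @export
setReplaceMethod("imageMetadata", "SpectralImage", function(x, value) {
  x@metadata <- value
  x
})

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@counts)
  cat(sprintf("SpectralImage: %d x %d px (%.4g um/px), %d m/z channels [%.4g..%.4g], %s mode\n",
              d[1L], d[2L], object@pixelSizeUm, d[3L],
              min(object@mz), max(object@mz), object@polarity))
  md <- object@metadata
  keys <- intersect(c("sample_id", "group", "animal", "replicate"), names(md))
  if (length(keys))
    cat("  ", paste(sprintf("%s=%s", keys, unlist(md[keys])), collapse = ", "),
        "\n", sep = "")
})

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:",
      paste(sprintf("%s(n=%d)", object@groups,
                    object@animalsPerGroup[object@groups]), collapse = ", "),
      sprintf("| %d replicates/animal | %dx%d px over %g um | seed %d\n",
              object@technicalReplicates, object@imageWidthPx,
              object@imageHeightPx, object@fieldOfViewUm, object@seed))
})

setMethod("show", "NoiseModel", function(object) {
  cat(sprintf(paste0("NoiseModel: TIC/px %g (cv %g), texture %g um (cv %g), ",
                     "drift %g ppm, animal cv %g\n"),
              object@ticPerPixelMean, object@ticCv, object@textureLengthUm,
              object@textureCv, object@driftPpm, object@animalCv))
})
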