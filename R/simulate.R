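# Synthetic ToF-SIMS study generator.
#
# Per pixel, each target ion's count is Poisson with mean
#   group_mean * TIC_budget * texture_multiplier  [* per-animal ion scale],
# while a broadband background of pseudo-ions (plus the five calibration
# reference species) fills the TIC fraction not assigned to targets, so
# per-pixel totals fluctuate around the nominal TIC budget and TIC
# normalisation is non-degenerate.

#' Default negative-ion calibration references
#'
#' The five low-mass reference species conventionally used for internal
#' mass calibration in negative mode: H-, C-, CH-, C2-, C3-.
#'
#' @return Named numeric vector of expected m/z positions (Th).
#' @export
defaultCalibrationRefs <- function() {
  c("H" = 1.0078, "C" = 12.0000, "CH" = 13.0078,
    "C2" = 24.0000, "C3" = 36.0000)
}

# fixed TIC fractions of the calibration species (dominant low-mass anions)
calibrationRefFractions <- function() {
  refs <- defaultCalibrationRefs()
  stats::setNames(c(0.04, 0.05, 0.03, 0.03, 0.02), names(refs))
}

# run code under a fixed seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# deterministic positions for broadband background pseudo-ions, kept clear
# of every target and calibration reference
backgroundPositions <- function(protected, n = 50L, mzMax = 911) {
  pos <- seq(7.3, mzMax - 7.3, length.out = n)
  for (i in seq_along(pos)) {
    while (any(abs(pos[i] - protected) < 0.6) ||
           (i > 1L && pos[i] - pos[i - 1L] < 0.6))
      pos[i] <- pos[i] + 0.73
  }
  pos
}

# full spectral model for one group: channel positions, per-channel TIC
# fraction, and which channels are panel targets
spectrumModel <- function(ions, group, nBackground = 50L) {
  targetMz <- ions$mz
  targetFrac <- if (nrow(ions)) ionGroupMeans(ions, group) else numeric(0)
  refs <- defaultCalibrationRefs()
  refFrac <- calibrationRefFractions()
  if (length(targetMz) && any(outer(targetMz, refs, function(a, b)
      abs(a - b)) < 0.5))
    stop("target ion overlaps a calibration reference species")
  bgMz <- backgroundPositions(sort(c(targetMz, refs)), n = nBackground)
  bgTotal <- 1 - sum(targetFrac) - sum(refFrac)
  if (bgTotal <= 0)
    stop("target panel and reference species exceed the total TIC budget")
  bgW <- exp(-bgMz / 180)
  bgFrac <- bgW / sum(bgW) * bgTotal
  mz <- c(targetMz, unname(refs), bgMz)
  frac <- c(targetFrac, unname(refFrac), bgFrac)
  isTarget <- c(rep(TRUE, length(targetMz)), rep(FALSE, length(refs) + nBackground))
  ord <- order(mz)
  list(mz = mz[ord], fraction = frac[ord], isTarget = isTarget[ord],
       targetIndex = match(targetMz, mz[ord]))
}

# smooth multiplicative random field: Gaussian-filtered white noise,
# rescaled to mean 1 and sd = cv, floored at 0.05
textureField <- function(width, height, lengthPx, cv) {
  if (cv == 0)
    return(matrix(1, width, height))
  z <- matrix(stats::rnorm(width * height), width, height)
  if (lengthPx > 0 && width > 1 && height > 1) {
    dx <- pmin(0:(width - 1), width - 0:(width - 1))
    dy <- pmin(0:(height - 1), height - 0:(height - 1))
    k <- outer(exp(-dx^2 / (2 * lengthPx^2)), exp(-dy^2 / (2 * lengthPx^2)))
    k <- k / sum(k)
    z <- Re(stats::fft(stats::fft(z) * stats::fft(k), inverse = TRUE)) /
      length(z)
  }
  s <- stats::sd(z)
  f <- if (s > 0) 1 + cv * (z - mean(z)) / s else matrix(1, width, height)
  pmax(f, 0.05)
}

#' Generate one synthetic secondary-ion image
#'
#' Simulates a single replicate acquisition for one animal of one group:
#' a sparse channel axis holding the target panel, the five calibration
#' reference species and a broadband background, with per-pixel Poisson
#' counting noise around the spectral model expectation.
#'
#' @param ions ion panel (see \code{\link{referenceIons}}); must carry a
#'   \code{mean_<group>} column for \code{group}.
#' @param group group name the image is drawn from.
#' @param noise a \linkS4class{NoiseModel}.
#' @param design a \linkS4class{StudyDesign} (geometry source).
#' @param seed integer seed; fixed seed gives bit-identical images.
#' @param sampleCounts if \code{FALSE}, Poisson sampling is replaced by its
#'   mean (the variance-off switch used for exactness checks).
#' @param ionScale optional multiplicative per-target-ion scale (the
#'   animal-level random effect, applied before Poisson sampling).
#' @return A \linkS4class{SpectralImage}; if \code{noise@driftPpm != 0} the
#'   stored m/z axis is shifted multiplicatively by that many ppm while the
#'   metadata keeps no record of the true axis (calibration must recover it).
#' @export
generateImage <- function(ions, group, noise = NoiseModel(),
                          design = StudyDesign(), seed = design@seed,
                          sampleCounts = TRUE, ionScale = NULL) {
  stopifnot(is(noise, "NoiseModel"), is(design, "StudyDesign"))
  model <- spectrumModel(ions, group)
  frac <- model$fraction
  if (!is.null(ionScale)) {
    stopifnot(length(ionScale) == length(model$targetIndex))
    frac[model$targetIndex] <- frac[model$targetIndex] * ionScale
  }
  w <- design@imageWidthPx
  h <- design@imageHeightPx
  pxUm <- design@fieldOfViewUm / w
  withSeed(seed, {
    ticBudget <- noise@ticPerPixelMean
    if (noise@ticCv > 0) {
      slog <- sqrt(log(1 + noise@ticCv^2))
      ticBudget <- ticBudget * stats::rlnorm(1, -slog^2 / 2, slog)
    }
    tex <- textureField(w, h, noise@textureLengthUm / pxUm, noise@textureCv)
    lambda <- outer(as.vector(tex) * ticBudget, frac)
    x <- if (sampleCounts) {
      matrix(stats::rpois(length(lambda), lambda), nrow(lambda), ncol(lambda))
    } else lambda
  })
  dim(x) <- c(w, h, length(frac))
  SpectralImage(x, mz = model$mz * (1 + noise@driftPpm * 1e-6),
                pixelSizeUm = pxUm, polarity = "negative",
                metadata = list(group = group, seed = as.integer(seed)))
}

#' Generate a complete synthetic study
#'
#' One image per (animal, technical replicate). Animal-level biological
#' variability is a per-animal log-normal scale on each target ion
#' (\code{noise@animalCv}), drawn once per animal and shared by its
#' replicates, so between-animal variance exceeds between-replicate
#' variance.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param ions ion panel with a \code{mean_<group>} column per group.
#' @param noise a \linkS4class{NoiseModel}.
#' @param sampleCounts passed to \code{\link{generateImage}}.
#' @return A list with \code{images} (list of \linkS4class{SpectralImage},
#'   named by sample id) and \code{samples} (data.frame with columns
#'   \code{sample_id}, \code{group}, \code{animal}, \code{replicate},
#'   \code{seed}).
#' @examples
#' d <- StudyDesign(imageWidthPx = 8, imageHeightPx = 8)
#' st <- generateStudy(d, referenceIons(), NoiseModel())
#' length(st$images)   # 60
#' @export
generateStudy <- function(design = StudyDesign(), ions = referenceIons(),
                          noise = NoiseModel(), sampleCounts = TRUE) {
  stopifnot(is(design, "StudyDesign"))
  for (g in design@groups) ionGroupMeans(ions, g)   # fail early, names ion
  images <- list()
  rows <- list()
  aGlobal <- 0L
  base <- as.integer(design@seed) %% 100000L
  for (g in design@groups) {
    for (a in seq_len(design@animalsPerGroup[[g]])) {
      aGlobal <- aGlobal + 1L
      animal <- sprintf("%s_%d", g, a)
      scale <- rep(1, nrow(ions))
      if (noise@animalCv > 0) {
        slog <- sqrt(log(1 + noise@animalCv^2))
        scale <- withSeed(base * 10007L + aGlobal * 97L,
                          stats::rlnorm(nrow(ions), -slog^2 / 2, slog))
      }
      for (r in seq_len(design@technicalReplicates)) {
        sid <- sprintf("%s_r%d", animal, r)
        imgSeed <- (base * 20011L + aGlobal * 1031L + r * 131L) %% 2147483647L
        img <- generateImage(ions, g, noise, design, seed = imgSeed,
                             sampleCounts = sampleCounts, ionScale = scale)
        md <- imageMetadata(img)
        md$sample_id <- sid
        md$animal <- animal
        md$replicate <- r
        imageMetadata(img) <- md
        images[[sid]] <- img
        rows[[sid]] <- data.frame(sample_id = sid, group = g,
                                  animal = animal, replicate = r,
                                  seed = imgSeed, stringsAsFactors = FALSE)
      }
    }
  }
  list(images = images, samples = do.call(rbind, c(rows, make.row.names = FALSE)))
}

#' Write a generated study to disk
#'
#' Saves one continuous-mode imzML file per image plus a sample-metadata
#' CSV (columns sample_id, group, animal, replicate, file, seed).
#'
#' @param study result of \code{\link{generateStudy}}.
#' @param dir output directory (created if needed).
#' @return Invisibly, the path of the metadata CSV.
#' @export
writeStudy <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- study$samples
  samples$file <- paste0(samples$sample_id, ".imzML")
  for (i in seq_len(nrow(samples)))
    writeImzML(study$images[[samples$sample_id[i]]],
               file.path(dir, samples$file[i]))
  csv <- file.path(dir, "samples.csv")
  utils::write.csv(samples, csv, row.names = FALSE)
  invisible(csv)
}
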