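test_that("an undrifted axis calibrates to the identity map", {
  img <- generateImage(referenceIons(), "LEAN", noiseFreeModel(),
                       smallDesign(8L), seed = 1, sampleCounts = FALSE)
  cal <- calibrateMassAxis(img)
  expect_lt(max(abs(cal$residualPpm)), 1e-6)
  expect_equal(mzAxis(cal$image), mzAxis(img), tolerance = 1e-12)
  expect_false(imageMetadata(cal$image)$calibration_failed)
})

test_that("a 200 ppm multiplicative drift is corrected below 10 ppm", {
  ions <- referenceIons()
  drift <- NoiseModel(ticCv = 0, textureCv = 0, animalCv = 0,
                      driftPpm = 200)
  img <- generateImage(ions, "LEAN", drift, smallDesign(16L), seed = 1,
                       sampleCounts = FALSE)
  cal <- calibrateMassAxis(img)
  expect_equal(length(cal$residualPpm), 5L)
  expect_lt(max(abs(cal$residualPpm)), 10)
  # mass accuracy contract: surviving images stay under 300 ppm
  expect_lt(max(abs(cal$residualPpm)), 300)
  expect_false(imageMetadata(cal$image)$calibration_failed)
  # and the corrected axis recovers the true peak positions
  roi <- extractROI(cal$image, 150)
  norm <- ticNormalize(integratePeaks(roi, ions), sum(counts(roi)))
  expect_equal(unname(norm), ions$mean_LEAN, tolerance = 1e-9)
})

test_that("non-linear axis distortion beyond 300 ppm raises the failure flag", {
  img <- generateImage(referenceIons(), "LEAN", noiseFreeModel(),
                       smallDesign(8L), seed = 1, sampleCounts = FALSE)
  mz <- mzAxis(img)
  refs <- defaultCalibrationRefs()
  idx <- vapply(refs, function(r) which.min(abs(mz - r)), 1L)
  mz[idx] <- mz[idx] * (1 + c(800, -800, 800, -800, 800) * 1e-6)
  mzAxis(img) <- sort(mz)
  expect_warning(cal <- calibrateMassAxis(img), "exceeds 300 ppm")
  expect_true(imageMetadata(cal$image)$calibration_failed)
})

test_that("calibration is skipped with a warning when references are absent", {
  img <- SpectralImage(array(1, c(2, 2, 3)), mz = c(100, 200, 300),
                       pixelSizeUm = 1)
  expect_warning(cal <- calibrateMassAxis(img), "skipped")
  expect_true(imageMetadata(cal$image)$calibration_skipped)
  expect_identical(mzAxis(cal$image), c(100, 200, 300))
})

test_that("ROI cropping follows the round/floor convention", {
  # 128 px over 250 um: 150 um is 76.8 -> 77 px, offset floor(51/2) = 25
  img <- SpectralImage(array(1, c(128, 128, 1)), mz = 100,
                       pixelSizeUm = 250 / 128)
  roi <- extractROI(img, 150)
  expect_equal(dim(counts(roi))[1:2], c(77L, 77L))
  expect_equal(unname(imageMetadata(roi)$roi_offset_px), c(25, 25))
  # independent index oracle for the same convention
  pxSize <- 250 / 128
  side <- round(150 / pxSize)
  expect_equal(side, 77)
  expect_equal((128 - side) %/% 2, 25)
  # ROI = field of view is the identity crop
  whole <- extractROI(img, 250)
  expect_equal(dim(counts(whole)), dim(counts(img)))
  # 2 px ROI on a 4 px image sits at offset 1
  small <- SpectralImage(array(1, c(4, 4, 1)), mz = 100, pixelSizeUm = 1)
  roi2 <- extractROI(small, 2)
  expect_equal(unname(imageMetadata(roi2)$roi_offset_px), c(1, 1))
  expect_error(extractROI(small, 9), "exceeds")
})

test_that("peak integration sums the window and conserves overlapping mass", {
  # single channel exactly at the target, every pixel 1 count
  img <- SpectralImage(array(1, c(5, 4, 1)), mz = 150.05, pixelSizeUm = 1)
  ions <- data.frame(mz = 150.05, annotation = "x", ion_class = "other",
                     mean_LEAN = 1e-3)
  expect_equal(unname(integratePeaks(img, ions)), 20)
  # two ions 0.04 Th apart: +/-0.05 windows truncate at the midpoint
  arr <- array(0, c(1, 1, 3))
  arr[1, 1, ] <- c(10, 7, 5)
  img2 <- SpectralImage(arr, mz = c(100.00, 100.02, 100.04), pixelSizeUm = 1)
  pair <- data.frame(mz = c(100.00, 100.04), annotation = c("l", "r"),
                     ion_class = "other", mean_LEAN = 0)
  got <- integratePeaks(img2, pair)
  expect_equal(unname(got), c(17, 5))          # midpoint channel goes left
  expect_equal(sum(got), sum(arr))             # no double counting
  expect_error(integratePeaks(img2, data.frame(mz = 700, annotation = "z",
                                               ion_class = "other")),
               "700")
})

test_that("TIC normalisation is exact, scale-invariant and guards zero TIC", {
  expect_equal(ticNormalize(c(5, 15), 100), c(0.05, 0.15))
  expect_equal(ticNormalize(10 * c(5, 15), 10 * 100), c(0.05, 0.15))
  expect_error(ticNormalize(c(1, 2), 0), "zero total ion count")
  # a TIC-normalised full spectrum sums to one
  set.seed(8)
  spec <- rpois(30, 50)
  expect_equal(sum(ticNormalize(spec, sum(spec))), 1)
})

test_that("cropping first and integrating equals integrating the crop", {
  ions <- tinyPanel()
  img <- generateImage(ions, "P1", NoiseModel(animalCv = 0),
                       smallDesign(16L), seed = 13)
  roi <- extractROI(img, 150)
  direct <- integratePeaks(roi, ions)
  off <- imageMetadata(roi)$roi_offset_px
  side <- imageMetadata(roi)$roi_size_px
  manual <- counts(img)[off[1] + seq_len(side), off[2] + seq_len(side), ,
                        drop = FALSE]
  manualSum <- integratePeaks(
    SpectralImage(manual, mzAxis(img), pixelSizeUm(img)), ions)
  expect_identical(direct, manualSum)
})

test_that("noise-free preprocessing recovers the panel means to 1e-12", {
  ions <- tinyPanel()
  d <- StudyDesign(animalsPerGroup = c(LEAN = 2L, P1 = 2L, P2 = 2L),
                   technicalReplicates = 2L, imageWidthPx = 8L,
                   imageHeightPx = 8L, seed = 2L)
  st <- generateStudy(d, ions, noiseFreeModel(), sampleCounts = FALSE)
  pt <- preprocessStudy(st$images, ions, samples = st$samples)
  ag <- aggregateReplicates(pt)
  a <- SummarizedExperiment::assay(ag, "intensity")
  cd <- SummarizedExperiment::colData(ag)
  for (g in c("LEAN", "P1", "P2")) {
    est <- rowMeans(a[, cd$group == g, drop = FALSE])
    expect_equal(unname(est), ionGroupMeans(ions, g), tolerance = 1e-12)
  }
  # calibration report covers every image and passes
  cal <- S4Vectors::metadata(pt)$calibration
  expect_equal(nrow(cal), 12L)
  expect_true(all(cal$passed))
})
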