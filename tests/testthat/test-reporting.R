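fakeResults <- function(fc, p) {
  S4Vectors::DataFrame(mz = seq_along(fc) + 100, annotation = "x",
                       ion_class = "lipid", log2fc_lean_p1 = fc,
                       log2fc_p2_p1 = fc, tukey_P1_LEAN = p,
                       tukey_P2_P1 = p, p_anova = p)
}

test_that("volcano flags use strict thresholds on the contrast p", {
  res <- fakeResults(fc = c(0.6, -1.75, 0.3), p = c(1e-4, 1e-4, 1e-4))
  v <- volcanoData(res, "LEAN_vs_P1")
  expect_false(v$flagged[1])   # |log2FC| = 0.6 exactly is not flagged
  expect_true(v$flagged[2])    # strong diabetes-associated decrease
  expect_false(v$flagged[3])
  expect_equal(v$neg_log10_p, rep(4, 3))
  allNull <- volcanoData(fakeResults(c(2, -2, 3), rep(1, 3)), "P2_vs_P1")
  expect_equal(sum(allNull$flagged), 0L)
  expect_error(volcanoData(res, "P3_vs_P1"))
})

test_that("Z-scored rows are standardised and identical samples merge first", {
  set.seed(6)
  m <- matrix(runif(40, 1e-4, 1e-2), 5, 8)
  rownames(m) <- paste0("i", 1:5)
  colnames(m) <- paste0("s", 1:8)
  m[, 2] <- m[, 1]   # duplicate sample
  cl <- zscoreCluster(m)
  expect_equal(unname(rowMeans(cl$z)), rep(0, 5), tolerance = 1e-10)
  expect_equal(unname(apply(cl$z, 1, sd)), rep(1, 5), tolerance = 1e-10)
  expect_equal(sort(cl$colTree$merge[1, ]), c(-2, -1))
  # zero-variance ions are dropped with a warning
  m2 <- rbind(m, i6 = rep(5e-3, 8))
  expect_warning(cl2 <- zscoreCluster(m2), "zero-variance")
  expect_equal(nrow(cl2$z), 5L)
})

test_that("noise-free groups split into three pure clusters", {
  ions <- referenceIons()
  d <- StudyDesign(animalsPerGroup = c(LEAN = 3L, P1 = 3L, P2 = 3L),
                   technicalReplicates = 1L, imageWidthPx = 8L,
                   imageHeightPx = 8L, seed = 9L)
  st <- generateStudy(d, ions, noiseFreeModel(), sampleCounts = FALSE)
  pt <- preprocessStudy(st$images, ions, samples = st$samples,
                        calibrate = FALSE)
  cl <- zscoreCluster(pt)
  k3 <- cutree(cl$colTree, k = 3)
  groups <- SummarizedExperiment::colData(pt)$group
  expect_equal(length(unique(tapply(k3, groups, function(x)
    length(unique(x))))), 1L)
  expect_true(all(tapply(k3, groups, function(x) length(unique(x))) == 1))
})

test_that("ion maps are TIC-relative, fixed-scale and ground-truth ordered", {
  uni <- SpectralImage(array(rep(c(3, 7), each = 16), c(4, 4, 2)),
                       mz = c(100, 241.043), pixelSizeUm = 1)
  m <- ionMap(uni, 241.043)
  expect_true(all(abs(m$raster - 0.7) < 1e-12))  # constant raster
  mFixed1 <- ionMap(uni, 241.043, scale = "fixed", fixedRange = c(0, 1e-2))
  mFixed2 <- ionMap(uni, 241.043, scale = "fixed", fixedRange = c(0, 1e-2))
  expect_identical(mFixed1$zlim, mFixed2$zlim)   # shared colour mapping
  expect_error(ionMap(uni, 500), "empty integration window")
  ions <- referenceIons()
  d <- smallDesign(8L)
  lean <- generateImage(ions, "LEAN", NoiseModel(animalCv = 0), d, seed = 2)
  p1 <- generateImage(ions, "P1", NoiseModel(animalCv = 0), d, seed = 3)
  mLean <- ionMap(lean, 241.043)
  mP1 <- ionMap(p1, 241.043)
  expect_gt(mean(mLean$raster, na.rm = TRUE), mean(mP1$raster, na.rm = TRUE))
})

test_that("boxplot summaries follow the Tukey convention", {
  ions <- tinyPanel()
  vals <- matrix(0, 3, 5)
  vals[1, ] <- c(1, 2, 3, 4, 5) * 1e-3   # symmetric: median equals mean
  vals[2, ] <- rep(2e-3, 5)              # degenerate: zero-height box
  vals[3, ] <- c(1, 1.1, 1.2, 1.3, 9) * 1e-3   # outlier beyond the whisker
  pt <- makePeakTable(vals, groups = rep("LEAN", 5))
  bx <- boxplotSummaries(pt, ions$mz)
  s <- bx$summary
  expect_equal(s$median[s$mz == 100.1], mean(vals[1, ]))
  expect_equal(s$q1[s$mz == 300.5], 2e-3)
  expect_equal(s$q3[s$mz == 300.5], 2e-3)
  expect_equal(s$n_outliers[s$mz == 500.25], 1L)
  expect_true(bx$points$outlier[bx$points$mz == 500.25][5])
  expect_error(boxplotSummaries(pt, 999), "999")
})

test_that("simulated healthy tyrosine levels match the generator mean", {
  ions <- referenceIons()
  d <- StudyDesign(animalsPerGroup = c(LEAN = 4L, P1 = 2L, P2 = 2L),
                   technicalReplicates = 3L, imageWidthPx = 16L,
                   imageHeightPx = 16L, seed = 17L)
  st <- generateStudy(d, ions, NoiseModel(ticPerPixelMean = 32000))
  pt <- preprocessStudy(st$images, ions, samples = st$samples,
                        calibrate = FALSE)
  bx <- boxplotSummaries(pt, 180.05)
  s <- bx$summary[bx$summary$group == "LEAN", ]
  pts <- bx$points$value[bx$points$group == "LEAN"]
  se <- sd(pts) / sqrt(length(pts))
  expect_lt(abs(s$median - 1.45e-3), 3 * se)
})
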