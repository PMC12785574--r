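# brute-force sums-of-squares oracle for the one-way F statistic
bruteForceF <- function(values, groups) {
  g <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, g, function(x) length(x) * (mean(x) - grand)^2))
  ssw <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  df1 <- nlevels(g) - 1
  df2 <- length(values) - nlevels(g)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = pf(F, df1, df2, lower.tail = FALSE))
}

test_that("one-way ANOVA matches the sums-of-squares oracle", {
  ref <- oneWayAnova(c(1, 2, 2, 3, 3, 4), rep(c("a", "b", "c"), each = 2))
  oracle <- bruteForceF(c(1, 2, 2, 3, 3, 4), rep(c("a", "b", "c"), each = 2))
  expect_equal(ref$F, oracle$F, tolerance = 1e-12)
  expect_equal(ref$p, oracle$p, tolerance = 1e-12)
  set.seed(42)
  for (i in 1:20) {
    n <- sample(2:6, 3, replace = TRUE)
    y <- rnorm(sum(n))
    g <- rep(letters[1:3], n)
    got <- oneWayAnova(y, g)
    want <- bruteForceF(y, g)
    expect_equal(got$F, want$F, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
})

test_that("degenerate ANOVA inputs resolve by convention", {
  # three identical groups {1,2,3}: no between-group signal at all
  expect_warning(res <- oneWayAnova(rep(1:3, 3),
                                    rep(c("a", "b", "c"), each = 3)), NA)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)
  expect_warning(flat <- oneWayAnova(rep(2, 6), rep(c("a", "b", "c"), 2)),
                 "convention")
  expect_equal(flat$p, 1)
  sep <- oneWayAnova(c(0, 0, 1, 1), rep(c("a", "b"), each = 2))
  expect_equal(sep$F, Inf)
  expect_equal(sep$p, 0)
  expect_error(oneWayAnova(c(1, 2, 3), c("a", "a", "b")), "at least 2")
})

test_that("Tukey-Kramer p-values behave like the studentized range", {
  # identical groups: every pairwise p is 1
  same <- tukeyPairwise(rep(5, 9), rep(c("a", "b", "c"), 3))
  expect_equal(unname(same), c(1, 1, 1))
  # equal-n case engineered so the largest observed studentized range
  # equals the 5% critical value q(0.05, k = 3, df = 12)
  e <- c(-1, -0.5, 0, 0.5, 1)          # per-group residuals, MSE = 0.625
  mse <- sum(e^2) * 3 / 12
  qcrit <- qtukey(0.95, 3, 12)
  d <- qcrit * sqrt(mse / 5) / 2
  y <- c(e, e + d, e + 2 * d)
  g <- rep(c("a", "b", "c"), each = 5)
  p <- tukeyPairwise(y, g)
  expect_equal(unname(p["c-a"]), 0.05, tolerance = 1e-6)
  # monotonicity: widening one pair's separation never raises its p
  seps <- seq(0.5, 3, by = 0.5)
  ps <- vapply(seps, function(s)
    tukeyPairwise(c(e, e + 1, e + 1 + s), g)[["c-a"]], 0)
  expect_true(all(diff(ps) <= 1e-12))
})

test_that("Benjamini-Hochberg reproduces the step-up formula", {
  expect_equal(benjaminiHochberg(0.037), 0.037)
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.04, 0.05)),
               c(0.04, 0.04, 0.05, 0.05))
  # independent step-up oracle on random vectors + invariance properties
  stepUp <- function(p) {
    m <- length(p)
    o <- order(p)
    q <- p[o] * m / seq_len(m)
    q <- rev(cummin(rev(q)))
    pmin(q, 1)[order(o)]
  }
  set.seed(7)
  for (i in 1:10) {
    p <- runif(sample(3:40, 1))
    q <- benjaminiHochberg(p)
    expect_equal(q, stepUp(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(q <= 1))
    perm <- sample(length(p))
    expect_equal(benjaminiHochberg(p[perm]), q[perm])
  }
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("log2 fold changes reproduce the published worked examples", {
  expect_equal(round(log2FoldChange(1.28e-3, 9.06e-4), 2), 0.50)
  expect_equal(round(log2FoldChange(1.87e-5, 5.89e-6), 2), 1.67)
  expect_equal(log2FoldChange(3e-4, 3e-4), 0)
  expect_true(is.na(log2FoldChange(0, 1e-3)))
  expect_true(is.na(log2FoldChange(1e-3, -2)))
})

test_that("the trend taxonomy follows the sign pattern of the contrasts", {
  expect_equal(classifyTrend(1.16, 0.24), "Up")
  expect_equal(classifyTrend(-0.66, -0.09), "Down")
  expect_equal(classifyTrend(-1.75, 0.52), "Mixed")
  expect_equal(classifyTrend(0.0, 0.5), "Mixed")   # exact zero is Mixed
  expect_warning(out <- classifyTrend(c(1, NA), c(1, 1)), "unclassified")
  expect_equal(out, c("Up", NA))
})

test_that("the recovery index reproduces the published percentages", {
  expect_equal(round(recoveryIndex(1.28e-3, 9.06e-4, 9.24e-4), 1), 4.8)
  expect_equal(round(recoveryIndex(9.14e-5, 1.36e-4, 1.06e-4), 1), 67.3)
  expect_equal(recoveryIndex(2e-3, 1e-3, 1e-3), 0)
  expect_equal(recoveryIndex(2e-3, 1e-3, 2e-3), 100)
  expect_true(is.na(recoveryIndex(1e-3, 1e-3 + 1e-13, 2e-3)))
  # overshoot is reported, not clipped
  expect_gt(recoveryIndex(2e-3, 1e-3, 3e-3), 100)
})

test_that("the recovery index is invariant under affine rescaling", {
  set.seed(11)
  for (i in 1:25) {
    m <- sort(runif(3, 1e-5, 1e-2))[sample(3)]
    a <- runif(1, 0.1, 10); b <- runif(1, -1e-3, 1e-3)
    r1 <- recoveryIndex(m[1], m[2], m[3])
    r2 <- recoveryIndex(a * m[1] + b, a * m[2] + b, a * m[3] + b)
    expect_equal(r1, r2, tolerance = 1e-9)
  }
})

test_that("trend labels cohere with the sign of the LEAN-P1 gap", {
  set.seed(12)
  for (i in 1:50) {
    m <- runif(3, 1e-5, 1e-2)
    tr <- classifyTrend(log2FoldChange(m[1], m[2]),
                        log2FoldChange(m[3], m[2]))
    if (tr == "Up") expect_gt(m[1], m[2])
    if (tr == "Down") expect_lt(m[1], m[2])
  }
})

test_that("class contributions close to 100% and ignore overall scale", {
  set.seed(5)
  vals <- matrix(runif(3 * 6, 1e-4, 1e-2), 3, 6)
  pt <- makePeakTable(vals)
  cc <- classContribution(pt)
  expect_equal(cc$perSample$amino_pct + cc$perSample$lipid_pct,
               rep(100, 6))
  pt2 <- makePeakTable(vals * 2)
  cc2 <- classContribution(pt2)
  expect_equal(cc$perSample$amino_pct, cc2$perSample$amino_pct)
  # one amino ion at 1e-3 against one lipid ion at 3e-3 is 25% / 75%
  two <- PeakTable(matrix(c(1e-3, 3e-3), 2, 1),
                   data.frame(mz = c(100, 300), annotation = c("a", "l"),
                              ion_class = c("amino_acid", "lipid")),
                   data.frame(sample_id = "s", group = "LEAN",
                              animal = "s", replicate = 1L))
  cc3 <- classContribution(two)
  expect_equal(cc3$perSample$amino_pct, 25)
  expect_equal(cc3$perSample$lipid_pct, 75)
  # missing class is an error
  lipidOnly <- makePeakTable(vals, ions = transform(tinyPanel(),
                                                    ion_class = "lipid"))
  expect_error(classContribution(lipidOnly), "amino_acid")
})

test_that("assumption checks are calibrated under the null and detect
           heteroscedasticity", {
  set.seed(31)
  nullP <- replicate(1000, {
    y <- rnorm(24)
    assumptionChecks(y, rep(c("a", "b", "c"), each = 8))$levene_p
  })
  expect_gte(mean(nullP > 0.05), 0.90)
  altP <- replicate(200, {
    y <- c(rnorm(8, sd = 1), rnorm(8, sd = 10), rnorm(8, sd = 1))
    assumptionChecks(y, rep(c("a", "b", "c"), each = 8))$levene_p
  })
  expect_lt(median(altP), 0.05)
  # a group of two animals has no defined normality p
  ch <- assumptionChecks(c(1, 2, rnorm(6)), rep(c("tiny", "big"), c(2, 6)))
  expect_true(is.na(ch$shapiro_p[["tiny"]]))
  expect_false(is.na(ch$shapiro_p[["big"]]))
})

test_that("runDifferential populates every per-ion field coherently", {
  ions <- tinyPanel()
  d <- StudyDesign(animalsPerGroup = c(LEAN = 4L, P1 = 8L, P2 = 8L),
                   technicalReplicates = 2L, imageWidthPx = 12L,
                   imageHeightPx = 12L, seed = 3L)
  st <- generateStudy(d, ions, NoiseModel(ticPerPixelMean = 20000))
  pt <- preprocessStudy(st$images, ions, samples = st$samples,
                        calibrate = FALSE)
  res <- suppressMessages(runDifferential(pt))
  expect_equal(nrow(res), 3L)
  expect_true(all(res$q >= res$p_anova - 1e-15))
  expect_true(all(res$q >= 0 & res$q <= 1))
  expect_true(all(res$trend %in% c("Up", "Down", "Mixed")))
  expect_true(all(is.finite(res$recovery_pct)))
  expect_true(all(c("tukey_P2_P1", "shapiro_LEAN", "levene_p",
                    "significant") %in% colnames(res)))
  # BH families are corrected independently per ion class
  for (cls in unique(res$ion_class)) {
    idx <- res$ion_class == cls
    expect_equal(res$q[idx], benjaminiHochberg(res$p_anova[idx]))
  }
})

test_that("a default-noise study recovers the resolvable ground-truth
           trends", {
  # ions whose contrasts are several noise standard errors wide must label
  # correctly at a fixed seed; ions with near-zero printed contrasts (for
  # example log2FC 0.0057 at m/z 86.03) are below the between-animal noise
  # floor by construction and are exercised by the 100-seed rate check
  # instead
  ions <- referenceIons(full = TRUE)
  d <- StudyDesign(imageWidthPx = 32L, imageHeightPx = 32L, seed = 1L)
  noise <- NoiseModel(ticPerPixelMean = 2000 * (128 / 32)^2)
  st <- generateStudy(d, referenceIons(), noise)
  pt <- preprocessStudy(st$images, referenceIons(), samples = st$samples,
                        calibrate = FALSE)
  res <- suppressMessages(runDifferential(pt))
  truth <- classifyTrend(log2FoldChange(ions$mean_LEAN, ions$mean_P1),
                         log2FoldChange(ions$mean_P2, ions$mean_P1))
  strong <- c(536.376, 281.253, 805.749, 93.05)
  idx <- match(strong, ions$mz)
  expect_equal(res$trend[idx], truth[idx])
  # and the overall per-seed mislabel count stays within the noise budget
  expect_gte(sum(res$trend == truth), 20L)
})
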