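# Per-ion group statistics: one-way ANOVA with Tukey-Kramer pairwise
# contrasts, Benjamini-Hochberg FDR control, log2 fold changes, trend
# taxonomy relative to the diabetic control, the recovery index, class
# contributions, and the orchestrating runDifferential().

# degenerate fits are resolved by the documented conventions, so R's
# "essentially perfect fit" advisory on near-zero residual variance is noise
mufflePerfectFit <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("essentially perfect fit", conditionMessage(w)))
      invokeRestart("muffleWarning")
  })
}

asGroupFactor <- function(values, groups) {
  g <- factor(groups, levels = unique(groups))
  if (length(values) != length(g))
    stop("'values' and 'groups' lengths differ")
  n <- table(g)
  if (nlevels(g) < 2L)
    stop("at least two groups are required")
  if (any(n < 2L))
    stop("every group needs at least 2 observations (group '",
         names(n)[n < 2L][1L], "' has ", min(n), ")")
  g
}

#' Classical one-way ANOVA
#'
#' Between/within F ratio with (k-1, N-k) degrees of freedom via
#' \code{stats::aov}. Degenerate inputs are resolved by convention: zero
#' within- and between-group variance gives F = 0, p = 1 (with a warning);
#' zero within-group variance with real separation gives an infinite F
#' reported as p = 0.
#'
#' @param values numeric vector of observations.
#' @param groups group label per observation.
#' @return List with \code{F}, \code{p}, \code{df1}, \code{df2}.
#' @export
oneWayAnova <- function(values, groups) {
  g <- asGroupFactor(values, groups)
  df1 <- nlevels(g) - 1L
  df2 <- length(values) - nlevels(g)
  withinVar <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  groupMeans <- tapply(values, g, mean)
  betweenVar <- sum(tapply(values, g, length) *
                    (groupMeans - mean(values))^2)
  if (withinVar == 0) {
    if (betweenVar == 0) {
      warning("no variance within or between groups; p = 1 by convention")
      return(list(F = 0, p = 1, df1 = df1, df2 = df2))
    }
    return(list(F = Inf, p = 0, df1 = df1, df2 = df2))
  }
  tab <- mufflePerfectFit(stats::anova(stats::aov(values ~ g)))
  list(F = tab[["F value"]][1L], p = tab[["Pr(>F)"]][1L],
       df1 = df1, df2 = df2)
}

#' Tukey-Kramer pairwise contrasts
#'
#' Studentized-range adjusted p-values for every group pair, valid for
#' unequal group sizes, via \code{stats::TukeyHSD}.
#'
#' @inheritParams oneWayAnova
#' @return Named numeric vector of adjusted p-values; names are
#'   \code{"<groupB>-<groupA>"} as produced by \code{TukeyHSD}.
#' @export
tukeyPairwise <- function(values, groups) {
  g <- asGroupFactor(values, groups)
  pairNames <- apply(utils::combn(levels(g), 2L), 2L,
                     function(p) paste(p[2L], p[1L], sep = "-"))
  withinVar <- sum(tapply(values, g, function(x) sum((x - mean(x))^2)))
  if (withinVar == 0) {
    groupMeans <- tapply(values, g, mean)
    p <- vapply(strsplit(pairNames, "-", fixed = TRUE), function(pr)
      if (groupMeans[[pr[1L]]] == groupMeans[[pr[2L]]]) 1 else 0, 0)
    return(stats::setNames(p, pairNames))
  }
  tk <- mufflePerfectFit(stats::TukeyHSD(stats::aov(values ~ g)))$g
  stats::setNames(tk[pairNames, "p adj"], pairNames)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' \code{q_(i) = min_(j >= i) p_(j) * m / j} over the ascending sort,
#' capped at 1 and mapped back to input order (\code{stats::p.adjust},
#' method \code{"BH"}). Features with q below the chosen alpha are the
#' FDR-significant set.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Vector of q-values, same order as the input.
#' @export
benjaminiHochberg <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' log2 fold change of two group means
#'
#' \code{log2(meanA / meanB)} on TIC-normalised group means of
#' animal-level values. Undefined (NA) when either mean is not strictly
#' positive.
#'
#' @param meanA,meanB group mean intensities (vectorised).
#' @return Numeric vector; NA where undefined.
#' @export
log2FoldChange <- function(meanA, meanB) {
  out <- ifelse(is.na(meanA) | is.na(meanB) | meanA <= 0 | meanB <= 0,
                NA_real_, log2(meanA / meanB))
  as.numeric(out)
}

#' Trend taxonomy relative to the diabetic control
#'
#' Classifies each ion by the sign pattern of its two contrasts against
#' P1: both positive is \code{"Up"} (depleted in disease, restored by
#' treatment), both negative is \code{"Down"} (accumulated in disease),
#' anything else -- opposite signs or an exact zero -- is \code{"Mixed"}
#' (divergent or bidirectional behaviour, the residual category).
#'
#' @param log2fcLeanP1 log2 fold change of the healthy control vs P1.
#' @param log2fcP2P1 log2 fold change of the treated group vs P1.
#' @return Character vector in \code{c("Up", "Down", "Mixed")}; NA (with a
#'   warning) where either input is missing.
#' @export
classifyTrend <- function(log2fcLeanP1, log2fcP2P1) {
  out <- ifelse(log2fcLeanP1 > 0 & log2fcP2P1 > 0, "Up",
         ifelse(log2fcLeanP1 < 0 & log2fcP2P1 < 0, "Down", "Mixed"))
  miss <- is.na(log2fcLeanP1) | is.na(log2fcP2P1)
  if (any(miss)) {
    warning(sum(miss), " ion(s) unclassified: missing fold change")
    out[miss] <- NA_character_
  }
  as.character(out)
}

#' Recovery index: percent of the disease-control gap closed by treatment
#'
#' \code{100 * (I_P2 - I_P1) / (I_LEAN - I_P1)}, where I is the
#' TIC-normalised mean intensity of the ion in each group: 0 means no
#' change relative to the diabetic control, 100 full convergence to the
#' healthy level. Overshoot is reported, not clipped, so values outside
#' [0, 100] are legitimate. Undefined (NA) when the LEAN-P1 gap is below
#' the degeneracy threshold.
#'
#' @param iLean,iP1,iP2 group mean intensities (vectorised).
#' @param degeneracyThreshold absolute lower bound on |iLean - iP1|.
#' @return Numeric vector of percentages; NA where degenerate.
#' @examples
#' recoveryIndex(1.28e-3, 9.06e-4, 9.24e-4)   # ~4.8
#' @export
recoveryIndex <- function(iLean, iP1, iP2, degeneracyThreshold = 1e-12) {
  ifelse(!is.na(iLean) & !is.na(iP1) &
           abs(iLean - iP1) <= degeneracyThreshold,
         NA_real_, (iP2 - iP1) / (iLean - iP1) * 100)
}

#' Shapiro-Wilk and Levene diagnostics
#'
#' Normality per group (Shapiro-Wilk, needs n >= 3; undefined otherwise)
#' and homogeneity of variances across groups (Levene's test, mean
#' centring). These are reported alongside the ANOVA, never used to gate
#' it.
#'
#' @inheritParams oneWayAnova
#' @return List with \code{shapiro_p} (named per group, NA where
#'   undefined) and \code{levene_p}.
#' @export
assumptionChecks <- function(values, groups) {
  g <- factor(groups, levels = unique(groups))
  shapiro <- vapply(levels(g), function(lev) {
    x <- values[g == lev]
    if (length(x) < 3L || stats::sd(x) == 0) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, 0)
  levene <- tryCatch(
    mufflePerfectFit(car::leveneTest(values, g, center = "mean")[1L, "Pr(>F)"]),
    error = function(e) NA_real_)
  list(shapiro_p = shapiro, levene_p = levene)
}

#' Class-level contribution of amino-acid- and lipid-related ions
#'
#' Per sample, the percentage of the summed target-panel intensity carried
#' by each of the two ion classes (ions of class \code{"other"} are
#' excluded from the denominator); per group, mean and standard error over
#' samples. The two percentages close to 100 by construction.
#'
#' @param table a \linkS4class{PeakTable}.
#' @return List with \code{perSample} (sample_id, group, amino_pct,
#'   lipid_pct) and \code{perGroup} (group, class, mean_pct, sem_pct, n).
#' @export
classContribution <- function(table) {
  stopifnot(is(table, "PeakTable"))
  rd <- SummarizedExperiment::rowData(table)
  a <- SummarizedExperiment::assay(table, "intensity")
  for (cls in c("amino_acid", "lipid"))
    if (!any(rd$ion_class == cls))
      stop("no ions of class '", cls, "' in the table")
  amino <- colSums(a[rd$ion_class == "amino_acid", , drop = FALSE])
  lipid <- colSums(a[rd$ion_class == "lipid", , drop = FALSE])
  tot <- amino + lipid
  if (any(tot == 0)) stop("sample with zero panel intensity")
  cd <- SummarizedExperiment::colData(table)
  perSample <- data.frame(sample_id = cd$sample_id, group = cd$group,
                          amino_pct = 100 * amino / tot,
                          lipid_pct = 100 * lipid / tot,
                          stringsAsFactors = FALSE, row.names = NULL)
  sem <- function(x) stats::sd(x) / sqrt(length(x))
  perGroup <- do.call(rbind, lapply(unique(perSample$group), function(g) {
    s <- perSample[perSample$group == g, ]
    data.frame(group = g, class = c("amino_acid", "lipid"),
               mean_pct = c(mean(s$amino_pct), mean(s$lipid_pct)),
               sem_pct = c(sem(s$amino_pct), sem(s$lipid_pct)),
               n = nrow(s), stringsAsFactors = FALSE)
  }))
  list(perSample = perSample, perGroup = perGroup)
}

#' Per-ion differential analysis across the three study groups
#'
#' For every ion of an animal-level peak table: group means and SEMs,
#' one-way ANOVA F and p, Tukey-Kramer pairwise p-values, log2 fold
#' changes of the healthy and treated groups against the diabetic control,
#' the trend label, the recovery index, and Shapiro-Wilk/Levene
#' diagnostics. Benjamini-Hochberg adjustment is applied within each ion
#' class separately by default (the lipid and amino-acid panels are
#' reported as separate families); \code{family = "global"} pools all ions
#' into one family.
#'
#' @param table an animal-level \linkS4class{PeakTable} (replicate-level
#'   input is aggregated automatically with a message).
#' @param alpha FDR significance threshold on q.
#' @param family \code{"class"} or \code{"global"} BH family structure.
#' @param roles named character vector mapping the semantic roles
#'   \code{lean} (healthy control), \code{reference} (diabetic control)
#'   and \code{treated} to group names.
#' @param degeneracyThreshold passed to \code{\link{recoveryIndex}}.
#' @return A \link[S4Vectors]{DataFrame} with one row per ion, ordered as
#'   the input table.
#' @export
runDifferential <- function(table, alpha = 0.05,
                            family = c("class", "global"),
                            roles = c(lean = "LEAN", reference = "P1",
                                      treated = "P2"),
                            degeneracyThreshold = 1e-12) {
  stopifnot(is(table, "PeakTable"))
  family <- match.arg(family)
  cd <- SummarizedExperiment::colData(table)
  if (anyDuplicated(cd$animal)) {
    message("replicate-level table supplied; averaging to animal level")
    table <- aggregateReplicates(table)
    cd <- SummarizedExperiment::colData(table)
  }
  missingRoles <- setdiff(roles, unique(cd$group))
  if (length(missingRoles))
    stop("group(s) not present in the table: ",
         paste(missingRoles, collapse = ", "))
  if (min(table(cd$group)) < 2L)
    stop("need at least 2 animals per group after aggregation")
  rd <- SummarizedExperiment::rowData(table)
  a <- SummarizedExperiment::assay(table, "intensity")
  groups <- as.character(cd$group)
  glev <- unique(groups)
  sem <- function(x) stats::sd(x) / sqrt(length(x))

  res <- lapply(seq_len(nrow(a)), function(i) {
    y <- a[i, ]
    means <- vapply(glev, function(g) mean(y[groups == g]), 0)
    sems <- vapply(glev, function(g) sem(y[groups == g]), 0)
    aov1 <- oneWayAnova(y, groups)
    tk <- tukeyPairwise(y, groups)
    checks <- assumptionChecks(y, groups)
    fc1 <- log2FoldChange(means[[roles[["lean"]]]],
                          means[[roles[["reference"]]]])
    fc2 <- log2FoldChange(means[[roles[["treated"]]]],
                          means[[roles[["reference"]]]])
    cols <- c(stats::setNames(as.list(means), paste0("mean_", glev)),
              stats::setNames(as.list(sems), paste0("sem_", glev)),
              list(F = aov1$F, p_anova = aov1$p),
              stats::setNames(as.list(tk),
                              paste0("tukey_", gsub("-", "_", names(tk)))),
              list(log2fc_lean_p1 = fc1, log2fc_p2_p1 = fc2,
                   recovery_pct = recoveryIndex(
                     means[[roles[["lean"]]]], means[[roles[["reference"]]]],
                     means[[roles[["treated"]]]], degeneracyThreshold)),
              stats::setNames(as.list(checks$shapiro_p),
                              paste0("shapiro_", glev)),
              list(levene_p = checks$levene_p))
    as.data.frame(cols, check.names = FALSE)
  })
  block <- do.call(rbind, res)
  trend <- suppressWarnings(
    classifyTrend(block$log2fc_lean_p1, block$log2fc_p2_p1))
  q <- rep(NA_real_, nrow(block))
  fams <- if (family == "class") rd$ion_class else rep("all", nrow(block))
  for (f in unique(fams)) {
    idx <- fams == f
    q[idx] <- benjaminiHochberg(block$p_anova[idx])
  }
  out <- S4Vectors::DataFrame(
    mz = rd$mz, annotation = rd$annotation, ion_class = rd$ion_class,
    block[c(paste0("mean_", glev), paste0("sem_", glev))],
    F = block$F, p_anova = block$p_anova, q = q,
    block[grep("^tukey_", colnames(block))],
    log2fc_lean_p1 = block$log2fc_lean_p1,
    log2fc_p2_p1 = block$log2fc_p2_p1,
    trend = trend, recovery_pct = block$recovery_pct,
    block[grep("^shapiro_", colnames(block))],
    levene_p = block$levene_p,
    significant = q < alpha, check.names = FALSE)
  rownames(out) <- formatMz(rd$mz)
  out
}
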