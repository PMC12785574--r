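# Reporting surfaces: volcano tables, Z-score hierarchical clustering,
# boxplot summaries and fixed-scale ion maps. Every figure has a
# data-behind-the-figure table so renderings are reproducible.

#' Volcano plot data for one pairwise contrast
#'
#' log2 fold change against -log10 p for either the healthy-vs-diabetic or
#' treated-vs-diabetic contrast. The p-value is the Tukey pairwise p by
#' default (a per-contrast volcano wants a per-contrast p), optionally the
#' omnibus ANOVA p. An ion is flagged when |log2FC| strictly exceeds
#' \code{fcThreshold} and its contrast p is strictly below
#' \code{pThreshold}.
#'
#' @param results output of \code{\link{runDifferential}}.
#' @param contrast \code{"LEAN_vs_P1"} or \code{"P2_vs_P1"}.
#' @param fcThreshold fold-change threshold (default 0.6).
#' @param pThreshold p-value threshold (default 0.05).
#' @param pSource \code{"tukey"} (default) or \code{"anova"}.
#' @return data.frame with \code{mz}, \code{annotation}, \code{log2fc},
#'   \code{p}, \code{neg_log10_p}, \code{flagged}.
#' @export
volcanoData <- function(results, contrast = c("LEAN_vs_P1", "P2_vs_P1"),
                        fcThreshold = 0.6, pThreshold = 0.05,
                        pSource = c("tukey", "anova")) {
  if (!nrow(results)) stop("empty results table")
  contrast <- match.arg(contrast)
  pSource <- match.arg(pSource)
  fc <- if (contrast == "LEAN_vs_P1") results$log2fc_lean_p1
        else results$log2fc_p2_p1
  p <- if (pSource == "anova") results$p_anova
  else {
    col <- if (contrast == "LEAN_vs_P1") {
      grep("^tukey_(LEAN_P1|P1_LEAN)$", colnames(results), value = TRUE)
    } else grep("^tukey_(P2_P1|P1_P2)$", colnames(results), value = TRUE)
    if (!length(col))
      stop("no Tukey column found for contrast ", contrast)
    results[[col[1L]]]
  }
  data.frame(mz = results$mz, annotation = results$annotation,
             log2fc = fc, p = p, neg_log10_p = -log10(p),
             flagged = !is.na(fc) & !is.na(p) &
               abs(fc) > fcThreshold & p < pThreshold,
             stringsAsFactors = FALSE)
}

#' Z-score hierarchical clustering of ion intensities
#'
#' Each ion is standardised across samples (mean 0, sd 1), then ions and
#' samples are clustered agglomeratively on Euclidean distances with Ward
#' linkage. Zero-variance ions are dropped with a warning. With
#' \code{results} supplied, the \code{topK} ions by ascending q are used
#' (mirroring a most-significant-features heatmap).
#'
#' @param x a \linkS4class{PeakTable} or a numeric matrix (ions x samples).
#' @param topK optional number of top ions to keep (requires
#'   \code{results}).
#' @param results optional \code{\link{runDifferential}} output for the
#'   top-K selection.
#' @return List with \code{z} (Z-score matrix), \code{rowOrder},
#'   \code{colOrder} (dendrogram leaf orders), \code{rowTree},
#'   \code{colTree} (\code{hclust} objects).
#' @export
zscoreCluster <- function(x, topK = NULL, results = NULL) {
  m <- if (is(x, "PeakTable")) SummarizedExperiment::assay(x, "intensity")
       else as.matrix(x)
  if (nrow(m) < 2L || ncol(m) < 2L)
    stop("need at least 2 ions and 2 samples")
  if (!is.null(topK)) {
    if (is.null(results)) stop("'topK' selection requires 'results'")
    keep <- rownames(results)[order(results$q)][seq_len(min(topK,
                                                            nrow(results)))]
    m <- m[rownames(m) %in% keep, , drop = FALSE]
  }
  sds <- apply(m, 1L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance ion(s) dropped before Z-scoring")
    m <- m[sds > 0, , drop = FALSE]
  }
  if (nrow(m) < 2L) stop("fewer than 2 ions left after dropping")
  z <- t(scale(t(m)))
  rowTree <- stats::hclust(stats::dist(z), method = "ward.D2")
  colTree <- stats::hclust(stats::dist(t(z)), method = "ward.D2")
  list(z = z, rowOrder = rowTree$order, colOrder = colTree$order,
       rowTree = rowTree, colTree = colTree)
}

#' @describeIn ionMap per-pixel TIC-normalised intensity raster for one
#'   target ion: integrated counts in the m/z window divided by the
#'   per-pixel total ion count. With \code{scale = "fixed"} the colour
#'   range is the supplied \code{fixedRange} (shared across all images of
#'   the same ion so groups are visually comparable); with \code{"auto"}
#'   it is the raster's own range. When \code{file} is given a PNG
#'   rendering is written alongside the returned raster.
#' @param window half-width of the integration window (Th).
#' @param scale \code{"fixed"} or \code{"auto"} colour scaling.
#' @param fixedRange numeric length-2 colour range for \code{"fixed"}.
#' @param file optional PNG output path.
#' @export
setMethod("ionMap", "SpectralImage",
          function(x, mz, window = 0.05, scale = c("fixed", "auto"),
                   fixedRange = NULL, file = NULL, ...) {
  scale <- match.arg(scale)
  axis <- mzAxis(x)
  sel <- which(abs(axis - mz) <= window)
  if (!length(sel))
    stop("empty integration window: no channel within ", window,
         " Th of m/z ", mz)
  cnt <- counts(x)
  num <- apply(cnt[, , sel, drop = FALSE], c(1L, 2L), sum)
  tic <- apply(cnt, c(1L, 2L), sum)
  raster <- ifelse(tic > 0, num / tic, NA_real_)
  zlim <- if (scale == "fixed" && !is.null(fixedRange)) sort(fixedRange)
          else range(raster, na.rm = TRUE)
  if (zlim[1L] == zlim[2L]) zlim[2L] <- zlim[1L] + .Machine$double.eps
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    graphics::image(seq_len(nrow(raster)) * pixelSizeUm(x),
                    seq_len(ncol(raster)) * pixelSizeUm(x),
                    pmin(pmax(raster, zlim[1L]), zlim[2L]),
                    zlim = zlim, col = grDevices::hcl.colors(256, "viridis"),
                    xlab = "x [um]", ylab = "y [um]",
                    main = sprintf("m/z %.3f", mz), useRaster = TRUE)
    grDevices::dev.off()
  }
  list(raster = raster, zlim = zlim, mz = mz, file = file)
})

#' Boxplot summaries per ion and group
#'
#' Tukey box convention via \code{grDevices::boxplot.stats}: median,
#' hinges, whiskers at 1.5 x IQR, with points beyond the whiskers listed
#' individually; every underlying data point is also exported so plots are
#' exactly reproducible.
#'
#' @param table a \linkS4class{PeakTable}.
#' @param mzValues target ion m/z values present in the table.
#' @return List with \code{summary} (mz, group, n, median, q1, q3,
#'   whisker_low, whisker_high, n_outliers) and \code{points} (mz, group,
#'   sample_id, value, outlier).
#' @export
boxplotSummaries <- function(table, mzValues) {
  stopifnot(is(table, "PeakTable"))
  rd <- SummarizedExperiment::rowData(table)
  cd <- SummarizedExperiment::colData(table)
  a <- SummarizedExperiment::assay(table, "intensity")
  idx <- match(mzValues, rd$mz)
  if (anyNA(idx))
    stop("ion m/z ", paste(mzValues[is.na(idx)], collapse = ", "),
         " absent from the table")
  summaries <- list()
  points <- list()
  for (k in seq_along(idx)) {
    for (g in unique(cd$group)) {
      y <- a[idx[k], cd$group == g]
      bs <- grDevices::boxplot.stats(y)
      summaries[[length(summaries) + 1L]] <- data.frame(
        mz = mzValues[k], group = g, n = length(y),
        median = bs$stats[3L], q1 = bs$stats[2L], q3 = bs$stats[4L],
        whisker_low = bs$stats[1L], whisker_high = bs$stats[5L],
        n_outliers = length(bs$out), stringsAsFactors = FALSE)
      points[[length(points) + 1L]] <- data.frame(
        mz = mzValues[k], group = g,
        sample_id = cd$sample_id[cd$group == g], value = y,
        outlier = y %in% bs$out, stringsAsFactors = FALSE, row.names = NULL)
    }
  }
  list(summary = do.call(rbind, summaries), points = do.call(rbind, points))
}
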