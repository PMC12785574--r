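#' Bundled negative-ion reference panel
#'
#' Loads the bundled panel of 26 target ions: 10 lipid-related ions and 16
#' amino-acid-related ions, each with its annotation, ion class and the
#' published TIC-normalised mean relative intensity in the three study
#' groups (LEAN healthy control, P1 diabetic control, P2 metformin-treated
#' diabetic). These group means drive the synthetic study generator and
#' anchor the worked examples. Note one curiosity preserved from the source
#' panel: m/z 115.011 is annotated "Aspartic acid" yet classed with the
#' lipid family, matching the published grouping.
#'
#' @param full if \code{TRUE}, also return the published per-ion statistics
#'   (trend label, the two log2 fold changes and the q-value) alongside the
#'   panel, for cross-checking derived quantities.
#' @param path optional path to an alternative panel CSV with the same
#'   columns.
#' @return A data.frame with columns \code{mz}, \code{annotation},
#'   \code{ion_class} and one \code{mean_<group>} column per group
#'   (\code{full = TRUE} appends \code{trend}, \code{log2fc_lean_p1},
#'   \code{log2fc_p2_p1}, \code{q_value}).
#' @examples
#' ions <- referenceIons()
#' nrow(ions)                       # 26
#' sum(ions$ion_class == "lipid")   # 10
#' @export
referenceIons <- function(full = FALSE, path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_ions.csv", package = "simsDiff",
                        mustWork = TRUE)
  ions <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("mz", "annotation", "ion_class",
                "mean_LEAN", "mean_P1", "mean_P2")
  for (col in setdiff(colnames(ions), c("annotation", "ion_class", "trend")))
    ions[[col]] <- as.numeric(ions[[col]])
  missing <- setdiff(required, colnames(ions))
  if (length(missing))
    stop("corrupted reference panel: missing column(s) ",
         paste(missing, collapse = ", "))
  bad <- which(!is.finite(ions$mz) | ions$mz <= 0 | ions$mz > 911 |
               !stats::complete.cases(ions[required]))
  if (length(bad))
    stop("corrupted reference panel: invalid row for m/z ",
         paste(ions$mz[bad], collapse = ", "))
  if (!all(ions$ion_class %in% c("lipid", "amino_acid", "other")))
    stop("corrupted reference panel: unknown ion_class")
  meanCols <- grep("^mean_", colnames(ions), value = TRUE)
  if (any(ions[meanCols] < 0) || any(ions[meanCols] >= 1))
    stop("corrupted reference panel: group means must lie in [0, 1)")
  if (!full)
    ions <- ions[required]
  ions
}

#' Group-mean columns of an ion panel
#'
#' @param ions an ion panel as returned by \code{\link{referenceIons}}.
#' @param group group name.
#' @return Numeric vector of TIC-normalised mean intensities for the group.
#' @export
ionGroupMeans <- function(ions, group) {
  col <- paste0("mean_", group)
  if (!col %in% colnames(ions))
    stop("group '", group, "' absent from ion panel (ion m/z ",
         ions$mz[1L], " has no column '", col, "')")
  ions[[col]]
}
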