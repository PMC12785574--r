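# Peak-table CSV exchange format: one row per sample; the four metadata
# columns (sample_id, group, animal, replicate) first, then one column per
# ion in ascending m/z, headed "mz|annotation|ion_class". Values are
# written at 12 significant digits, so a write/read cycle is lossless at
# that precision.

metaCols <- c("sample_id", "group", "animal", "replicate")

#' Write a peak table to CSV
#'
#' @param table a \linkS4class{PeakTable}.
#' @param path output CSV path.
#' @return Invisibly, \code{path}.
#' @export
writePeakTable <- function(table, path) {
  stopifnot(is(table, "PeakTable"))
  rd <- SummarizedExperiment::rowData(table)
  cd <- SummarizedExperiment::colData(table)
  a <- SummarizedExperiment::assay(table, "intensity")
  ord <- order(rd$mz)
  header <- sprintf("%s|%s|%s", formatMz(rd$mz[ord]), rd$annotation[ord],
                    rd$ion_class[ord])
  vals <- t(a[ord, , drop = FALSE])
  out <- data.frame(as.data.frame(cd)[metaCols],
                    matrix(formatC(vals, format = "g", digits = 12),
                           nrow(vals), ncol(vals)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  colnames(out) <- c(metaCols, header)
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Read a peak table from CSV
#'
#' Accepts the format written by \code{\link{writePeakTable}}; shuffled
#' columns are restored to canonical order (metadata first, ions by
#' ascending m/z). Duplicate sample ids and non-numeric intensity cells are
#' hard errors with the offending address; ragged (truncated) files are
#' rejected.
#'
#' @param path CSV path.
#' @return A \linkS4class{PeakTable}.
#' @export
readPeakTable <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character", fill = FALSE)
  missing <- setdiff(metaCols, colnames(raw))
  if (length(missing))
    stop("peak table is missing metadata column(s): ",
         paste(missing, collapse = ", "))
  ionCols <- grep("|", setdiff(colnames(raw), metaCols), fixed = TRUE,
                  value = TRUE)
  if (!length(ionCols)) stop("no ion columns ('mz|annotation|class') found")
  if (anyDuplicated(raw$sample_id))
    stop("duplicate sample_id: ",
         raw$sample_id[duplicated(raw$sample_id)][1L])
  parts <- strsplit(ionCols, "|", fixed = TRUE)
  ions <- data.frame(
    mz = as.numeric(vapply(parts, `[`, "", 1L)),
    annotation = vapply(parts, function(p)
      paste(p[-c(1L, length(p))], collapse = "|"), ""),
    ion_class = vapply(parts, function(p) p[[length(p)]], ""),
    stringsAsFactors = FALSE)
  if (anyNA(ions$mz))
    stop("unparseable ion column header: ", ionCols[is.na(ions$mz)][1L])
  vals <- matrix(NA_real_, nrow(raw), length(ionCols))
  for (j in seq_along(ionCols)) {
    v <- suppressWarnings(as.numeric(raw[[ionCols[j]]]))
    bad <- which(is.na(v) & !raw[[ionCols[j]]] %in% c("NA", ""))
    if (length(bad))
      stop(sprintf("non-numeric intensity at row %d, column '%s'",
                   bad[1L], ionCols[j]))
    if (anyNA(v))
      stop(sprintf("missing intensity at row %d, column '%s'",
                   which(is.na(v))[1L], ionCols[j]))
    vals[, j] <- v
  }
  samples <- raw[metaCols]
  samples$replicate <- suppressWarnings(as.integer(samples$replicate))
  ord <- order(ions$mz)
  PeakTable(t(vals[, ord, drop = FALSE]), ions[ord, , drop = FALSE], samples)
}

#' Average technical replicates to animal level
#'
#' Technical replicates are pseudoreplicates: statistics downstream run on
#' animal-level values, so the replicate rows of each animal are averaged
#' (arithmetic mean) into a single row. The alternative policy
#' \code{"pool"} keeps every replicate as its own observation.
#'
#' @param table a \linkS4class{PeakTable} at replicate level.
#' @param policy \code{"average"} (default) or \code{"pool"} (returns the
#'   input unchanged).
#' @return A \linkS4class{PeakTable} with one column per animal.
#' @export
aggregateReplicates <- function(table, policy = c("average", "pool")) {
  stopifnot(is(table, "PeakTable"))
  policy <- match.arg(policy)
  if (policy == "pool")
    return(table)
  cd <- SummarizedExperiment::colData(table)
  byAnimal <- split(seq_len(ncol(table)), cd$animal)
  groupOf <- vapply(byAnimal, function(idx) {
    g <- unique(cd$group[idx])
    if (length(g) > 1L)
      stop("animal '", cd$animal[idx[1L]], "' spans groups: ",
           paste(g, collapse = ", "))
    g
  }, "")
  # keep first-appearance order of animals
  animals <- unique(as.character(cd$animal))
  a <- SummarizedExperiment::assay(table, "intensity")
  m <- vapply(animals, function(an)
    rowMeans(a[, byAnimal[[an]], drop = FALSE]), numeric(nrow(a)))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  samples <- data.frame(sample_id = animals, group = groupOf[animals],
                        animal = animals, replicate = NA_integer_,
                        stringsAsFactors = FALSE)
  out <- PeakTable(m, as.data.frame(SummarizedExperiment::rowData(table)),
                   samples)
  S4Vectors::metadata(out) <- S4Vectors::metadata(table)
  out
}
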