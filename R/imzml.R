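# Continuous-mode imzML input/output.
#
# imzML stores spectra as an XML index (*.imzML) plus an external binary
# blob (*.ibd): 16 UUID bytes, then the shared m/z axis, then one
# intensity vector per pixel, addressed by byte offsets recorded in the
# XML. Only continuous mode on a full rectangular grid is supported;
# processed-mode files are rejected.

ibdPath <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write a SpectralImage as continuous-mode imzML
#'
#' Produces an \code{.imzML}/\code{.ibd} pair readable by standard imzML
#' parsers. Both the m/z axis and intensities are stored as uncompressed
#' little-endian 64-bit floats; the UUID is derived from the payload MD5 so
#' identical images yield byte-identical files.
#'
#' @param image a \linkS4class{SpectralImage}.
#' @param path output path ending in \code{.imzML}; the \code{.ibd} file is
#'   written alongside.
#' @return Invisibly, \code{path}.
#' @export
writeImzML <- function(image, path) {
  stopifnot(is(image, "SpectralImage"))
  d <- dim(counts(image))
  w <- d[1L]; h <- d[2L]; nch <- d[3L]
  if (nch < 1L) stop("cannot write an image with zero m/z channels")
  mz <- mzAxis(image)

  payload <- tempfile(fileext = ".bin")
  con <- file(payload, "wb")
  writeBin(mz, con, size = 8L, endian = "little")
  cnt <- counts(image)
  for (y in seq_len(h))
    for (x in seq_len(w))
      writeBin(as.numeric(cnt[x, y, ]), con, size = 8L, endian = "little")
  close(con)
  md5 <- unname(tools::md5sum(payload))
  uuidRaw <- as.raw(strtoi(substring(md5, seq(1, 31, 2), seq(2, 32, 2)),
                           base = 16L))
  ibd <- ibdPath(path)
  con <- file(ibd, "wb")
  writeBin(uuidRaw, con)
  writeBin(readBin(payload, "raw", file.info(payload)$size), con)
  close(con)
  unlink(payload)
  uuid <- toupper(sprintf("{%s-%s-%s-%s-%s}", substr(md5, 1, 8),
                          substr(md5, 9, 12), substr(md5, 13, 16),
                          substr(md5, 17, 20), substr(md5, 21, 32)))

  mzLen <- nch * 8L
  mzOff <- 16L
  specXml <- character(w * h)
  i <- 0L
  for (y in seq_len(h)) {
    for (x in seq_len(w)) {
      i <- i + 1L
      intOff <- 16 + mzLen + (i - 1) * mzLen
      specXml[i] <- sprintf(
'      <spectrum defaultArrayLength="0" id="spectrum=%d" index="%d">
        <referenceableParamGroupRef ref="spectrum1"/>
        <scanList count="1">
          <cvParam accession="MS:1000795" cvRef="MS" name="no combination"/>
          <scan instrumentConfigurationRef="IC1">
            <referenceableParamGroupRef ref="scan1"/>
            <cvParam accession="IMS:1000050" cvRef="IMS" name="position x" value="%d"/>
            <cvParam accession="IMS:1000051" cvRef="IMS" name="position y" value="%d"/>
          </scan>
        </scanList>
        <binaryDataArrayList count="2">
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="mzArray"/>
            <cvParam accession="IMS:1000103" cvRef="IMS" name="external array length" value="%d"/>
            <cvParam accession="IMS:1000104" cvRef="IMS" name="external encoded length" value="%d"/>
            <cvParam accession="IMS:1000102" cvRef="IMS" name="external offset" value="%d"/>
            <binary/>
          </binaryDataArray>
          <binaryDataArray encodedLength="0">
            <referenceableParamGroupRef ref="intensityArray"/>
            <cvParam accession="IMS:1000103" cvRef="IMS" name="external array length" value="%d"/>
            <cvParam accession="IMS:1000104" cvRef="IMS" name="external encoded length" value="%d"/>
            <cvParam accession="IMS:1000102" cvRef="IMS" name="external offset" value="%.0f"/>
            <binary/>
          </binaryDataArray>
        </binaryDataArrayList>
      </spectrum>', i, i, x, y, nch, mzLen, mzOff, nch, mzLen, intOff)
    }
  }

  polCv <- if (polarity(image) == "negative")
    '<cvParam cvRef="MS" accession="MS:1000129" name="negative scan" value=""/>'
  else
    '<cvParam cvRef="MS" accession="MS:1000130" name="positive scan" value=""/>'

  xml <- sprintf(
'<?xml version="1.0" encoding="ISO-8859-1"?>
<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">
  <cvList count="2">
    <cv uri="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" id="MS" version="3.65.0"/>
    <cv uri="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo" fullName="Imaging MS Ontology" id="IMS" version="0.9.1"/>
  </cvList>
  <fileDescription>
    <fileContent>
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000030" name="continuous" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="%s"/>
      <cvParam cvRef="IMS" accession="IMS:1000090" name="ibd MD5" value="%s"/>
    </fileContent>
  </fileDescription>
  <referenceableParamGroupList count="4">
    <referenceableParamGroup id="mzArray">
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="intensityArray">
      <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>
      <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>
      <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>
      <cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="scan1">
      <cvParam cvRef="MS" accession="MS:1000093" name="increasing m/z scan"/>
    </referenceableParamGroup>
    <referenceableParamGroup id="spectrum1">
      <cvParam cvRef="MS" accession="MS:1000579" name="MS1 spectrum" value=""/>
      %s
    </referenceableParamGroup>
  </referenceableParamGroupList>
  <softwareList count="1">
    <software id="simsDiff" version="0.99">
      <cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="simsDiff imzML export"/>
    </software>
  </softwareList>
  <scanSettingsList count="1">
    <scanSettings id="scanSettings1">
      <cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>
      <cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size (x)" value="%.12g"/>
      <cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size (y)" value="%.12g"/>
    </scanSettings>
  </scanSettingsList>
  <instrumentConfigurationList count="1">
    <instrumentConfiguration id="IC1">
    </instrumentConfiguration>
  </instrumentConfigurationList>
  <dataProcessingList count="1">
    <dataProcessing id="export">
      <processingMethod order="0" softwareRef="simsDiff">
        <cvParam cvRef="MS" accession="MS:1000530" name="file format conversion" value="Output to imzML"/>
      </processingMethod>
    </dataProcessing>
  </dataProcessingList>
  <run defaultInstrumentConfigurationRef="IC1" id="%s">
    <spectrumList count="%d" defaultDataProcessingRef="export">
%s
    </spectrumList>
  </run>
</mzML>
', uuid, toupper(md5), polCv, w, h, pixelSizeUm(image), pixelSizeUm(image),
   tools::file_path_sans_ext(basename(path)), w * h,
   paste(specXml, collapse = "\n"))
  writeLines(xml, path, sep = "")
  invisible(path)
}

cvValue <- function(node, accession) {
  v <- xml2::xml_attr(xml2::xml_find_first(node, sprintf(
    ".//*[local-name()='cvParam'][@accession='%s']", accession)), "value")
  v
}

hasCv <- function(node, accession) {
  length(xml2::xml_find_all(node, sprintf(
    ".//*[local-name()='cvParam'][@accession='%s']", accession))) > 0
}

# byte width of one value in a binary array group: 64-bit or 32-bit float
groupPrecision <- function(group, what) {
  if (hasCv(group, "MS:1000523")) 8L
  else if (hasCv(group, "MS:1000521")) 4L
  else stop("unsupported ", what, " precision (need 32- or 64-bit float)")
}

#' Read a continuous-mode imzML file
#'
#' Counterpart of \code{\link{writeImzML}}; also reads files produced by
#' other continuous-mode imzML writers. The full rectangular pixel grid is
#' required: a missing coordinate is an error naming the pixel.
#'
#' @param path path to the \code{.imzML} file (the \code{.ibd} must sit
#'   alongside).
#' @param pixelSizeUm override for the physical pixel size; by default the
#'   value stored in the file is used, or 1 um when absent.
#' @return A \linkS4class{SpectralImage}.
#' @export
readImzML <- function(path, pixelSizeUm = NULL) {
  doc <- xml2::read_xml(path)
  fc <- xml2::xml_find_first(doc, ".//*[local-name()='fileContent']")
  if (hasCv(fc, "IMS:1000031"))
    stop("processed-mode imzML is not supported (continuous mode required)")
  groups <- xml2::xml_find_all(doc,
    ".//*[local-name()='referenceableParamGroup']")
  ids <- xml2::xml_attr(groups, "id")
  mzGroupId <- ids[vapply(groups, hasCv, logical(1), "MS:1000514")]
  intGroupId <- ids[vapply(groups, hasCv, logical(1), "MS:1000515")]
  if (!length(mzGroupId) || !length(intGroupId))
    stop("could not identify m/z and intensity binary array groups")
  mzGroup <- groups[[match(mzGroupId[1L], ids)]]
  intGroup <- groups[[match(intGroupId[1L], ids)]]
  for (g in list(mzGroup, intGroup))
    if (hasCv(g, "MS:1000574") || hasCv(g, "MS:1000572"))
      stop("compressed binary arrays are not supported")
  mzBytes <- groupPrecision(mzGroup, "m/z array")
  intBytes <- groupPrecision(intGroup, "intensity array")

  negative <- length(xml2::xml_find_all(doc,
    ".//*[local-name()='cvParam'][@accession='MS:1000130']")) == 0

  if (is.null(pixelSizeUm)) {
    px <- xml2::xml_attr(xml2::xml_find_first(doc,
      ".//*[local-name()='cvParam'][@accession='IMS:1000046']"), "value")
    pixelSizeUm <- if (is.na(px)) 1 else as.numeric(px)
  }

  spectra <- xml2::xml_find_all(doc, ".//*[local-name()='spectrum']")
  if (!length(spectra)) stop("no spectra found in ", path)
  n <- length(spectra)
  posX <- posY <- integer(n)
  intOff <- numeric(n)
  intLen <- integer(n)
  mzOff <- NA_real_
  mzLen <- NA_integer_
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    posX[i] <- as.integer(cvValue(sp, "IMS:1000050"))
    posY[i] <- as.integer(cvValue(sp, "IMS:1000051"))
    arrays <- xml2::xml_find_all(sp, ".//*[local-name()='binaryDataArray']")
    for (arr in arrays) {
      ref <- xml2::xml_attr(xml2::xml_find_first(arr,
        ".//*[local-name()='referenceableParamGroupRef']"), "ref")
      isMz <- if (!is.na(ref)) ref == mzGroupId[1L] else hasCv(arr, "MS:1000514")
      off <- as.numeric(cvValue(arr, "IMS:1000102"))
      len <- as.integer(cvValue(arr, "IMS:1000103"))
      if (isMz) {
        if (is.na(mzOff)) { mzOff <- off; mzLen <- len }
        else if (len != mzLen)
          stop("inconsistent m/z array length: not continuous mode")
      } else {
        intOff[i] <- off
        intLen[i] <- len
      }
    }
  }
  if (anyNA(posX) || anyNA(posY))
    stop("spectrum without pixel coordinates")
  w <- max(posX); h <- max(posY)
  filled <- matrix(FALSE, w, h)
  filled[cbind(posX, posY)] <- TRUE
  if (!all(filled)) {
    miss <- which(!filled, arr.ind = TRUE)[1L, ]
    stop(sprintf("missing coordinate for pixel (x=%d, y=%d): grid is not rectangular",
                 miss[1L], miss[2L]))
  }
  if (n != w * h) stop("duplicate pixel coordinates in ", path)

  ibd <- ibdPath(path)
  if (!file.exists(ibd)) stop("binary data file not found: ", ibd)
  ibdSize <- file.info(ibd)$size
  need <- max(mzOff + as.numeric(mzLen) * mzBytes,
              max(intOff + as.numeric(intLen) * intBytes))
  if (ibdSize < need)
    stop("truncated .ibd file: expected at least ", need, " bytes, found ",
         ibdSize)

  con <- file(ibd, "rb")
  on.exit(close(con))
  seek(con, mzOff)
  mz <- readBin(con, "numeric", n = mzLen, size = mzBytes, endian = "little")
  arr <- array(0, dim = c(w, h, mzLen))
  for (i in seq_len(n)) {
    seek(con, intOff[i])
    arr[posX[i], posY[i], ] <- readBin(con, "numeric", n = intLen[i],
                                       size = intBytes, endian = "little")
  }
  SpectralImage(arr, mz = mz, pixelSizeUm = pixelSizeUm,
                polarity = if (negative) "negative" else "positive",
                metadata = list(source = path))
}
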