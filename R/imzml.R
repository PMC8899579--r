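# imzML I/O: the imaging MS exchange format, an mzML-dialect XML file paired
# with a binary .ibd file (16-byte UUID header, then raw IEEE-754 arrays
# addressed by external offsets from the XML). Continuous mode stores one
# shared m/z axis; processed mode stores one per spectrum. Only uncompressed
# 32/64-bit float arrays are supported, which covers peak-reduced data.

ibd_path_for <- function(path) sub("\\.imzml$", ".ibd", path, ignore.case = TRUE)

# deterministic pseudo-UUID derived from the dataset content
dataset_uuid <- function(ds) {
  set.seed(split_seed(round(sum(ds$intensities)) %% 1000003 +
                        nrow(ds$coords), "ibd-uuid"))
  bytes <- sample(0:255, 16, replace = TRUE)
  hx <- paste(sprintf("%02x", bytes), collapse = "")
  sprintf("%s-%s-%s-%s-%s", substr(hx, 1, 8), substr(hx, 9, 12),
          substr(hx, 13, 16), substr(hx, 17, 20), substr(hx, 21, 32))
}

#' Write an MSI dataset as imzML
#'
#' Emits an imzML XML file plus the binary `.ibd` companion next to it.
#' In continuous mode the shared m/z axis is stored once; in processed mode
#' each spectrum carries its own copy (the axes are identical here, but the
#' file is a valid processed-mode imzML as emitted by peak-picking tools).
#'
#' @param ds an `msi_dataset`
#' @param path output path ending in `.imzML`
#' @param mode `"continuous"` or `"processed"`
#' @return `path`, invisibly
#' @export
write_imzml <- function(ds, path, mode = c("continuous", "processed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ds, "msi_dataset"))
  ibd <- ibd_path_for(path)
  np <- length(ds$mz)
  n <- nrow(ds$intensities)
  uuid <- dataset_uuid(ds)

  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(strtoi(substring(gsub("-", "", uuid),
                                   seq(1, 31, 2), seq(2, 32, 2)), 16L)), con)
  offset <- 16
  if (mode == "continuous") {
    writeBin(ds$mz, con, size = 8, endian = "little")
    mz_offsets <- rep(offset, n)
    offset <- offset + 8 * np
  } else {
    mz_offsets <- offset + (seq_len(n) - 1) * 2 * 8 * np
  }
  int_offsets <- numeric(n)
  for (i in seq_len(n)) {
    if (mode == "processed") {
      writeBin(ds$mz, con, size = 8, endian = "little")
      offset <- offset + 8 * np
    }
    writeBin(as.numeric(ds$intensities[i, ]), con, size = 8, endian = "little")
    int_offsets[i] <- offset
    offset <- offset + 8 * np
  }

  mode_acc <- if (mode == "continuous") "IMS:1000030" else "IMS:1000031"
  hdr <- c(
    '<?xml version="1.0" encoding="ISO-8859-1"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="3">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    sprintf('<cvParam cvRef="IMS" accession="%s" name="%s" value=""/>',
            mode_acc, mode),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000080" name="universally unique identifier" value="{%s}"/>', uuid),
    '<cvParam cvRef="MS" accession="MS:1000294" name="mass spectrum" value=""/>',
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    '<cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value="" unitCvRef="MS" unitAccession="MS:1000040" unitName="m/z"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    '<cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value="" unitCvRef="MS" unitAccession="MS:1000131" unitName="number of detector counts"/>',
    '<cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
    '<cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
    '<cvParam cvRef="IMS" accession="IMS:1000101" name="external data" value="true"/>',
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<softwareList count="1"><software id="msifuse" version="0.1.0"><cvParam cvRef="MS" accession="MS:1000799" name="custom unreleased software tool" value="msifuse"/></software></softwareList>',
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000042" name="max count of pixels x" value="%d"/>', ds$nx),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000043" name="max count of pixels y" value="%d"/>', ds$ny),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000046" name="pixel size x" value="%g"/>', ds$pixel_size[1]),
    sprintf('<cvParam cvRef="IMS" accession="IMS:1000047" name="pixel size y" value="%g"/>', ds$pixel_size[2]),
    '</scanSettings></scanSettingsList>',
    '<instrumentConfigurationList count="1"><instrumentConfiguration id="IC1"/></instrumentConfigurationList>',
    '<dataProcessingList count="1"><dataProcessing id="export"><processingMethod order="1" softwareRef="msifuse"><cvParam cvRef="MS" accession="MS:1000544" name="Conversion to mzML" value=""/></processingMethod></dataProcessing></dataProcessingList>',
    sprintf('<run id="run1" defaultInstrumentConfigurationRef="IC1"><spectrumList count="%d" defaultDataProcessingRef="export">', n)
  )

  spec <- sprintf(paste0(
    '<spectrum id="spectrum=%d" defaultArrayLength="%d" index="%d">',
    '<scanList count="1"><cvParam cvRef="MS" accession="MS:1000795" name="no combination" value=""/>',
    '<scan><cvParam cvRef="IMS" accession="IMS:1000050" name="position x" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000051" name="position y" value="%d"/></scan></scanList>',
    '<binaryDataArrayList count="2">',
    '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="mzArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '<binaryDataArray encodedLength="0"><referenceableParamGroupRef ref="intensityArray"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000103" name="external array length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000104" name="external encoded length" value="%d"/>',
    '<cvParam cvRef="IMS" accession="IMS:1000102" name="external offset" value="%.0f"/>',
    '<binary/></binaryDataArray>',
    '</binaryDataArrayList></spectrum>'),
    seq_len(n), np, seq_len(n) - 1L,
    ds$coords[, 1] + 1L, ds$coords[, 2] + 1L,
    np, 8 * np, mz_offsets,
    np, 8 * np, int_offsets)

  writeLines(c(hdr, spec, '</spectrumList></run></mzML>'), path)
  invisible(path)
}

#' Read an imzML file into an `msi_dataset`
#'
#' Supports continuous- and processed-mode files with uncompressed 32- or
#' 64-bit float arrays. Processed-mode spectra must share a common peak list
#' (peak-reduced data), since the dataset container carries a single m/z axis.
#'
#' @param path path to the `.imzML` file (the `.ibd` must sit next to it)
#' @param pixel_size fallback pixel size (um) if absent from the metadata
#' @return an `msi_dataset`
#' @export
read_imzml <- function(path, pixel_size = c(50, 75)) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  cv_val <- function(node, acc) {
    n <- xml2::xml_find_first(node, sprintf(".//cvParam[@accession='%s']", acc))
    xml2::xml_attr(n, "value")
  }
  mode <- if (!is.na(xml2::xml_attr(xml2::xml_find_first(
    doc, "//fileContent/cvParam[@accession='IMS:1000030']"), "name")))
    "continuous" else "processed"

  prec_for <- function(group_id) {
    g <- xml2::xml_find_first(doc, sprintf(
      "//referenceableParamGroup[@id='%s']", group_id))
    if (!is.na(xml2::xml_attr(xml2::xml_find_first(
      g, ".//cvParam[@accession='MS:1000521']"), "name"))) 4L else 8L
  }
  mz_size <- prec_for("mzArray"); int_size <- prec_for("intensityArray")

  psx <- suppressWarnings(as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, "//scanSettings/cvParam[@accession='IMS:1000046']"), "value")))
  psy <- suppressWarnings(as.numeric(xml2::xml_attr(xml2::xml_find_first(
    doc, "//scanSettings/cvParam[@accession='IMS:1000047']"), "value")))
  if (!is.na(psx) && !is.na(psy)) pixel_size <- c(psx, psy)

  spectra <- xml2::xml_find_all(doc, "//spectrum")
  n <- length(spectra)
  if (n == 0) stop("malformed imzML: no spectra found")
  grab <- function(xpath) {
    v <- xml2::xml_attr(xml2::xml_find_all(doc, xpath), "value")
    suppressWarnings(as.numeric(v))
  }
  px <- grab("//spectrum//scan/cvParam[@accession='IMS:1000050']")
  py <- grab("//spectrum//scan/cvParam[@accession='IMS:1000051']")
  mz_off <- grab("//binaryDataArray[referenceableParamGroupRef/@ref='mzArray']/cvParam[@accession='IMS:1000102']")
  mz_len <- grab("//binaryDataArray[referenceableParamGroupRef/@ref='mzArray']/cvParam[@accession='IMS:1000103']")
  it_off <- grab("//binaryDataArray[referenceableParamGroupRef/@ref='intensityArray']/cvParam[@accession='IMS:1000102']")
  it_len <- grab("//binaryDataArray[referenceableParamGroupRef/@ref='intensityArray']/cvParam[@accession='IMS:1000103']")
  lens <- vapply(list(px, py, mz_off, mz_len, it_off, it_len), length, 0L)
  if (any(lens != n) || anyNA(c(px, py, mz_off, mz_len, it_off, it_len))) {
    for (i in seq_len(n)) {
      s <- spectra[[i]]
      vals <- c(cv_val(s, "IMS:1000050"), cv_val(s, "IMS:1000051"))
      if (anyNA(vals) || anyNA(suppressWarnings(as.numeric(vals))))
        stop("malformed imzML: missing/invalid scan position in spectrum ", i)
      if (length(xml2::xml_find_all(s, ".//binaryDataArray")) != 2)
        stop("malformed imzML: spectrum ", i, " lacks m/z or intensity array")
    }
    stop("malformed imzML: inconsistent spectrum metadata")
  }
  if (anyDuplicated(paste(px, py)))
    stop("malformed imzML: duplicate pixel coordinate at spectrum ",
         which(duplicated(paste(px, py)))[1])

  raw_ibd <- readBin(ibd_path_for(path), "raw",
                     n = file.info(ibd_path_for(path))$size)
  read_arr <- function(off, len, size) {
    readBin(raw_ibd[(off + 1):(off + len * size)], "double",
            n = len, size = size, endian = "little")
  }
  mz <- read_arr(mz_off[1], mz_len[1], mz_size)
  if (mode == "processed") {
    for (i in seq_len(n)[-1]) {
      mzi <- read_arr(mz_off[i], mz_len[i], mz_size)
      if (length(mzi) != length(mz) || any(abs(mzi - mz) > 1e-9))
        stop("processed-mode spectra must share a common peak list (spectrum ",
             i, " differs); re-bin before loading")
    }
  }
  ints <- matrix(0, n, length(mz))
  for (i in seq_len(n)) ints[i, ] <- read_arr(it_off[i], it_len[i], int_size)
  msi_dataset(mz = mz, intensities = ints,
              coords = cbind(px - 1L, py - 1L),
              pixel_size = pixel_size)
}
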