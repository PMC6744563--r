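# imzML 1.1 reader/writer, processed mode: one XML file plus an .ibd binary
# with a 16-byte identifier header followed by per-spectrum m/z (64-bit
# float) and intensity (32-bit float) arrays, little-endian. Coordinates are
# 1-based in the file and converted to the package's 0-based convention at
# the boundary.

MZML_NS <- "http://psi.hupo.org/ms/mzml"

ibd_path_for <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

#' Write a dataset to imzML (processed mode)
#'
#' Writes `<path>` (XML) and the sibling `.ibd` binary. m/z values are
#' stored as 64-bit floats, intensities as 32-bit floats, uncompressed. The
#' 16-byte ibd identifier is derived from the MD5 of the binary payload, so
#' identical datasets produce byte-identical files.
#'
#' @param dataset an `ims_dataset`.
#' @param path output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  stopifnot(inherits(dataset, "ims_dataset"))
  if (!grepl("\\.imzML$", path, ignore.case = TRUE)) {
    stopf("imzML path must end in .imzML")
  }
  ibd_path <- ibd_path_for(path)

  # binary payload and per-spectrum offsets (offsets include the 16-byte
  # identifier header, as required by the format)
  payload <- raw(0)
  chunks <- vector("list", length(dataset$spectra))
  offs <- matrix(0, nrow = length(dataset$spectra), ncol = 2)  # mz, int
  lens <- integer(length(dataset$spectra))
  pos <- 16L
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    n <- length(s$mz)
    lens[i] <- n
    mz_raw <- writeBin(as.numeric(s$mz), raw(), size = 8, endian = "little")
    int_raw <- writeBin(as.numeric(s$intensity), raw(), size = 4,
                        endian = "little")
    offs[i, 1] <- pos
    offs[i, 2] <- pos + length(mz_raw)
    pos <- pos + length(mz_raw) + length(int_raw)
    chunks[[i]] <- c(mz_raw, int_raw)
  }
  payload <- do.call(c, c(list(raw(0)), chunks))

  # content-derived 16-byte identifier
  tmp <- tempfile()
  on.exit(unlink(tmp), add = TRUE)
  writeBin(payload, tmp)
  md5 <- tools::md5sum(tmp)[[1]]
  uuid_bytes <- as.raw(strtoi(substring(md5, seq(1, 31, 2), seq(2, 32, 2)),
                              base = 16L))
  uuid_str <- paste0("{", substr(md5, 1, 8), "-", substr(md5, 9, 12), "-",
                     substr(md5, 13, 16), "-", substr(md5, 17, 20), "-",
                     substr(md5, 21, 32), "}")

  con <- file(ibd_path, "wb")
  writeBin(uuid_bytes, con)
  writeBin(payload, con)
  close(con)

  cv <- function(parent, acc, name, value = "", cvref = "MS") {
    xml2::xml_add_child(parent, "cvParam", cvRef = cvref, accession = acc,
                        name = name, value = as.character(value))
  }

  doc <- xml2::xml_new_root("mzML", xmlns = MZML_NS, version = "1.1")
  cvl <- xml2::xml_add_child(doc, "cvList", count = "3")
  xml2::xml_add_child(cvl, "cv", id = "MS", fullName = "Proteomics Standards Initiative Mass Spectrometry Ontology", URI = "https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo")
  xml2::xml_add_child(cvl, "cv", id = "UO", fullName = "Unit Ontology", URI = "https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo")
  xml2::xml_add_child(cvl, "cv", id = "IMS", fullName = "Imaging MS Ontology", URI = "https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo")

  fd <- xml2::xml_add_child(doc, "fileDescription")
  fc <- xml2::xml_add_child(fd, "fileContent")
  cv(fc, "MS:1000579", "MS1 spectrum")
  cv(fc, "IMS:1000031", "processed", cvref = "IMS")
  cv(fc, "IMS:1000080", "universally unique identifier", uuid_str, cvref = "IMS")
  xml2::xml_add_child(fc, "userParam", name = "mz_range_lo",
                      value = as.character(dataset$mz_range[1]))
  xml2::xml_add_child(fc, "userParam", name = "mz_range_hi",
                      value = as.character(dataset$mz_range[2]))

  rpgl <- xml2::xml_add_child(doc, "referenceableParamGroupList", count = "2")
  g1 <- xml2::xml_add_child(rpgl, "referenceableParamGroup", id = "mzArray")
  cv(g1, "MS:1000514", "m/z array")
  cv(g1, "MS:1000523", "64-bit float")
  cv(g1, "MS:1000576", "no compression")
  cv(g1, "IMS:1000101", "external data", "true", cvref = "IMS")
  g2 <- xml2::xml_add_child(rpgl, "referenceableParamGroup",
                            id = "intensityArray")
  cv(g2, "MS:1000515", "intensity array")
  cv(g2, "MS:1000521", "32-bit float")
  cv(g2, "MS:1000576", "no compression")
  cv(g2, "IMS:1000101", "external data", "true", cvref = "IMS")

  swl <- xml2::xml_add_child(doc, "softwareList", count = "1")
  xml2::xml_add_child(swl, "software", id = "msiclust", version = "0.1.0")

  ssl <- xml2::xml_add_child(doc, "scanSettingsList", count = "1")
  ss <- xml2::xml_add_child(ssl, "scanSettings", id = "scanSettings1")
  cv(ss, "IMS:1000042", "max count of pixels x", dataset$dims[1], cvref = "IMS")
  cv(ss, "IMS:1000043", "max count of pixels y", dataset$dims[2], cvref = "IMS")
  cv(ss, "IMS:1000046", "pixel size (x)", dataset$raster, cvref = "IMS")
  xml2::xml_add_child(ss, "userParam", name = "raster_um",
                      value = as.character(dataset$raster))

  icl <- xml2::xml_add_child(doc, "instrumentConfigurationList", count = "1")
  ic <- xml2::xml_add_child(icl, "instrumentConfiguration", id = "IC1")

  run <- xml2::xml_add_child(doc, "run", id = "run1",
                             defaultInstrumentConfigurationRef = "IC1")
  sl <- xml2::xml_add_child(run, "spectrumList",
                            count = as.character(length(dataset$spectra)))
  for (i in seq_along(dataset$spectra)) {
    s <- dataset$spectra[[i]]
    sp <- xml2::xml_add_child(sl, "spectrum", id = sprintf("spectrum=%d", i),
                              index = as.character(i - 1),
                              defaultArrayLength = as.character(lens[i]))
    scl <- xml2::xml_add_child(sp, "scanList", count = "1")
    sc <- xml2::xml_add_child(scl, "scan")
    cv(sc, "IMS:1000050", "position x", s$coord[1] + 1L, cvref = "IMS")
    cv(sc, "IMS:1000051", "position y", s$coord[2] + 1L, cvref = "IMS")
    bal <- xml2::xml_add_child(sp, "binaryDataArrayList", count = "2")

    b1 <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(b1, "referenceableParamGroupRef", ref = "mzArray")
    cv(b1, "IMS:1000102", "external offset", offs[i, 1], cvref = "IMS")
    cv(b1, "IMS:1000103", "external array length", lens[i], cvref = "IMS")
    cv(b1, "IMS:1000104", "external encoded length", lens[i] * 8L,
       cvref = "IMS")
    xml2::xml_add_child(b1, "binary")

    b2 <- xml2::xml_add_child(bal, "binaryDataArray", encodedLength = "0")
    xml2::xml_add_child(b2, "referenceableParamGroupRef",
                        ref = "intensityArray")
    cv(b2, "IMS:1000102", "external offset", offs[i, 2], cvref = "IMS")
    cv(b2, "IMS:1000103", "external array length", lens[i], cvref = "IMS")
    cv(b2, "IMS:1000104", "external encoded length", lens[i] * 4L,
       cvref = "IMS")
    xml2::xml_add_child(b2, "binary")
  }

  xml2::write_xml(doc, path)
  invisible(path)
}

#' Read an imzML file
#'
#' Supports continuous and processed mode, 32- or 64-bit float arrays,
#' uncompressed external data.
#'
#' @param path path to the `.imzML` file; the sibling `.ibd` must exist.
#' @param mz_range optional declared m/z range override; by default taken
#'   from the file's metadata or, failing that, the data extent.
#' @return an `ims_dataset`.
#' @export
read_imzml <- function(path, mz_range = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  ibd_path <- ibd_path_for(path)
  if (!file.exists(ibd_path)) stopf("ibd binary not found: %s", ibd_path)

  doc <- xml2::read_xml(path)
  ns <- c(d = MZML_NS)

  grp_type <- function(gid) {
    g <- xml2::xml_find_first(
      doc, sprintf(".//d:referenceableParamGroup[@id='%s']", gid), ns)
    accs <- xml2::xml_attr(xml2::xml_find_all(g, "./d:cvParam", ns),
                           "accession")
    if ("MS:1000523" %in% accs) 8L else if ("MS:1000521" %in% accs) 4L
    else stopf("unsupported binary data type in group '%s'", gid)
  }

  ss <- xml2::xml_find_first(doc, ".//d:scanSettings", ns)
  get_cv <- function(node, acc) {
    p <- xml2::xml_find_first(node, sprintf("./d:cvParam[@accession='%s']", acc),
                              ns)
    if (inherits(p, "xml_missing")) NA else xml2::xml_attr(p, "value")
  }
  width <- as.integer(get_cv(ss, "IMS:1000042"))
  height <- as.integer(get_cv(ss, "IMS:1000043"))
  raster_node <- xml2::xml_find_first(ss, "./d:userParam[@name='raster_um']", ns)
  raster <- if (!inherits(raster_node, "xml_missing")) {
    as.numeric(xml2::xml_attr(raster_node, "value"))
  } else {
    r <- suppressWarnings(as.numeric(get_cv(ss, "IMS:1000046")))
    if (is.na(r)) 50 else r
  }
  if (is.null(mz_range)) {
    fc <- xml2::xml_find_first(doc, ".//d:fileContent", ns)
    lo <- xml2::xml_find_first(fc, "./d:userParam[@name='mz_range_lo']", ns)
    hi <- xml2::xml_find_first(fc, "./d:userParam[@name='mz_range_hi']", ns)
    if (!inherits(lo, "xml_missing") && !inherits(hi, "xml_missing")) {
      mz_range <- c(as.numeric(xml2::xml_attr(lo, "value")),
                    as.numeric(xml2::xml_attr(hi, "value")))
    }
  }

  ibd <- readBin(ibd_path, "raw", n = file.size(ibd_path))
  spectra_nodes <- xml2::xml_find_all(doc, ".//d:spectrum", ns)
  spectra <- vector("list", length(spectra_nodes))
  mz_lo <- Inf
  mz_hi <- -Inf
  for (i in seq_along(spectra_nodes)) {
    sp <- spectra_nodes[[i]]
    scan <- xml2::xml_find_first(sp, ".//d:scan", ns)
    px <- as.integer(get_cv(scan, "IMS:1000050")) - 1L
    py <- as.integer(get_cv(scan, "IMS:1000051")) - 1L
    arrays <- xml2::xml_find_all(sp, ".//d:binaryDataArray", ns)
    mz <- NULL
    intensity <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(arr, "./d:referenceableParamGroupRef", ns), "ref")
      off <- as.numeric(get_cv(arr, "IMS:1000102"))
      len <- as.integer(get_cv(arr, "IMS:1000103"))
      if (is.na(off) || is.na(len)) {
        stopf("spectrum %d: missing external offset/length", i)
      }
      size <- grp_type(ref)
      end <- off + len * size
      if (end > length(ibd)) {
        stopf("spectrum %d: binary data out of range (ibd truncated?)", i)
      }
      vals <- if (len > 0) {
        readBin(ibd[(off + 1):end], "double", n = len, size = size,
                endian = "little")
      } else {
        numeric(0)
      }
      if (identical(ref, "mzArray")) mz <- vals else intensity <- vals
    }
    if (is.null(mz) || is.null(intensity)) {
      stopf("spectrum %d: missing m/z or intensity array", i)
    }
    if (length(mz)) {
      mz_lo <- min(mz_lo, min(mz))
      mz_hi <- max(mz_hi, max(mz))
    }
    spectra[[i]] <- new_spectrum(mz, intensity, c(px, py))
  }
  if (is.null(mz_range)) {
    mz_range <- if (is.finite(mz_lo)) c(floor(mz_lo), ceiling(mz_hi))
                else c(0, Inf)
  }
  new_ims_dataset(spectra, dims = c(width, height), raster = raster,
                  mz_range = mz_range)
}
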