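# imzML I/O. The XML follows the imzML 1.1.0 layout: mzML-style document with
# referenceable param groups for the m/z and intensity arrays, per-spectrum
# pixel positions (IMS:1000050/51, 1-based in files, 0-based in memory), and
# external binary storage in a sibling .ibd file that starts with a 16-byte
# UUID. Continuous files share one m/z array; processed files store one axis
# per pixel. m/z is encoded as 64-bit float; intensity defaults to 32-bit
# float (common imaging practice), so profile round-trips are exact to float32
# resolution (~1e-7 relative). Pass intensity_format = "float64" for exact
# round-trips.

IMS_NS <- "http://psi.hupo.org/ms/mzml"

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

cv_ims <- function(acc, name, value = NULL) {
  sprintf('<cvParam cvRef="IMS" accession="%s" name="%s"%s/>', acc, name,
          if (is.null(value)) "" else sprintf(' value="%s"', value))
}
cv_ms <- function(acc, name, value = NULL) {
  sprintf('<cvParam cvRef="MS" accession="%s" name="%s"%s/>', acc, name,
          if (is.null(value)) "" else sprintf(' value="%s"', value))
}

# deterministic pseudo-UUID from the dataset content (md5 of serialization)
content_uuid <- function(d) {
  tf <- tempfile()
  on.exit(unlink(tf))
  saveRDS(list(d$coords, d$mz, d$section_id), tf)
  hex <- unname(tools::md5sum(tf))
  as.raw(strtoi(substring(hex, seq(1, 31, 2), seq(2, 32, 2)), 16L))
}

#' Write a dataset to imzML
#'
#' Writes `<path>.imzML` plus the external binary `<path>.ibd`. Shared-axis
#' datasets are written in the continuous dialect, per-pixel-axis datasets in
#' the processed dialect. Pixel coordinates are converted from the package's
#' 0-based convention to the format's 1-based one.
#'
#' @param d an `msi_dataset`
#' @param path output path; `.imzML` is appended when missing
#' @param intensity_format `"float32"` (default) or `"float64"`
#' @return the imzML path, invisibly
#' @export
write_imzml <- function(d, path, intensity_format = c("float32", "float64")) {
  intensity_format <- match.arg(intensity_format)
  validate_msi_dataset(d)
  if (!grepl("\\.imzML$", path, ignore.case = TRUE)) path <- paste0(path, ".imzML")
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  int_size <- if (intensity_format == "float32") 4L else 8L
  int_acc <- if (intensity_format == "float32") {
    cv_ms("MS:1000521", "32-bit float")
  } else {
    cv_ms("MS:1000523", "64-bit float")
  }
  n <- n_pixels(d)
  continuous <- d$shared_axis

  con <- file(ibd_path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(content_uuid(d), con)
  offset <- 16
  if (continuous) {
    mz_len <- length(d$mz)
    writeBin(as.double(d$mz), con, size = 8)
    mz_offsets <- rep(offset, n)
    mz_lengths <- rep(mz_len, n)
    offset <- offset + 8 * mz_len
    int_offsets <- int_lengths <- numeric(n)
    for (i in seq_len(n)) {
      writeBin(as.double(d$intensities[i, ]), con, size = int_size)
      int_offsets[i] <- offset
      int_lengths[i] <- mz_len
      offset <- offset + int_size * mz_len
    }
  } else {
    mz_offsets <- mz_lengths <- int_offsets <- int_lengths <- numeric(n)
    for (i in seq_len(n)) {
      mzi <- d$mz[[i]]
      writeBin(as.double(mzi), con, size = 8)
      mz_offsets[i] <- offset
      mz_lengths[i] <- length(mzi)
      offset <- offset + 8 * length(mzi)
      writeBin(as.double(d$intensities[[i]]), con, size = int_size)
      int_offsets[i] <- offset
      int_lengths[i] <- length(mzi)
      offset <- offset + int_size * length(mzi)
    }
  }

  spec_mode_cv <- if (d$mode == "centroid") {
    cv_ms("MS:1000127", "centroid spectrum")
  } else {
    cv_ms("MS:1000128", "profile spectrum")
  }
  dialect_cv <- if (continuous) {
    cv_ims("IMS:1000030", "continuous")
  } else {
    cv_ims("IMS:1000031", "processed")
  }
  uuid_hex <- paste(format(content_uuid(d)), collapse = "")

  spectra_xml <- vapply(seq_len(n), function(i) {
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1L, i, int_lengths[i]),
      spec_mode_cv,
      '<scanList count="1">', cv_ms("MS:1000795", "no combination"),
      "<scan>",
      cv_ims("IMS:1000050", "position x", d$coords$x[i] + 1L),
      cv_ims("IMS:1000051", "position y", d$coords$y[i] + 1L),
      "</scan></scanList>",
      '<binaryDataArrayList count="2">',
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="mzArray"/>',
      cv_ims("IMS:1000103", "external array length", mz_lengths[i]),
      cv_ims("IMS:1000104", "external encoded length", 8 * mz_lengths[i]),
      cv_ims("IMS:1000102", "external offset", sprintf("%.0f", mz_offsets[i])),
      "<binary/></binaryDataArray>",
      '<binaryDataArray encodedLength="0">',
      '<referenceableParamGroupRef ref="intensityArray"/>',
      cv_ims("IMS:1000103", "external array length", int_lengths[i]),
      cv_ims("IMS:1000104", "external encoded length", int_size * int_lengths[i]),
      cv_ims("IMS:1000102", "external offset", sprintf("%.0f", int_offsets[i])),
      "<binary/></binaryDataArray>",
      "</binaryDataArrayList></spectrum>"
    )
  }, "")

  doc <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    sprintf('<mzML xmlns="%s" version="1.1">', IMS_NS),
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="http://psidev.info/ms/mzML/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="http://www.maldi-msi.org/download/imzml/imagingMS.obo"/>',
    "</cvList>",
    "<fileDescription><fileContent>",
    cv_ims("IMS:1000080", "universally unique identifier",
           xml_escape(paste0("{", uuid_hex, "}"))),
    dialect_cv, spec_mode_cv,
    "</fileContent></fileDescription>",
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    cv_ms("MS:1000514", "m/z array"), cv_ms("MS:1000523", "64-bit float"),
    cv_ms("MS:1000576", "no compression"),
    cv_ims("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    '<referenceableParamGroup id="intensityArray">',
    cv_ms("MS:1000515", "intensity array"), int_acc,
    cv_ms("MS:1000576", "no compression"),
    cv_ims("IMS:1000101", "external data", "true"),
    "</referenceableParamGroup>",
    "</referenceableParamGroupList>",
    '<scanSettingsList count="1"><scanSettings id="scanSettings1">',
    cv_ims("IMS:1000042", "max count of pixels x", max(d$coords$x) + 1L),
    cv_ims("IMS:1000043", "max count of pixels y", max(d$coords$y) + 1L),
    cv_ims("IMS:1000046", "pixel size (x)", d$pixel_pitch),
    cv_ims("IMS:1000047", "pixel size (y)", d$pixel_pitch),
    "</scanSettings></scanSettingsList>",
    '<instrumentConfigurationList count="1">',
    '<instrumentConfiguration id="IC1"/>',
    "</instrumentConfigurationList>",
    '<dataProcessingList count="1"><dataProcessing id="dp1">',
    '<processingMethod order="1"/>',
    "</dataProcessing></dataProcessingList>",
    sprintf('<run id="%s" defaultInstrumentConfigurationRef="IC1">',
            xml_escape(d$section_id)),
    sprintf('<spectrumList count="%d" defaultDataProcessingRef="dp1">', n),
    paste(spectra_xml, collapse = ""),
    "</spectrumList></run></mzML>"
  )
  writeLines(doc, path, useBytes = TRUE)
  invisible(path)
}

imzml_cv_value <- function(node, accession, ns) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns)
  if (inherits(p, "xml_missing")) return(NULL)
  xml2::xml_attr(p, "value")
}

imzml_has_cv <- function(node, accession, ns) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns),
    "xml_missing")
}

#' Read an imzML dataset
#'
#' Supports the continuous and processed dialects with uncompressed external
#' binary data (32/64-bit float arrays). Pixel coordinates are returned
#' 0-based.
#'
#' @param path path to the `.imzML` file (`.ibd` expected alongside)
#' @param section_id,group optional metadata overrides
#' @return an `msi_dataset`
#' @export
read_imzml <- function(path, section_id = NULL, group = NA_character_) {
  if (!file.exists(path)) stop("read_imzml: no such file: ", path)
  ibd_path <- sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)
  if (!file.exists(ibd_path)) stop("read_imzml: missing binary file: ", ibd_path)
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)

  groups <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup", ns)
  if (length(groups) == 0) stop("read_imzml: malformed container: no referenceableParamGroup")
  precision_of <- function(g) {
    if (imzml_has_cv(g, "MS:1000523", ns)) 8L
    else if (imzml_has_cv(g, "MS:1000521", ns)) 4L
    else stop("read_imzml: malformed container: unknown precision in param group '",
              xml2::xml_attr(g, "id"), "'")
  }
  mz_group_id <- int_group_id <- NULL
  mz_size <- int_size <- NULL
  for (g in groups) {
    if (imzml_has_cv(g, "MS:1000514", ns)) {
      mz_group_id <- xml2::xml_attr(g, "id"); mz_size <- precision_of(g)
    }
    if (imzml_has_cv(g, "MS:1000515", ns)) {
      int_group_id <- xml2::xml_attr(g, "id"); int_size <- precision_of(g)
    }
  }
  if (is.null(mz_group_id) || is.null(int_group_id)) {
    stop("read_imzml: malformed container: m/z or intensity param group missing")
  }

  fc <- xml2::xml_find_first(doc, ".//d1:fileContent", ns)
  continuous <- imzml_has_cv(fc, "IMS:1000030", ns)
  processed <- imzml_has_cv(fc, "IMS:1000031", ns)
  if (!continuous && !processed) {
    stop("read_imzml: file declares neither continuous nor processed dialect")
  }
  mode <- if (imzml_has_cv(fc, "MS:1000127", ns)) "centroid" else "profile"

  spectra <- xml2::xml_find_all(doc, ".//d1:spectrum", ns)
  n <- length(spectra)
  if (n == 0) stop("read_imzml: malformed container: no spectra")

  xs <- ys <- integer(n)
  mz_off <- mz_len <- int_off <- int_len <- numeric(n)
  for (i in seq_len(n)) {
    sp <- spectra[[i]]
    x <- imzml_cv_value(sp, "IMS:1000050", ns)
    y <- imzml_cv_value(sp, "IMS:1000051", ns)
    if (is.null(x) || is.null(y)) {
      stop("read_imzml: malformed container: spectrum ",
           xml2::xml_attr(sp, "id"), " lacks pixel position")
    }
    xs[i] <- as.integer(x) - 1L
    ys[i] <- as.integer(y) - 1L
    arrays <- xml2::xml_find_all(sp, ".//d1:binaryDataArray", ns)
    found_mz <- found_int <- FALSE
    for (a in arrays) {
      ref <- xml2::xml_attr(
        xml2::xml_find_first(a, ".//d1:referenceableParamGroupRef", ns), "ref")
      off <- imzml_cv_value(a, "IMS:1000102", ns)
      len <- imzml_cv_value(a, "IMS:1000103", ns)
      if (is.null(off) || is.null(len)) {
        stop("read_imzml: malformed container: spectrum ",
             xml2::xml_attr(sp, "id"), " array lacks offset/length")
      }
      if (identical(ref, mz_group_id)) {
        mz_off[i] <- as.numeric(off); mz_len[i] <- as.numeric(len); found_mz <- TRUE
      } else if (identical(ref, int_group_id)) {
        int_off[i] <- as.numeric(off); int_len[i] <- as.numeric(len); found_int <- TRUE
      }
    }
    if (!found_mz || !found_int) {
      stop("read_imzml: malformed container: spectrum ",
           xml2::xml_attr(sp, "id"), " lacks m/z or intensity array")
    }
  }

  con <- file(ibd_path, "rb")
  on.exit(close(con))
  read_arr <- function(offset, length, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = "double", n = length, size = size)
  }

  if (continuous) {
    mz <- read_arr(mz_off[1], mz_len[1], mz_size)
    ints <- matrix(0, nrow = n, ncol = length(mz))
    for (i in seq_len(n)) ints[i, ] <- read_arr(int_off[i], int_len[i], int_size)
  } else {
    mz <- vector("list", n)
    ints <- vector("list", n)
    for (i in seq_len(n)) {
      mz[[i]] <- read_arr(mz_off[i], mz_len[i], mz_size)
      ints[[i]] <- read_arr(int_off[i], int_len[i], int_size)
    }
  }
  msi_dataset(
    coords = data.frame(x = xs, y = ys), mz = mz, intensities = ints,
    mode = mode,
    section_id = section_id %||% sub("\\.imzML$", "", basename(path), ignore.case = TRUE),
    group = group
  )
}
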