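## MSI dataset container and imzML 1.1.0 (+ .ibd) input/output.
##
## Coordinate convention: x is the 1-based column index, y the 1-based row
## index, as in imzML. Spectra are stored and iterated row-major by (y, x).
## m/z values are written as 64-bit floats, intensities as 32-bit floats
## (the common imzML dialect); output is always processed mode because
## peak-picked spectra have unequal axes.

#' Construct a single mass spectrum
#'
#' @param mz numeric vector of m/z values (Th), strictly ascending.
#' @param intensity numeric vector of non-negative intensities, same length.
#' @return list with elements `mz` and `intensity`, class `"mass_spectrum"`.
#' @export
mass_spectrum <- function(mz, intensity) {
  fail_if(length(mz) != length(intensity),
          "mz and intensity must have equal length")
  if (length(mz) > 1) fail_if(any(diff(mz) <= 0), "mz must be strictly ascending")
  fail_if(any(intensity < 0), "intensities must be non-negative")
  structure(list(mz = as.numeric(mz), intensity = as.numeric(intensity)),
            class = "mass_spectrum")
}

#' Construct an MSI dataset
#'
#' A pixel-indexed collection of spectra on a rectangular grid.
#'
#' @param spectra list of [mass_spectrum()] (or bare `list(mz=, intensity=)`),
#'   one per pixel, in any order.
#' @param coords data.frame with integer columns `x` (column index) and `y`
#'   (row index), 1-based, one row per spectrum.
#' @param width,height grid dimensions in pixels; default to the coordinate
#'   maxima.
#' @param mode `"processed"` (per-pixel m/z axes) or `"continuous"`.
#' @param pixel_size pixel pitch in micrometers (default 5, the acquisition
#'   step size typical for paint cross sections).
#' @return object of class `"msi_dataset"`; spectra reordered row-major by
#'   (y, x).
#' @export
msi_dataset <- function(spectra, coords, width = max(coords$x),
                        height = max(coords$y),
                        mode = c("processed", "continuous"), pixel_size = 5) {
  mode <- match.arg(mode)
  fail_if(length(spectra) != nrow(coords),
          "need one coordinate row per spectrum")
  fail_if(any(coords$x < 1) || any(coords$y < 1), "coordinates are 1-based")
  fail_if(any(coords$x > width) || any(coords$y > height),
          "coordinates outside the declared %dx%d grid", width, height)
  key <- (coords$y - 1) * width + coords$x
  fail_if(anyDuplicated(key) > 0, "duplicated pixel coordinates")
  o <- order(coords$y, coords$x)
  spectra <- lapply(spectra[o], function(s) mass_spectrum(s$mz, s$intensity))
  if (mode == "continuous" && length(spectra) > 1) {
    ax <- spectra[[1]]$mz
    same <- vapply(spectra, function(s) identical(s$mz, ax), logical(1))
    fail_if(!all(same), "continuous mode requires one shared m/z axis")
  }
  structure(list(spectra = spectra,
                 coords = data.frame(x = as.integer(coords$x[o]),
                                     y = as.integer(coords$y[o])),
                 width = as.integer(width), height = as.integer(height),
                 mode = mode, pixel_size = pixel_size),
            class = "msi_dataset")
}

#' @export
print.msi_dataset <- function(x, ...) {
  cat(sprintf("<msi_dataset> %d x %d grid, %d spectra, %s mode, %g um/px\n",
              x$width, x$height, length(x$spectra), x$mode, x$pixel_size))
  invisible(x)
}

## Per-pixel total ion count.
tic <- function(dataset) {
  vapply(dataset$spectra, function(s) sum(s$intensity), numeric(1))
}

## -- imzML writing -----------------------------------------------------------

.ibd_path <- function(path) sub("\\.imzML$", ".ibd", path, ignore.case = TRUE)

.xml_cv <- function(cv, accession, name, value = NULL) {
  v <- if (is.null(value)) "" else sprintf(' value="%s"', value)
  sprintf('<cvParam cvRef="%s" accession="%s" name="%s"%s/>', cv, accession,
          name, v)
}

#' Write an MSI dataset as imzML
#'
#' Writes `path` (the XML part) and its binary companion `.ibd`. Output is
#' always processed mode: each pixel carries its own m/z axis, m/z encoded as
#' 64-bit and intensities as 32-bit little-endian floats.
#'
#' @param dataset an [msi_dataset()].
#' @param path output path ending in `.imzML`.
#' @return `path`, invisibly.
#' @export
write_imzml <- function(dataset, path) {
  fail_if(!inherits(dataset, "msi_dataset"), "not an msi_dataset")
  fail_if(!grepl("\\.imzML$", path, ignore.case = TRUE),
          "path must end in .imzML")
  dir <- dirname(path)
  fail_if(!dir.exists(dir), "cannot write to '%s': no such directory", dir)
  ibd <- .ibd_path(path)
  ## content-derived UUID keeps written artifacts byte-reproducible
  tics <- vapply(dataset$spectra, function(s) sum(s$intensity), numeric(1))
  uuid_seed <- (length(tics) * 2654435761 +
                  floor(sum(tics %% 1e6))) %% 2147483647
  uuid <- with_seed(uuid_seed,
                    as.raw(sample.int(256L, 16L, replace = TRUE) - 1L))
  uuid_str <- paste(sprintf("%02x", as.integer(uuid)), collapse = "")

  con <- file(ibd, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(uuid, con)
  offset <- 16
  n <- length(dataset$spectra)
  entries <- vector("list", n)
  for (i in seq_len(n)) {
    s <- dataset$spectra[[i]]
    len <- length(s$mz)
    mz_off <- offset
    writeBin(as.numeric(s$mz), con, size = 8, endian = "little")
    offset <- offset + 8 * len
    int_off <- offset
    writeBin(as.numeric(s$intensity), con, size = 4, endian = "little")
    offset <- offset + 4 * len
    entries[[i]] <- list(len = len, mz_off = mz_off, int_off = int_off)
  }

  sp_xml <- vapply(seq_len(n), function(i) {
    e <- entries[[i]]
    paste0(
      sprintf('<spectrum index="%d" id="spectrum=%d" defaultArrayLength="%d">',
              i - 1, i, e$len),
      '<scanList count="1"><scan>',
      .xml_cv("IMS", "IMS:1000050", "position x", dataset$coords$x[i]),
      .xml_cv("IMS", "IMS:1000051", "position y", dataset$coords$y[i]),
      '</scan></scanList>',
      '<binaryDataArrayList count="2">',
      sprintf('<binaryDataArray encodedLength="0">%s%s%s%s<binary/></binaryDataArray>',
              '<referenceableParamGroupRef ref="mzArray"/>',
              .xml_cv("IMS", "IMS:1000103", "external array length", e$len),
              .xml_cv("IMS", "IMS:1000104", "external encoded length", 8 * e$len),
              .xml_cv("IMS", "IMS:1000102", "external offset", e$mz_off)),
      sprintf('<binaryDataArray encodedLength="0">%s%s%s%s<binary/></binaryDataArray>',
              '<referenceableParamGroupRef ref="intensityArray"/>',
              .xml_cv("IMS", "IMS:1000103", "external array length", e$len),
              .xml_cv("IMS", "IMS:1000104", "external encoded length", 4 * e$len),
              .xml_cv("IMS", "IMS:1000102", "external offset", e$int_off)),
      '</binaryDataArrayList></spectrum>')
  }, character(1))

  xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1">',
    '<cvList count="2">',
    '<cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '<cv id="IMS" fullName="Imaging MS Ontology" URI="https://raw.githubusercontent.com/imzML/imzML/master/imagingMS.obo"/>',
    '</cvList>',
    '<fileDescription><fileContent>',
    .xml_cv("IMS", "IMS:1000031", "processed"),
    .xml_cv("IMS", "IMS:1000080", "universally unique identifier",
            paste0("{", uuid_str, "}")),
    '</fileContent></fileDescription>',
    '<referenceableParamGroupList count="2">',
    '<referenceableParamGroup id="mzArray">',
    .xml_cv("MS", "MS:1000514", "m/z array"),
    .xml_cv("MS", "MS:1000523", "64-bit float"),
    .xml_cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '<referenceableParamGroup id="intensityArray">',
    .xml_cv("MS", "MS:1000515", "intensity array"),
    .xml_cv("MS", "MS:1000521", "32-bit float"),
    .xml_cv("IMS", "IMS:1000101", "external data", "true"),
    '</referenceableParamGroup>',
    '</referenceableParamGroupList>',
    '<scanSettingsList count="1"><scanSettings id="scan1">',
    .xml_cv("IMS", "IMS:1000042", "max count of pixel x", dataset$width),
    .xml_cv("IMS", "IMS:1000043", "max count of pixel y", dataset$height),
    .xml_cv("IMS", "IMS:1000046", "pixel size x", dataset$pixel_size),
    .xml_cv("IMS", "IMS:1000047", "pixel size y", dataset$pixel_size),
    '</scanSettings></scanSettingsList>',
    sprintf('<run id="run1"><spectrumList count="%d">', n),
    paste0(sp_xml, collapse = ""),
    '</spectrumList></run></mzML>\n')
  writeLines(xml, path, useBytes = TRUE)
  invisible(path)
}

## -- imzML reading -----------------------------------------------------------

.cv_value <- function(node, accession, ns) {
  p <- xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns)
  if (inherits(p, "xml_missing")) return(NA_character_)
  xml2::xml_attr(p, "value")
}

.cv_present <- function(node, accession, ns) {
  !inherits(xml2::xml_find_first(
    node, sprintf(".//d1:cvParam[@accession='%s']", accession), ns),
    "xml_missing")
}

#' Read an imzML file
#'
#' Reads an imzML 1.1.0 file and its `.ibd` companion into an
#' [msi_dataset()]. Both processed and continuous layouts are supported;
#' spectra are returned exactly as stored (no implicit centroiding).
#'
#' @param path path to the `.imzML` file.
#' @return an [msi_dataset()], pixels ordered row-major by (y, x).
#' @export
read_imzml <- function(path) {
  fail_if(!file.exists(path), "imzML file not found: %s", path)
  ibd <- .ibd_path(path)
  fail_if(!file.exists(ibd),
          "missing binary companion file: expected '%s' next to '%s'",
          ibd, basename(path))
  doc <- xml2::read_xml(path)
  ns <- xml2::xml_ns(doc)

  fc <- xml2::xml_find_first(doc, ".//d1:fileContent", ns)
  mode <- if (!inherits(fc, "xml_missing") && .cv_present(fc, "IMS:1000030", ns))
    "continuous" else "processed"

  ## referenceable param groups: which id is the m/z array?
  groups <- xml2::xml_find_all(doc, ".//d1:referenceableParamGroup", ns)
  group_kind <- setNames(vapply(groups, function(g) {
    if (.cv_present(g, "MS:1000514", ns)) "mz"
    else if (.cv_present(g, "MS:1000515", ns)) "intensity"
    else "other"
  }, character(1)), xml2::xml_attr(groups, "id"))
  group_size <- setNames(vapply(groups, function(g) {
    if (.cv_present(g, "MS:1000523", ns)) 8L
    else if (.cv_present(g, "MS:1000521", ns)) 4L else NA_integer_
  }, integer(1)), xml2::xml_attr(groups, "id"))

  sp_nodes <- xml2::xml_find_all(doc, ".//d1:spectrum", ns)
  fail_if(length(sp_nodes) == 0, "no spectra in '%s'", path)

  con <- file(ibd, "rb")
  on.exit(close(con), add = TRUE)
  read_array <- function(offset, n, size) {
    seek(con, where = offset, origin = "start")
    readBin(con, what = "numeric", n = n, size = size, endian = "little")
  }

  xs <- ys <- integer(length(sp_nodes))
  spectra <- vector("list", length(sp_nodes))
  for (i in seq_along(sp_nodes)) {
    node <- sp_nodes[[i]]
    scan <- xml2::xml_find_first(node, ".//d1:scan", ns)
    xs[i] <- as.integer(.cv_value(scan, "IMS:1000050", ns))
    ys[i] <- as.integer(.cv_value(scan, "IMS:1000051", ns))
    arrays <- xml2::xml_find_all(node, ".//d1:binaryDataArray", ns)
    mz <- intensity <- NULL
    for (arr in arrays) {
      ref <- xml2::xml_find_first(arr, ".//d1:referenceableParamGroupRef", ns)
      gid <- if (inherits(ref, "xml_missing")) NA else xml2::xml_attr(ref, "ref")
      kind <- if (!is.na(gid)) group_kind[[gid]]
        else if (.cv_present(arr, "MS:1000514", ns)) "mz"
        else if (.cv_present(arr, "MS:1000515", ns)) "intensity" else "other"
      size <- if (!is.na(gid) && !is.na(group_size[[gid]])) group_size[[gid]]
        else if (.cv_present(arr, "MS:1000523", ns)) 8L
        else if (.cv_present(arr, "MS:1000521", ns)) 4L
        else if (kind == "mz") 8L else 4L
      off <- as.numeric(.cv_value(arr, "IMS:1000102", ns))
      len <- as.integer(.cv_value(arr, "IMS:1000103", ns))
      vals <- read_array(off, len, size)
      if (kind == "mz") mz <- vals else if (kind == "intensity") intensity <- vals
    }
    fail_if(is.null(mz) || is.null(intensity),
            "spectrum %d lacks m/z or intensity array", i)
    spectra[[i]] <- list(mz = mz, intensity = intensity)
  }

  settings <- xml2::xml_find_first(doc, ".//d1:scanSettings", ns)
  width <- suppressWarnings(as.integer(.cv_value(settings, "IMS:1000042", ns)))
  height <- suppressWarnings(as.integer(.cv_value(settings, "IMS:1000043", ns)))
  px <- suppressWarnings(as.numeric(.cv_value(settings, "IMS:1000046", ns)))
  if (is.na(width)) width <- max(xs)
  if (is.na(height)) height <- max(ys)
  if (is.na(px)) px <- 1

  key <- (ys - 1) * width + xs
  fail_if(anyDuplicated(key) > 0, "imzML format error: duplicated coordinates")
  msi_dataset(spectra, data.frame(x = xs, y = ys), width = width,
              height = height, mode = mode, pixel_size = px)
}
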