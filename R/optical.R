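## Brightfield optical images: PNG and baseline uncompressed TIFF I/O.
## Rasters are height x width x 3 numeric arrays with channel values 0-255.

#' Construct an optical image
#'
#' @param raster height x width x 3 array, channel values in `[0, 255]`;
#'   a 2-channel-free (h x w) matrix is replicated across channels.
#' @param pixel_size micrometers per pixel.
#' @return object of class `"optical_image"`.
#' @export
optical_image <- function(raster, pixel_size = 5) {
  if (length(dim(raster)) == 2) {
    raster <- array(rep(raster, 3), dim = c(dim(raster), 3))
  }
  fail_if(length(dim(raster)) != 3 || dim(raster)[3] != 3,
          "raster must be height x width x 3")
  fail_if(any(raster < 0) || any(raster > 255),
          "channel values must lie in [0, 255]")
  structure(list(raster = raster, pixel_size = pixel_size),
            class = "optical_image")
}

#' @export
print.optical_image <- function(x, ...) {
  d <- dim(x$raster)
  cat(sprintf("<optical_image> %d x %d px, %g um/px\n", d[1], d[2],
              x$pixel_size))
  invisible(x)
}

## -- minimal baseline TIFF codec --------------------------------------------
## Uncompressed, little-endian, single strip, 8- or 16-bit, 1 or 3 samples.
## Hand-rolled because no TIFF package is available in the supported stack.

.tiff_tag <- function(id, type, count, value) {
  list(id = id, type = type, count = count, value = value)
}

write_tiff <- function(pixels, path, bits = 8L) {
  ## pixels: h x w (gray) or h x w x 3 integer array of raw sample values
  fail_if(!bits %in% c(8L, 16L), "bits must be 8 or 16")
  d <- dim(pixels)
  h <- d[1]; w <- d[2]; spp <- if (length(d) == 3) d[3] else 1L
  ## interleave samples row-major
  if (spp == 1) {
    samples <- as.integer(t(pixels))
  } else {
    samples <- as.integer(aperm(pixels, c(3, 2, 1)))
  }
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(charToRaw("II"), con)
  writeBin(42L, con, size = 2, endian = "little")
  data_offset <- 8L
  n_bytes <- length(samples) * (bits / 8L)
  ifd_offset <- data_offset + n_bytes
  writeBin(as.integer(ifd_offset), con, size = 4, endian = "little")
  if (bits == 8L) {
    writeBin(as.raw(samples), con)
  } else {
    writeBin(samples, con, size = 2, endian = "little")
  }
  tags <- list(
    .tiff_tag(256L, 3L, 1L, w),                      # ImageWidth
    .tiff_tag(257L, 3L, 1L, h),                      # ImageLength
    .tiff_tag(258L, 3L, spp, rep(bits, spp)),        # BitsPerSample
    .tiff_tag(259L, 3L, 1L, 1L),                     # Compression: none
    .tiff_tag(262L, 3L, 1L, if (spp == 3) 2L else 1L), # Photometric
    .tiff_tag(273L, 4L, 1L, data_offset),            # StripOffsets
    .tiff_tag(277L, 3L, 1L, spp),                    # SamplesPerPixel
    .tiff_tag(278L, 3L, 1L, h),                      # RowsPerStrip
    .tiff_tag(279L, 4L, 1L, n_bytes)                 # StripByteCounts
  )
  ## out-of-line data area (only BitsPerSample for RGB needs it)
  extra_offset <- ifd_offset + 2L + length(tags) * 12L + 4L
  extra <- list()
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) {
    writeBin(tg$id, con, size = 2, endian = "little")
    writeBin(tg$type, con, size = 2, endian = "little")
    writeBin(tg$count, con, size = 4, endian = "little")
    unit <- if (tg$type == 3L) 2L else 4L
    if (tg$count * unit <= 4L) {
      ## value fits inline, left-justified
      if (tg$type == 3L) {
        vals <- c(tg$value, rep(0L, 2L - length(tg$value)))
        writeBin(as.integer(vals), con, size = 2, endian = "little")
      } else {
        writeBin(as.integer(tg$value), con, size = 4, endian = "little")
      }
    } else {
      writeBin(as.integer(extra_offset), con, size = 4, endian = "little")
      extra <- c(extra, list(list(type = tg$type, value = tg$value)))
      extra_offset <- extra_offset + tg$count * unit
    }
  }
  writeBin(0L, con, size = 4, endian = "little") # no next IFD
  for (e in extra) {
    writeBin(as.integer(e$value), con, size = if (e$type == 3L) 2 else 4,
             endian = "little")
  }
  invisible(path)
}

read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  order_tag <- rawToChar(raw[1:2])
  fail_if(!order_tag %in% c("II", "MM"), "not a TIFF file: %s", path)
  endian <- if (order_tag == "II") "little" else "big"
  int_at <- function(off, size, n = 1L) {
    ## size-4 values are read signed (R has no unsigned 32-bit); offsets in
    ## files this codec handles stay far below 2^31.
    readBin(raw[(off + 1):(off + size * n)], "integer", n = n, size = size,
            endian = endian, signed = size == 4L)
  }
  fail_if(int_at(2, 2) != 42L, "bad TIFF magic in %s", path)
  ifd <- int_at(4, 4)
  n_tags <- int_at(ifd, 2)
  tags <- list()
  for (i in seq_len(n_tags)) {
    base <- ifd + 2 + (i - 1) * 12
    id <- int_at(base, 2); type <- int_at(base + 2, 2)
    count <- int_at(base + 4, 4)
    unit <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L, 4L)
    if (count * unit <= 4) {
      value <- int_at(base + 8, unit, count)
    } else {
      off <- int_at(base + 8, 4)
      value <- int_at(off, unit, count)
    }
    tags[[as.character(id)]] <- value
  }
  w <- tags[["256"]]; h <- tags[["257"]]
  bits <- tags[["258"]][1]
  comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
  spp <- if (is.null(tags[["277"]])) 1L else tags[["277"]]
  fail_if(comp != 1L, "unsupported TIFF compression (%d) in %s", comp, path)
  fail_if(!bits %in% c(8L, 16L),
          "unsupported TIFF bit depth (%d) in %s", bits, path)
  offs <- tags[["273"]]; counts <- tags[["279"]]
  samples <- unlist(lapply(seq_along(offs), function(i) {
    int_at(offs[i], bits / 8L, counts[i] / (bits / 8L))
  }))
  if (spp == 1) {
    px <- array(0, dim = c(h, w))
    px[] <- matrix(samples, nrow = h, ncol = w, byrow = TRUE)
  } else {
    px <- aperm(array(samples, dim = c(spp, w, h)), c(3, 2, 1))
  }
  list(pixels = px, bits = bits)
}

## -- user-facing readers/writers ---------------------------------------------

#' Read a brightfield optical image
#'
#' Reads a PNG or TIFF raster (detected by magic bytes) into an
#' [optical_image()]. Grayscale inputs are replicated across the three
#' channels; alpha channels are dropped; 16-bit TIFF samples are rescaled to
#' 0-255 by the maximum observed value.
#'
#' @param path path to a PNG or TIFF file.
#' @param pixel_size micrometers per pixel of the image.
#' @return an [optical_image()].
#' @export
read_optical <- function(path, pixel_size = 5) {
  fail_if(!file.exists(path), "image not found: %s", path)
  magic <- readBin(path, "raw", 4)
  is_png <- identical(magic, as.raw(c(0x89, 0x50, 0x4e, 0x47)))
  is_tiff <- rawToChar(magic[1:2]) %in% c("II", "MM")
  fail_if(!is_png && !is_tiff, "unsupported image format: %s", path)
  if (is_png) {
    a <- png::readPNG(path) # values in [0, 1] regardless of bit depth
    vals <- round(a * 255)
  } else {
    tf <- read_tiff(path)
    vals <- tf$pixels
    if (tf$bits == 16L) {
      m <- max(vals)
      vals <- if (m > 0) round(vals / m * 255) else vals
    }
  }
  if (length(dim(vals)) == 3 && dim(vals)[3] == 4) vals <- vals[, , 1:3]
  if (length(dim(vals)) == 3 && dim(vals)[3] == 2) vals <- vals[, , 1] # gray+alpha
  optical_image(vals, pixel_size = pixel_size)
}

#' Write an optical image or mask raster as PNG
#'
#' @param image an [optical_image()], an h x w x 3 array (0-255), or a
#'   logical matrix (written as black/white).
#' @param path output PNG path.
#' @return `path`, invisibly.
#' @export
write_optical <- function(image, path) {
  if (inherits(image, "optical_image")) image <- image$raster
  if (is.logical(image)) image <- array(ifelse(image, 255, 0), dim = dim(image))
  png::writePNG(image / 255, path)
  invisible(path)
}
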