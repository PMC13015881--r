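## Spectral preprocessing: prominence-based peak picking, ppm binning into a
## pixels x ions feature matrix, TIC normalization, per-ion unit scaling,
## and single-ion image extraction.

#' Pick peaks from one spectrum
#'
#' Local maxima are selected by topographic prominence computed on the
#' discrete intensity sequence; maxima closer than `ppm_window` (relative to
#' the larger m/z) are merged keeping the most intense, which prevents split
#' centroids. The defaults (prominence 500, 10 ppm) are the standard settings
#' for Orbitrap paint-section data.
#'
#' @param spectrum a [mass_spectrum()] or `list(mz=, intensity=)`.
#' @param min_prominence minimum topographic prominence retained.
#' @param ppm_window minimum separation between retained peaks, ppm.
#' @return data.frame with columns `mz`, `intensity`, `prominence`, class
#'   `"peak_list"`; empty for an empty or featureless spectrum.
#' @export
pick_peaks <- function(spectrum, min_prominence = 500, ppm_window = 10) {
  fail_if(min_prominence < 0, "min_prominence must be >= 0")
  fail_if(ppm_window <= 0, "ppm_window must be positive")
  empty <- structure(data.frame(mz = numeric(0), intensity = numeric(0),
                                prominence = numeric(0)),
                     class = c("peak_list", "data.frame"))
  y <- spectrum$intensity
  if (length(y) < 3) return(empty)
  res <- .cpp_peak_prominences(as.numeric(y))
  keep <- res$prominence >= min_prominence
  if (!any(keep)) return(empty)
  idx <- res$index[keep]
  mz <- spectrum$mz[idx]
  intensity <- y[idx]
  prominence <- res$prominence[keep]
  ## merge within ppm_window: greedy from the most intense
  o <- order(-intensity, mz)
  accepted <- integer(0)
  for (i in o) {
    if (!length(accepted) ||
        !any(within_ppm(mz[i], mz[accepted], ppm_window))) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- accepted[order(mz[accepted])]
  structure(data.frame(mz = mz[accepted], intensity = intensity[accepted],
                       prominence = prominence[accepted]),
            class = c("peak_list", "data.frame"))
}

#' Pick peaks across a whole MSI dataset
#'
#' @param dataset an [msi_dataset()].
#' @param ... passed to [pick_peaks()].
#' @param id dataset identifier carried into downstream feature matrices.
#' @return object of class `"msi_peaks"`: per-pixel peak lists plus
#'   coordinates.
#' @export
pick_peaks_dataset <- function(dataset, ..., id = "dataset1") {
  peaks <- lapply(dataset$spectra, pick_peaks, ...)
  structure(list(peaks = peaks, coords = dataset$coords, id = id,
                 width = dataset$width, height = dataset$height),
            class = "msi_peaks")
}

## Treat already-centroided spectra (each stick a peak) as an msi_peaks
## object without thresholding; used for noiseless fixtures.
as_msi_peaks <- function(dataset, id = "dataset1") {
  peaks <- lapply(dataset$spectra, function(s)
    structure(data.frame(mz = s$mz, intensity = s$intensity,
                         prominence = s$intensity),
              class = c("peak_list", "data.frame")))
  structure(list(peaks = peaks, coords = dataset$coords, id = id,
                 width = dataset$width, height = dataset$height),
            class = "msi_peaks")
}

#' Construct a feature matrix directly
#'
#' Usually produced by [align_peaks()]; exposed for tests and import.
#'
#' @param bin_mz ascending representative m/z per bin.
#' @param values pixels x bins matrix (dense or `Matrix` sparse).
#' @param pixels data.frame with columns `dataset`, `x`, `y`.
#' @param bin_ppm the alignment bin width used, ppm.
#' @return object of class `"feature_matrix"`.
#' @export
feature_matrix <- function(bin_mz, values, pixels, bin_ppm = NA_real_) {
  values <- methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  fail_if(length(bin_mz) != ncol(values),
          "bin_mz length must equal number of columns")
  fail_if(nrow(pixels) != nrow(values),
          "pixels must have one row per matrix row")
  if (length(bin_mz) > 1) fail_if(any(diff(bin_mz) <= 0), "bins must ascend")
  fail_if(any(values@x < 0), "intensities must be non-negative")
  structure(list(bin_mz = as.numeric(bin_mz), values = values,
                 pixels = pixels, bin_ppm = bin_ppm,
                 normalized = FALSE, scaled = FALSE),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d pixels (%d dataset%s) x %d bins%s%s\n",
    nrow(x$values), length(unique(x$pixels$dataset)),
    if (length(unique(x$pixels$dataset)) == 1) "" else "s", ncol(x$values),
    if (x$normalized) ", TIC-normalized" else "",
    if (x$scaled) ", unit-scaled" else ""))
  invisible(x)
}

#' Align peak lists into a pixels x ions feature matrix
#'
#' Bins are constructed on a logarithmic m/z axis with constant relative
#' width `bin_ppm`, anchored at the global minimum observed m/z. Each peak
#' falls into exactly one bin; multiple peaks of one pixel in one bin are
#' summed; the representative m/z of a bin is the intensity-weighted mean of
#' its member peaks. Alignment is invariant to the order of input pixels and
#' datasets.
#'
#' @param x an `msi_peaks` object ([pick_peaks_dataset()]) or a list of them
#'   (several sections aligned onto one axis).
#' @param bin_ppm bin width, ppm.
#' @return a [feature_matrix()] whose `pixels` carry dataset ids and
#'   coordinates row-major per dataset.
#' @export
align_peaks <- function(x, bin_ppm = 10) {
  fail_if(bin_ppm <= 0, "bin_ppm must be positive")
  if (inherits(x, "msi_peaks")) x <- list(x)
  pixels <- do.call(rbind, lapply(x, function(d)
    data.frame(dataset = d$id, x = d$coords$x, y = d$coords$y)))
  n_pixels <- sum(vapply(x, function(d) length(d$peaks), integer(1)))
  mz <- unlist(lapply(x, function(d) lapply(d$peaks, `[[`, "mz")))
  intensity <- unlist(lapply(x, function(d) lapply(d$peaks, `[[`, "intensity")))
  counts <- unlist(lapply(x, function(d)
    vapply(d$peaks, nrow, integer(1))))
  row <- rep(seq_len(n_pixels), counts)
  if (length(mz) == 0) {
    return(feature_matrix(numeric(0),
                          Matrix::sparseMatrix(integer(0), integer(0),
                                               x = numeric(0),
                                               dims = c(n_pixels, 0)),
                          pixels, bin_ppm))
  }
  w <- log1p(bin_ppm * 1e-6)
  bin <- floor(log(mz / min(mz)) / w + 1e-12)
  ids <- sort(unique(bin))
  j <- match(bin, ids)
  rep_mz <- vapply(split(seq_along(mz), j), function(i) {
    if (sum(intensity[i]) > 0) weighted.mean(mz[i], intensity[i])
    else mean(mz[i])
  }, numeric(1))
  values <- Matrix::sparseMatrix(i = row, j = j, x = intensity,
                                 dims = c(n_pixels, length(ids)))
  feature_matrix(as.numeric(rep_mz), values, pixels, bin_ppm)
}

#' Total-ion-count normalization
#'
#' Divides every nonzero pixel row by its sum so rows sum to 1. All-zero
#' rows are left untouched and reported in the `skipped_pixels` attribute.
#'
#' @param fm a [feature_matrix()].
#' @return the normalized feature matrix; `attr(, "skipped_pixels")` holds
#'   the row indices of all-zero pixels.
#' @export
tic_normalize <- function(fm) {
  fail_if(!inherits(fm, "feature_matrix"), "not a feature_matrix")
  rs <- Matrix::rowSums(fm$values)
  skipped <- which(rs == 0)
  scale <- ifelse(rs > 0, 1 / rs, 1)
  fm$values <- Matrix::Diagonal(x = scale) %*% fm$values
  fm$values <- methods::as(fm$values, "CsparseMatrix")
  fm$normalized <- TRUE
  attr(fm, "skipped_pixels") <- skipped
  fm
}

#' Min-max scale each ion image to the unit interval
#'
#' Every column (ion image) is independently mapped to `[0, 1]` by its
#' minimum and maximum over pixels; constant columns are mapped to 0. Scaling
#' per ion image keeps LASSO coefficients comparable across ions.
#'
#' @param fm a [feature_matrix()].
#' @return the scaled feature matrix.
#' @export
scale_unit <- function(fm) {
  fail_if(!inherits(fm, "feature_matrix"), "not a feature_matrix")
  v <- fm$values
  n <- nrow(v)
  nnz <- diff(v@p)
  jj <- rep(seq_len(ncol(v)), nnz)
  cmax <- rep(0, ncol(v))
  cmin <- rep(0, ncol(v))
  if (length(v@x)) {
    mx <- tapply(v@x, factor(jj, levels = seq_len(ncol(v))), max)
    mn <- tapply(v@x, factor(jj, levels = seq_len(ncol(v))), min)
    cmax[!is.na(mx)] <- mx[!is.na(mx)]
    ## a column with structural zeros has min 0; dense columns use data min
    dense <- nnz == n
    cmin[dense] <- mn[dense]
  }
  rng <- cmax - cmin
  const <- rng == 0
  x <- v@x
  scale <- ifelse(const, 0, 1 / ifelse(rng == 0, 1, rng))
  x <- (x - cmin[jj]) * scale[jj]
  v@x <- x
  v <- Matrix::drop0(v)
  fm$values <- v
  fm$scaled <- TRUE
  fm
}

#' Extract a single-ion image
#'
#' Sums, per pixel, the intensities of peaks within `tol_ppm` of `target_mz`.
#'
#' @param x an [msi_dataset()], `msi_peaks`, or [feature_matrix()] (single
#'   dataset only).
#' @param target_mz ion m/z, Th.
#' @param tol_ppm tolerance, ppm.
#' @return height x width numeric matrix; pixels with no matching peak are 0.
#' @export
extract_ion_image <- function(x, target_mz, tol_ppm = 10) {
  fail_if(tol_ppm <= 0, "tol_ppm must be positive")
  if (inherits(x, "msi_dataset")) {
    img <- matrix(0, x$height, x$width)
    for (i in seq_along(x$spectra)) {
      s <- x$spectra[[i]]
      sel <- abs(s$mz - target_mz) <= ppm_tol(target_mz, tol_ppm)
      if (any(sel))
        img[x$coords$y[i], x$coords$x[i]] <- sum(s$intensity[sel])
    }
    return(img)
  }
  if (inherits(x, "msi_peaks")) {
    img <- matrix(0, x$height, x$width)
    for (i in seq_along(x$peaks)) {
      p <- x$peaks[[i]]
      sel <- abs(p$mz - target_mz) <= ppm_tol(target_mz, tol_ppm)
      if (any(sel))
        img[x$coords$y[i], x$coords$x[i]] <- sum(p$intensity[sel])
    }
    return(img)
  }
  if (inherits(x, "feature_matrix")) {
    fail_if(length(unique(x$pixels$dataset)) != 1,
            "extract_ion_image on a feature_matrix needs a single dataset")
    sel <- abs(x$bin_mz - target_mz) <= ppm_tol(target_mz, tol_ppm)
    h <- max(x$pixels$y); w <- max(x$pixels$x)
    img <- matrix(0, h, w)
    vals <- if (any(sel)) Matrix::rowSums(x$values[, sel, drop = FALSE])
            else rep(0, nrow(x$values))
    img[cbind(x$pixels$y, x$pixels$x)] <- vals
    return(img)
  }
  stop("unsupported input to extract_ion_image", call. = FALSE)
}

#' Export / import a feature matrix as a delimited table
#'
#' The table has the pixel coordinates in the first two columns (`x`, `y`)
#' and one column per bin named by its representative m/z. Only
#' single-dataset matrices can be exported.
#'
#' @param fm a [feature_matrix()].
#' @param path TSV path.
#' @return `path` (write) or a [feature_matrix()] (read).
#' @export
write_feature_matrix <- function(fm, path) {
  fail_if(length(unique(fm$pixels$dataset)) > 1,
          "export supports a single dataset per file")
  tab <- cbind(data.frame(x = fm$pixels$x, y = fm$pixels$y),
               as.data.frame(as.matrix(fm$values)))
  names(tab)[-(1:2)] <- sprintf("%.6f", fm$bin_mz)
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @param id dataset identifier to attach on import.
#' @export
read_feature_matrix <- function(path, id = "dataset1") {
  tab <- read.delim(path, check.names = FALSE)
  fail_if(!all(c("x", "y") %in% names(tab)[1:2]),
          "feature matrix table must start with x, y columns")
  bin_mz <- as.numeric(names(tab)[-(1:2)])
  feature_matrix(bin_mz, as.matrix(tab[, -(1:2), drop = FALSE]),
                 data.frame(dataset = id, x = tab$x, y = tab$y))
}
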