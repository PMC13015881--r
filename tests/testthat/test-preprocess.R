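## Peak picking, alignment, normalization, scaling, ion images.

test_that("peak picking anchor cases", {
  ## constant spectrum: no local maxima
  flat <- mass_spectrum(seq(100, 101, length.out = 50), rep(7, 50))
  expect_identical(nrow(pick_peaks(flat, 0, 10)), 0L)

  ## triangular peak over zero baseline: exactly one peak at the apex
  mz <- seq(500, 500.01, length.out = 11)
  tri <- mass_spectrum(mz, c(0, 0, 0, 500, 1000, 500, 0, 0, 0, 0, 0))
  pk <- pick_peaks(tri, min_prominence = 500, ppm_window = 10)
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$mz, mz[5])
  expect_equal(pk$prominence, 1000)

  ## apex below the default prominence threshold: nothing retained
  tri499 <- mass_spectrum(mz, c(0, 0, 0, 250, 499, 250, 0, 0, 0, 0, 0))
  expect_identical(nrow(pick_peaks(tri499, 500, 10)), 0L)

  ## maxima closer than the window merge, keeping the most intense
  mz2 <- c(500.000, 500.001, 500.002, 500.003, 500.004)
  two <- mass_spectrum(mz2, c(0, 800, 10, 900, 0))
  pk2 <- pick_peaks(two, min_prominence = 100, ppm_window = 10)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$intensity, 900)

  expect_identical(nrow(pick_peaks(mass_spectrum(numeric(0), numeric(0)),
                                   500, 10)), 0L)
})

test_that("peak picking equals the brute-force prominence oracle", {
  withr::with_seed(2024, {
    for (i in 1:100) {
      s <- random_spectrum(sample(100:500, 1))
      got <- pick_peaks(s, min_prominence = 500, ppm_window = 10)
      want <- oracle_pick_peaks(s, min_prominence = 500, ppm_window = 10)
      expect_equal(got$mz, want$mz)
      expect_equal(got$prominence, want$prominence)
    }
  })
})

make_peakset <- function(peaktabs, id = "d1") {
  ds <- msi_dataset(
    lapply(peaktabs, function(p) list(mz = p$mz, intensity = p$intensity)),
    data.frame(x = seq_along(peaktabs), y = 1L))
  paintmsi:::as_msi_peaks(ds, id = id)
}

test_that("alignment bins by relative width and weights representatives", {
  ## 6 ppm apart: one shared bin
  ps <- make_peakset(list(data.frame(mz = 500.000, intensity = 1),
                          data.frame(mz = 500.003, intensity = 3)))
  fm <- align_peaks(ps, bin_ppm = 10)
  expect_identical(ncol(fm$values), 1L)
  expect_equal(fm$bin_mz, stats::weighted.mean(c(500.000, 500.003), c(1, 3)))

  ## 20 ppm apart: two bins
  ps2 <- make_peakset(list(data.frame(mz = 500.000, intensity = 1),
                           data.frame(mz = 500.010, intensity = 1)))
  expect_identical(ncol(align_peaks(ps2, 10)$values), 2L)

  ## empty input: zero bins, pixels preserved
  ps0 <- make_peakset(list(data.frame(mz = numeric(0),
                                      intensity = numeric(0))))
  fm0 <- align_peaks(ps0, 10)
  expect_identical(ncol(fm0$values), 0L)
  expect_identical(nrow(fm0$values), 1L)

  ## two peaks of one pixel in one bin are summed
  ps3 <- make_peakset(list(data.frame(mz = c(500.000, 500.002),
                                      intensity = c(1, 2))))
  expect_equal(as.numeric(align_peaks(ps3, 10)$values), 3)
})

test_that("alignment is invariant to pixel and dataset order", {
  lib <- tiny_library()
  sec <- noiseless_section(lib)
  pk <- pick_peaks_dataset(sec$dataset, min_prominence = 10, id = "a")
  perm <- withr::with_seed(1, sample(length(pk$peaks)))
  pk_perm <- pk
  pk_perm$peaks <- pk$peaks[perm]
  pk_perm$coords <- pk$coords[perm, ]
  f1 <- align_peaks(pk, 10)
  f2 <- align_peaks(pk_perm, 10)
  expect_equal(f1$bin_mz, f2$bin_mz)
  key1 <- paste(f1$pixels$x, f1$pixels$y)
  key2 <- paste(f2$pixels$x, f2$pixels$y)
  expect_setequal(key1, key2)
  expect_equal(as.matrix(f1$values),
               as.matrix(f2$values)[match(key1, key2), ],
               ignore_attr = TRUE)
})

test_that("TIC normalization and unit scaling", {
  fm <- feature_matrix(c(100, 200, 300),
                       rbind(c(2, 3, 5), c(0, 0, 0), c(1, 1, 0)),
                       data.frame(dataset = "d", x = 1:3, y = 1L))
  tn <- tic_normalize(fm)
  expect_equal(as.numeric(tn$values[1, ]), c(0.2, 0.3, 0.5))
  expect_equal(as.numeric(tn$values[2, ]), c(0, 0, 0))
  expect_identical(attr(tn, "skipped_pixels"), 2L)
  ## relative within-row proportions conserved
  expect_equal(as.numeric(tn$values[1, 2] / tn$values[1, 1]), 3 / 2)

  sc <- scale_unit(feature_matrix(c(100, 200),
                                  rbind(c(1, 4), c(3, 4), c(5, 4)),
                                  data.frame(dataset = "d", x = 1:3, y = 1L)))
  expect_equal(as.numeric(sc$values[, 1]), c(0, 0.5, 1))
  ## constant column maps to zero
  expect_equal(as.numeric(sc$values[, 2]), c(0, 0, 0))
})

test_that("normalization properties hold on random matrices", {
  withr::with_seed(99, {
    for (i in 1:5) {
      m <- matrix(rexp(20 * 7), 20, 7) * matrix(rbinom(140, 1, 0.6), 20, 7)
      fm <- feature_matrix(sort(runif(7, 100, 900)), m,
                           data.frame(dataset = "d", x = 1:20, y = 1L))
      tn <- tic_normalize(fm)
      rs <- Matrix::rowSums(tn$values)
      nonzero <- Matrix::rowSums(fm$values) > 0
      expect_true(all(abs(rs[nonzero] - 1) < 1e-9))
      sc <- scale_unit(tn)
      expect_true(all(sc$values@x >= 0 & sc$values@x <= 1))
    }
  })
})

test_that("ion image extraction respects ppm tolerance and ground truth", {
  ds <- msi_dataset(list(list(mz = c(100, 400.0), intensity = c(1, 7)),
                         list(mz = 400.006, intensity = 5),
                         list(mz = 200, intensity = 2),
                         list(mz = numeric(0), intensity = numeric(0))),
                    data.frame(x = c(1, 2, 1, 2), y = c(1, 1, 2, 2)))
  img <- extract_ion_image(ds, 400.0, tol_ppm = 10)
  expect_equal(img, rbind(c(7, 0), c(0, 0))) # +15 ppm pixel excluded
  img2 <- extract_ion_image(ds, 400.0, tol_ppm = 20)
  expect_equal(img2, rbind(c(7, 5), c(0, 0)))

  ## planted-layer ground truth on a noiseless section
  lib <- tiny_library()
  sec <- noiseless_section(lib)
  target <- lib$ions$ultramarine$mz[which.max(lib$ions$ultramarine$intensity)]
  img3 <- extract_ion_image(sec$dataset, target, tol_ppm = 5)
  truth <- mask_lookup_raster(sec$masks, "ultramarine", "pigment")
  expect_identical(img3 > 0, truth)
})

test_that("feature matrix export/import round trips", {
  dir <- withr::local_tempdir()
  fm <- feature_matrix(c(100.5, 200.25),
                       rbind(c(1.5, 0), c(0, 2.25)),
                       data.frame(dataset = "d", x = 1:2, y = c(1L, 2L)))
  f <- file.path(dir, "fm.tsv")
  write_feature_matrix(fm, f)
  back <- read_feature_matrix(f, id = "d")
  expect_equal(back$bin_mz, fm$bin_mz, tolerance = 1e-6)
  expect_equal(as.matrix(back$values), as.matrix(fm$values),
               ignore_attr = TRUE)
  expect_equal(back$pixels$x, fm$pixels$x)
})
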