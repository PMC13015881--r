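## Synthetic replica generator: planted content, determinism, coverage.

test_that("noiseless sections contain exactly the planted signature set", {
  lib <- tiny_library()
  sec <- noiseless_section(lib)
  layout <- sec$layout
  planted_layer1 <- sort(c(lib$ions$glue$mz, lib$ions$ochre$mz))
  planted_matrix <- sort(lib$ions$Matrix$mz)
  coords <- sec$dataset$coords
  for (i in seq_along(sec$dataset$spectra)) {
    reg <- layout[coords$y[i], coords$x[i]]
    s <- sec$dataset$spectra[[i]]
    if (reg == 1) {
      expect_equal(s$mz, planted_layer1)
    } else if (reg == 0) {
      expect_equal(s$mz, planted_matrix)
    }
  }
  ## mean planted intensity is recovered exactly without noise
  first_layer1 <- which(layout[cbind(coords$y, coords$x)] == 1)[1]
  s <- sec$dataset$spectra[[first_layer1]]
  want <- rbind(lib$ions$glue, lib$ions$ochre)
  want <- want[order(want$mz), ]
  expect_equal(s$intensity, want$intensity, tolerance = 1e-9)
})

test_that("generation is bit-reproducible under a seed", {
  lib <- tiny_library()
  cfg <- synth_config(grid = c(20, 24),
                      layers = list(layer_spec(6, "glue", "ochre")),
                      matrix_border = 3, seed = 77)
  a <- generate_dataset(cfg, lib)
  b <- generate_dataset(cfg, lib)
  expect_identical(a$dataset$spectra, b$dataset$spectra)
  expect_identical(a$layout, b$layout)
  expect_identical(a$optical$raster, b$optical$raster)
})

test_that("ground-truth masks partition the on-sample pixels", {
  lib <- tiny_library()
  bench <- tiny_bench(lib = lib)
  for (sec in c(bench$train, bench$validation, bench$test)) {
    layout <- sec$layout
    in_layer <- layout > 0
    binder_cover <- Reduce(`+`, lapply(sec$masks$binder, function(m)
      m$raster + 0))
    pigment_cover <- Reduce(`+`, lapply(sec$masks$pigment, function(m)
      m$raster + 0))
    ## every non-void in-layer pixel: exactly one binder and one pigment
    expect_true(all(binder_cover[in_layer] == 1))
    expect_true(all(pigment_cover[in_layer] == 1))
    ## voids and matrix carry no class label
    expect_true(all(binder_cover[layout <= 0] == 0))
    expect_true(all(sec$masks$matrix_mask$raster == (layout == 0)))
  }
})

test_that("void pixels carry background only and optical masks overhang them", {
  lib <- tiny_library()
  cfg <- synth_config(grid = c(24, 28),
                      layers = list(layer_spec(8, "glue", "ochre")),
                      matrix_border = 3, void_fraction = 0.15,
                      n_background_ions = 10, background_prob = 0.3,
                      seed = 5)
  sec <- generate_dataset(cfg, lib)
  voids <- which(sec$layout == -1L)
  expect_gt(length(voids), 0)
  coords <- sec$dataset$coords
  vi <- which(sec$layout[cbind(coords$y, coords$x)] == -1L)
  for (i in vi) {
    s <- sec$dataset$spectra[[i]]
    expect_true(all(s$mz %in% sec$background_mz))
  }
  ## the optical image colours voids like their layer (mask overhang)
  v1 <- voids[1]
  expect_false(sec$masks$pigment[[1]]$raster[v1])
  lay <- which(sec$layout == 1L)[1]
  rc <- function(i) c((i - 1) %% 28 + 1, (i - 1) %/% 28 + 1)
  expect_identical(sec$optical$raster[rc(v1)[1], rc(v1)[2], ],
                   sec$optical$raster[rc(lay)[1], rc(lay)[2], ])
})

test_that("benchmark coverage and reproducibility", {
  lib <- tiny_library()
  ## n_train = 4 with 2 classes per problem: every class appears in training
  bench <- generate_benchmark(lib, n_train = 4, n_validation = 1, n_test = 1,
                              grid = c(24, 36), seed = 9,
                              n_layers_range = c(2, 2),
                              thickness_range = c(5, 7), matrix_border = 3)
  train_binders <- unique(unlist(lapply(bench$train, function(s)
    vapply(s$config$layers, `[[`, character(1), "binder"))))
  train_pigments <- unique(unlist(lapply(bench$train, function(s)
    vapply(s$config$layers, `[[`, character(1), "pigment"))))
  expect_setequal(train_binders, c("glue", "oil"))
  expect_setequal(train_pigments, c("ochre", "ultramarine"))
  ## test classes are a subset of training classes by construction
  test_classes <- unlist(lapply(bench$test[[1]]$config$layers, function(l)
    c(l$binder, l$pigment)))
  expect_true(all(test_classes %in% c(train_binders, train_pigments)))

  bench2 <- generate_benchmark(lib, n_train = 4, n_validation = 1,
                               n_test = 1, grid = c(24, 36), seed = 9,
                               n_layers_range = c(2, 2),
                               thickness_range = c(5, 7), matrix_border = 3)
  expect_identical(bench$train[[1]]$dataset$spectra,
                   bench2$train[[1]]$dataset$spectra)

  expect_error(generate_benchmark(lib, n_train = 0), ">= 1")
})

test_that("library construction avoids collisions and plants chemistry", {
  lib <- tiny_library()
  all_mz <- sort(unlist(lapply(lib$ions, `[[`, "mz")))
  ## no two signatures closer than 20 ppm anywhere
  gaps_ppm <- diff(all_mz) / all_mz[-1] * 1e6
  expect_gt(min(gaps_ppm), 20)
  ## ochre metal members follow the declared formula chemistry
  info <- lib$metal_info$ochre
  expect_equal(info$series_mzs[1], adduct_mz("FeO4H5", "[M+H]+"),
               tolerance = 1e-9)
  expect_equal(sort(info$base_pattern$abundance, decreasing = TRUE),
               isotope_pattern("FeO4H5", "[M+H]+", top_n = 4)$abundance)
  expect_error(
    generate_dataset(synth_config(grid = c(20, 24),
                                  layers = list(layer_spec(5, "nope", "ochre")),
                                  matrix_border = 3, seed = 1), lib),
    "missing from the signature library")
})

test_that("the reference benchmark generates within its budget", {
  elapsed <- system.time(bench <- default_benchmark(seed = 42))["elapsed"]
  expect_lt(elapsed, 30)
  expect_identical(length(bench$train), 6L)
  expect_identical(length(bench$validation), 2L)
  expect_identical(length(bench$test), 1L)
  expect_identical(bench$train[[1]]$dataset$width, 64L)
})

test_that("sections are written to disk as standard artifacts", {
  dir <- withr::local_tempdir()
  sec <- noiseless_section()
  write_section(sec, dir)
  expect_true(file.exists(file.path(dir, "noiseless.imzML")))
  expect_true(file.exists(file.path(dir, "noiseless.ibd")))
  expect_true(file.exists(file.path(dir, "noiseless_bf.png")))
  expect_true(file.exists(file.path(dir, "noiseless_truth.tsv")))
  back <- read_imzml(file.path(dir, "noiseless.imzML"))
  expect_identical(length(back$spectra), 20L * 24L)
})
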