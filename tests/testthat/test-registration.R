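## Similarity registration, colour masks, refinement, balanced sampling.

test_that("identity landmarks give the identity transform", {
  pts <- cbind(x = c(1, 10, 10, 1), y = c(1, 1, 8, 8))
  tr <- fit_similarity(pts, pts)
  expect_equal(tr$scale, 1, tolerance = 1e-12)
  expect_equal(tr$rotation, 0, tolerance = 1e-12)
  expect_equal(tr$translation, c(0, 0), tolerance = 1e-12)
})

test_that("forward-generated transforms are recovered to 1e-9", {
  withr::with_seed(7, {
    for (i in 1:100) {
      n <- sample(3:12, 1)
      src <- cbind(runif(n, -50, 50), runif(n, -50, 50))
      s <- runif(1, 0.3, 3)
      th <- runif(1, -pi, pi)
      tr_true <- list(scale = s, rotation = th,
                      translation = runif(2, -20, 20))
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
      dst <- sweep(s * src %*% t(R), 2, tr_true$translation, `+`)
      fit <- fit_similarity(src, dst)
      expect_equal(fit$scale, s, tolerance = 1e-9)
      expect_equal(fit$rotation, th, tolerance = 1e-9)
      expect_equal(fit$translation, tr_true$translation, tolerance = 1e-9)
      expect_lt(fit$residual, 1e-9)
    }
  })
})

test_that("noisy correspondences report their residual", {
  withr::with_seed(8, {
    src <- cbind(runif(20, 0, 100), runif(20, 0, 100))
    dst <- 2 * src + 5 + matrix(rnorm(40, 0, 0.5), 20, 2)
    fit <- fit_similarity(src, dst)
    expect_equal(fit$scale, 2, tolerance = 0.05)
    expect_gt(fit$residual, 0)
    expect_lt(fit$residual, 2)
  })
  expect_error(fit_similarity(cbind(c(1, 1), c(2, 2)),
                              cbind(c(1, 2), c(2, 3))),
               "degenerate|coincident")
})

test_that("resampling through the transform behaves at the anchors", {
  img <- optical_image(array(rep(1:24, 3), dim = c(4, 6, 3)))
  ident <- fit_similarity(cbind(c(1, 6, 6), c(1, 1, 4)),
                          cbind(c(1, 6, 6), c(1, 1, 4)))
  out <- apply_transform(img, ident, grid = c(6, 4))
  expect_equal(out[, , 1], img$raster[, , 1])

  shift <- ident
  shift$translation <- c(1, 0) # move content one pixel right
  out2 <- apply_transform(img, shift, grid = c(6, 4))
  expect_equal(out2[, 2:6, 1], img$raster[, 1:5, 1])
  expect_equal(out2[, 1, 1], rep(255, 4)) # sentinel fill (magenta r)

  far <- ident
  far$translation <- c(1000, 1000)
  out3 <- apply_transform(img, far, grid = c(6, 4))
  expect_true(all(out3[, , 1] == 255 & out3[, , 2] == 0 & out3[, , 3] == 255))
})

test_that("colour thresholding builds the expected masks", {
  reg <- array(0, dim = c(6, 6, 3))
  reg[, , 1] <- 255; reg[, , 3] <- 255 # sentinel everywhere
  reg[2:3, 2:5, 1] <- 200; reg[2:3, 2:5, 2] <- 60; reg[2:3, 2:5, 3] <- 60
  reg[4:5, 2:5, 1] <- 60; reg[4:5, 2:5, 2] <- 140; reg[4:5, 2:5, 3] <- 60
  attr(reg, "sentinel") <- c(255, 0, 255)
  specs <- data.frame(label = c("glue", "oil", "ochre", "ultra"),
                      type = c("binder", "binder", "pigment", "pigment"),
                      r = c(200, 60, 200, 60), g = c(60, 140, 60, 140),
                      b = c(60, 60, 60, 60), tol = 10)
  masks <- extract_masks_color(reg, specs)
  expect_true(all(mask_lookup_raster(masks, "glue", "binder")[2:3, 2:5]))
  expect_identical(sum(mask_lookup_raster(masks, "glue", "binder")), 8L)
  expect_identical(sum(mask_lookup_raster(masks, "ultra", "pigment")), 8L)
  expect_identical(sum(masks$matrix_mask$raster), 36L - 16L)

  ## a pixel just past tolerance stays unlabelled
  reg2 <- reg
  reg2[2, 2, 1] <- 200 + 11
  masks2 <- extract_masks_color(reg2, specs)
  expect_false(mask_lookup_raster(masks2, "glue", "binder")[2, 2])

  ## all-sentinel raster: only the Matrix mask is populated
  reg3 <- array(0, dim = c(3, 3, 3))
  reg3[, , 1] <- 255; reg3[, , 3] <- 255
  attr(reg3, "sentinel") <- c(255, 0, 255)
  masks3 <- extract_masks_color(reg3, specs)
  expect_true(all(masks3$matrix_mask$raster))
  expect_false(any(mask_lookup_raster(masks3, "glue", "binder")))

  ## overlapping specs within one problem are a configuration error
  bad <- specs
  bad$r[2] <- 205; bad$g[2] <- 60; bad$b[2] <- 60
  expect_error(extract_masks_color(reg, bad), "overlap")
})

test_that("mask refinement shrinks but never grows the optical mask", {
  ## feature matrix equal to a binary ion image: refinement is the identity
  h <- 6; w <- 6
  raster <- matrix(FALSE, h, w)
  raster[2:4, 2:4] <- TRUE
  pixels <- data.frame(dataset = "d",
                       x = rep(seq_len(w), times = h),
                       y = rep(seq_len(h), each = w))
  ion <- as.numeric(raster[cbind(pixels$y, pixels$x)])
  fm <- feature_matrix(c(100, 200), cbind(ion, 1 - ion), pixels)
  m <- class_mask("layer", raster, "binder")
  refined <- refine_mask(fm, m)
  expect_identical(refined$raster, raster)

  ## optical mask overhanging a void (no ions there): void pixels dropped
  void <- matrix(FALSE, h, w); void[3, 3] <- TRUE
  ion_v <- as.numeric((raster & !void)[cbind(pixels$y, pixels$x)])
  fm_v <- feature_matrix(c(100, 200), cbind(ion_v, 1 - ion_v), pixels)
  refined_v <- refine_mask(fm_v, m)
  expect_false(refined_v$raster[3, 3])
  expect_identical(refined_v$raster, raster & !void)
  ## shrink-only property
  expect_true(all(refined_v$raster <= m$raster))

  ## all-zero features: warning, unchanged
  fm0 <- feature_matrix(c(100), matrix(0, h * w, 1), pixels)
  expect_warning(ref0 <- refine_mask(fm0, m), "all-zero")
  expect_identical(ref0$raster, raster)
  expect_error(refine_mask(fm, class_mask("x", matrix(FALSE, h, w),
                                          "binder")), "empty")
})

test_that("balanced sampling is exact, warned, and reproducible", {
  big <- matrix(FALSE, 10, 20); big[1:5, ] <- TRUE     # 100 px
  small <- matrix(FALSE, 10, 20); small[10, 1:10] <- TRUE # 10 px
  ms <- mask_set(binder = list(class_mask("A", big, "binder"),
                               class_mask("B", !big & !small, "binder")))
  s <- sample_balanced(ms, n_per_class = 50, seed = 4, which = "binder")
  expect_identical(as.integer(table(s$label)[c("A", "B")]), c(50L, 50L))

  ms2 <- mask_set(binder = list(class_mask("A", big, "binder"),
                                class_mask("C", small, "binder")))
  s2 <- sample_balanced(ms2, n_per_class = 50, seed = 4, which = "binder")
  expect_identical(sum(s2$label == "C"), 10L)

  expect_identical(sample_balanced(ms, 30, seed = 9, which = "binder"),
                   sample_balanced(ms, 30, seed = 9, which = "binder"))
  ## pixel indices are row-major and coordinates consistent
  expect_true(all(s$pixel == (s$y - 1) * 20 + s$x))

  empty <- mask_set(binder = list(class_mask("A", big, "binder"),
                                  class_mask("Z", matrix(FALSE, 10, 20),
                                             "binder")))
  expect_warning(sample_balanced(empty, 5, seed = 1, which = "binder"),
                 "no pixels")
})

test_that("mask-set disjointness is enforced and survives refinement", {
  a <- matrix(FALSE, 4, 4); a[1:2, ] <- TRUE
  b <- matrix(FALSE, 4, 4); b[2:3, ] <- TRUE
  expect_error(mask_set(binder = list(class_mask("a", a, "binder"),
                                      class_mask("b", b, "binder"))),
               "disjoint")
  expect_error(mask_set(binder = list(class_mask("a", a, "binder")),
                        matrix_mask = class_mask("Matrix", a, "matrix")),
               "overlaps")

  ## refinement on a generated section preserves disjointness
  lib <- tiny_library()
  sec <- tiny_bench(lib = lib)$train[[1]]
  pk <- pick_peaks_dataset(sec$dataset, id = sec$id)
  fm <- scale_unit(tic_normalize(align_peaks(pk)))
  corners <- cbind(x = c(1, 28, 28, 1), y = c(1, 1, 36, 36))
  reg <- apply_transform(sec$optical, fit_similarity(corners, corners),
                         grid = c(28, 36))
  masks <- extract_masks_color(reg, sec$color_specs)
  refined <- paintmsi:::refine_masks(fm, masks)
  expect_s3_class(refined, "mask_set") # constructor re-checks disjointness
  for (m in refined$binder) {
    orig <- mask_lookup_raster(masks, m$label, "binder")
    expect_true(all(m$raster <= orig))
  }
})
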