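## Synthetic multilayer paint cross sections with ground truth.
##
## The generator emulates aged replica boards: horizontal paint layers, each
## carrying one binder class and one pigment class with characteristic ion
## signatures (metal pigments carry full isotopic patterns and FeOOH /
## water-loss cluster series), an off-sample Matrix border, voids inside
## layers, sparse background ions, and multiplicative/additive noise.
## Everything is reproducible from a single seed.

## Distinct, exactly-known layer colours (away from the magenta sentinel).
.layer_palette <- matrix(c(
  200, 60, 60,   60, 140, 60,   70, 90, 200,  220, 170, 60,
  140, 80, 170,  80, 190, 190,  150, 100, 50, 240, 130, 170,
  100, 60, 120,  180, 220, 100, 60, 60, 60,   240, 240, 240),
  ncol = 3, byrow = TRUE)

.sentinel_color <- c(255, 0, 255)

## Masses whose accidental reproduction between random signature ions would
## fake an isotopologue or homologous-series relation in noiseless data.
.reserved_spacings <- function() {
  fe <- isotope_table("Fe")
  p <- which.max(fe[, "abundance"])
  c(monoisotopic_mass("FeOOH"), monoisotopic_mass("H2O"),
    abs(fe[-p, "mass"] - fe[p, "mass"]))
}

#' Build a signature-ion library for the synthetic replicas
#'
#' Each class receives `n_ions` characteristic ions drawn once, uniformly
#' over the acquisition mass range, with lognormal mean intensities.
#' Candidate m/z are rejected within 50 ppm of any previously accepted
#' signature and within 30 ppm of any mass one FeOOH, H2O or Fe-isotope
#' spacing away from one, so signatures never mimic isotopologue or series
#' relations by accident. Metal pigment classes additionally carry planted
#' cluster chemistry: full isotopic patterns of a base cluster ion and its
#' FeOOH-addition / water-loss series.
#'
#' @param classes data.frame with columns `class`, `type` ("binder",
#'   "pigment", "matrix"); default: the four traditional binders (animal
#'   glue, casein, egg tempera, linseed oil), five pigments (gesso, lead
#'   white, ochre, sienna, ultramarine) and Matrix.
#' @param metals named list (by class) of metal specs: `formula`, `adduct`,
#'   optional `series_unit`, `n_additions`, `n_losses`; defaults plant an
#'   iron hydroxide-hydrate cluster in ochre (with FeOOH/H2O series), an
#'   iron oxide species in sienna and elemental lead in lead white.
#' @param n_ions signature ions per class.
#' @param mz_range acquisition range (Th).
#' @param intensity_meanlog,intensity_sdlog lognormal parameters of mean
#'   signature intensities.
#' @param metal_intensity principal-isotopologue intensity of the metal base
#'   cluster.
#' @param isotope_top_n isotopologues planted per metal species.
#' @param seed RNG seed.
#' @return object of class `"signature_library"`.
#' @export
signature_library <- function(classes = NULL, metals = NULL, n_ions = 15,
                              mz_range = c(60, 900),
                              intensity_meanlog = log(4000),
                              intensity_sdlog = 0.4,
                              metal_intensity = 8000,
                              isotope_top_n = 4, seed = 42) {
  if (is.null(classes)) {
    classes <- data.frame(
      class = c("animal_glue", "casein", "egg_tempera", "linseed_oil",
                "gesso", "lead_white", "ochre", "sienna", "ultramarine",
                "Matrix"),
      type = c(rep("binder", 4), rep("pigment", 5), "matrix"))
  }
  if (is.null(metals)) {
    metals <- list(
      ochre = list(formula = "FeO4H5", adduct = "[M+H]+",
                   series_unit = "FeOOH", n_additions = 2, n_losses = 2),
      sienna = list(formula = "Fe2O3H3", adduct = "[M+H]+"),
      lead_white = list(formula = "Pb", adduct = "M+."))
  }
  metals <- metals[intersect(names(metals), classes$class)]
  spacings <- .reserved_spacings()
  ions <- list()
  metal_info <- list()
  accepted <- numeric(0)

  admissible <- function(m) {
    if (length(accepted) == 0) return(TRUE)
    if (any(within_ppm(m, accepted, 50))) return(FALSE)
    shifted <- as.vector(outer(accepted, c(spacings, -spacings), `+`))
    !any(within_ppm(m, shifted[shifted > 0], 30))
  }

  with_seed(seed, {
    ## metal chemistry first: its masses are dictated by the formulas
    for (cl in names(metals)) {
      sp <- metals[[cl]]
      members <- list(parse_formula(sp$formula))
      if (!is.null(sp$series_unit)) {
        for (k in seq_len(sp$n_additions %||% 0)) {
          members <- c(members, list(Reduce(formula_add,
            c(list(parse_formula(sp$formula)),
              rep(list(sp$series_unit), k)))))
        }
        base <- parse_formula(sp$formula)
        for (j in seq_len(sp$n_losses %||% 0)) {
          f <- unclass(base)
          f[["H"]] <- f[["H"]] - 2L * j
          f[["O"]] <- f[["O"]] - 1L * j
          if (all(f >= 0) && sum(f) > 0)
            members <- c(members, list(parse_formula(f)))
        }
      }
      rows <- list()
      for (i in seq_along(members)) {
        pat <- isotope_pattern(members[[i]], sp$adduct, top_n = isotope_top_n)
        rows[[i]] <- data.frame(
          mz = pat$mz,
          intensity = metal_intensity * 0.65^(i - 1) * pat$abundance,
          group = i, kind = "metal")
      }
      tab <- do.call(rbind, rows)
      ions[[cl]] <- tab
      accepted <- c(accepted, tab$mz)
      metal_info[[cl]] <- list(
        spec = sp,
        series_mzs = vapply(members, function(f) adduct_mz(f, sp$adduct),
                            numeric(1)),
        base_pattern = isotope_pattern(sp$formula, sp$adduct,
                                       top_n = isotope_top_n))
    }
    ## plain signature ions
    for (cl in classes$class) {
      have <- if (is.null(ions[[cl]])) 0L else max(ions[[cl]]$group)
      n_draw <- n_ions
      mzs <- numeric(0)
      guard <- 0
      while (length(mzs) < n_draw) {
        m <- runif(1, mz_range[1], mz_range[2])
        guard <- guard + 1
        fail_if(guard > 10000 * n_draw, "cannot place signature ions")
        if (admissible(m) && (length(mzs) == 0 || !any(within_ppm(m, mzs, 50)))) {
          mzs <- c(mzs, m)
          accepted <- c(accepted, m)
        }
      }
      plain <- data.frame(
        mz = mzs,
        intensity = exp(rnorm(n_draw, intensity_meanlog, intensity_sdlog)),
        group = have + seq_len(n_draw), kind = "plain")
      ions[[cl]] <- rbind(ions[[cl]], plain)
    }
  })
  ions <- lapply(ions, function(tab) tab[order(tab$mz), ])
  structure(list(classes = classes, ions = ions, metal_info = metal_info,
                 mz_range = mz_range, seed = seed),
            class = "signature_library")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.signature_library <- function(x, ...) {
  cat(sprintf("<signature_library> %d classes, %d ions total, seed %d\n",
              nrow(x$classes), sum(vapply(x$ions, nrow, integer(1))),
              x$seed))
  invisible(x)
}

#' Layer specification
#'
#' @param thickness layer thickness in pixels (>= 1).
#' @param binder,pigment class labels.
#' @return list of class `"layer_spec"`.
#' @export
layer_spec <- function(thickness, binder, pigment) {
  fail_if(thickness < 1, "thickness must be >= 1")
  structure(list(thickness = as.integer(thickness), binder = binder,
                 pigment = pigment), class = "layer_spec")
}

#' Synthetic dataset configuration
#'
#' @param grid `c(width, height)` in pixels.
#' @param layers list of [layer_spec()], top to bottom.
#' @param matrix_border off-sample border width in pixels.
#' @param void_fraction fraction of each layer's area turned into voids.
#' @param noise list with `additive_sd` (half-normal additive intensity
#'   noise), `multiplicative_sdlog` (lognormal intensity noise) and
#'   `background_scale` (mean background-ion intensity).
#' @param n_background_ions ions in the dataset-wide background pool.
#' @param background_prob per-pixel presence probability of each background
#'   ion.
#' @param seed RNG seed.
#' @return list of class `"synth_config"`.
#' @export
synth_config <- function(grid = c(64, 64), layers,
                         matrix_border = 4, void_fraction = 0.04,
                         noise = list(additive_sd = 40,
                                      multiplicative_sdlog = 0.3,
                                      background_scale = 600),
                         n_background_ions = 200, background_prob = 0.12,
                         seed = 1) {
  fail_if(void_fraction < 0 || void_fraction >= 1,
          "void_fraction must lie in [0, 1)")
  total <- sum(vapply(layers, `[[`, integer(1), "thickness"))
  fail_if(total + 2 * matrix_border > grid[2],
          "layers (%d px) plus borders exceed grid height %d", total, grid[2])
  structure(list(grid = grid, layers = layers, matrix_border = matrix_border,
                 void_fraction = void_fraction, noise = noise,
                 n_background_ions = n_background_ions,
                 background_prob = background_prob, seed = seed),
            class = "synth_config")
}

#' Generate one synthetic paint cross section
#'
#' Builds the MSI dataset, the matching brightfield image and the exact
#' ground-truth mask set for one stacked-layer replica. Layer pixels carry
#' the binder and pigment signature ions of their layer (metal species with
#' their full isotopic patterns, cluster members sharing one multiplicative
#' noise factor so isotope ratios survive), plus sparse background ions and
#' additive noise; void pixels carry background only; border pixels carry
#' the Matrix signature. The optical image colours each distinct
#' binder/pigment combination with its own exact colour (voids included, so
#' optical masks overhang voids and exercise refinement) and the border with
#' the magenta sentinel.
#'
#' @param config a [synth_config()].
#' @param library a [signature_library()].
#' @param id dataset identifier.
#' @return list with `id`, `dataset` ([msi_dataset()]), `optical`
#'   ([optical_image()]), `masks` (ground-truth [mask_set()], voids
#'   excluded), `color_specs` (for [extract_masks_color()]), `layout`
#'   (region matrix: 0 matrix, -1 void, k = layer), `config`.
#' @export
generate_dataset <- function(config, library, id = "dataset1") {
  w <- config$grid[1]; h <- config$grid[2]; mb <- config$matrix_border
  for (ls in config$layers) {
    for (cl in c(ls$binder, ls$pigment)) {
      fail_if(is.null(library$ions[[cl]]),
              "class '%s' missing from the signature library", cl)
    }
  }
  fail_if(is.null(library$ions[["Matrix"]]),
          "library must provide a 'Matrix' class")

  region <- matrix(0L, h, w)
  r0 <- mb
  for (k in seq_along(config$layers)) {
    th <- config$layers[[k]]$thickness
    region[(r0 + 1):(r0 + th), (mb + 1):(w - mb)] <- k
    r0 <- r0 + th
  }

  ## unique binder/pigment combinations get distinct optical colours
  combos <- vapply(config$layers, function(l)
    paste(l$binder, l$pigment, sep = "|"), character(1))
  ucombo <- unique(combos)
  fail_if(length(ucombo) > nrow(.layer_palette),
          "more distinct layer compositions than palette colours")
  combo_color <- .layer_palette[seq_along(ucombo), , drop = FALSE]

  noise <- config$noise
  out <- with_seed(config$seed, {
    bg_mz <- sort(runif(config$n_background_ions, library$mz_range[1],
                        library$mz_range[2]))
    ## voids
    for (k in seq_along(config$layers)) {
      cells <- which(region == k)
      target <- round(config$void_fraction * length(cells))
      guard <- 0
      while (sum(region == -1L & .in_cells(region, cells)) < target &&
             guard < 200) {
        guard <- guard + 1
        c0 <- cells[sample.int(length(cells), 1)]
        cy <- (c0 - 1) %% h + 1; cx <- (c0 - 1) %/% h + 1
        r <- sample(1:2, 1)
        ys <- pmax(1, cy - r):pmin(h, cy + r)
        xs <- pmax(1, cx - r):pmin(w, cx + r)
        blob <- as.matrix(expand.grid(y = ys, x = xs))
        blob <- blob[(blob[, "y"] - cy)^2 + (blob[, "x"] - cx)^2 <= r^2, ,
                     drop = FALSE]
        sel <- region[blob] == k
        region[blob[sel, , drop = FALSE]] <- -1L
      }
    }

    ## per-pixel spectra, row-major by (y, x); ion-group indices (groups =
    ## sets of isotopologues sharing one noise factor) precomputed per layer
    prep_tab <- function(tab) {
      g <- paste(tab$src, tab$group)
      list(mz = tab$mz, base = tab$intensity,
           gidx = match(g, unique(g)), ngroups = length(unique(g)))
    }
    layer_tabs <- lapply(config$layers, function(l) prep_tab(
      rbind(cbind(library$ions[[l$binder]], src = "binder"),
            cbind(library$ions[[l$pigment]], src = "pigment"))))
    matrix_tab <- prep_tab(cbind(library$ions[["Matrix"]], src = "matrix"))
    spectra <- vector("list", w * h)
    coords <- data.frame(x = rep(seq_len(w), times = h),
                         y = rep(seq_len(h), each = w))
    i <- 0L
    for (yy in seq_len(h)) for (xx in seq_len(w)) {
      i <- i + 1L
      reg <- region[yy, xx]
      tab <- if (reg > 0) layer_tabs[[reg]]
             else if (reg == 0L) matrix_tab
             else NULL
      mz <- numeric(0); intensity <- numeric(0)
      if (!is.null(tab)) {
        ## one lognormal factor per ion group (isotopologues move together)
        f <- exp(rnorm(tab$ngroups, 0, noise$multiplicative_sdlog))
        intensity <- tab$base * f[tab$gidx]
        mz <- tab$mz
      }
      present <- runif(length(bg_mz)) < config$background_prob
      if (any(present)) {
        mz <- c(mz, bg_mz[present])
        intensity <- c(intensity,
                       rexp(sum(present), rate = 1 / noise$background_scale))
      }
      if (length(mz) && noise$additive_sd > 0) {
        intensity <- intensity + abs(rnorm(length(mz), 0, noise$additive_sd))
      }
      o <- order(mz)
      mz <- mz[o]; intensity <- intensity[o]
      if (length(mz) > 1) { # collapse exact duplicates
        dup <- c(FALSE, diff(mz) == 0)
        if (any(dup)) {
          grp <- cumsum(!dup)
          intensity <- as.numeric(tapply(intensity, grp, sum))
          mz <- mz[!dup]
        }
      }
      spectra[[i]] <- list(mz = mz, intensity = intensity)
    }
    list(region = region, spectra = spectra, coords = coords, bg_mz = bg_mz)
  })
  region <- out$region

  ## optical image + colour specs
  raster <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) raster[, , ch] <- .sentinel_color[ch]
  for (k in seq_along(config$layers)) {
    col <- combo_color[match(combos[k], ucombo), ]
    sel <- region == k | (region == -1L & .layer_rows(config, k, h, w))
    for (ch in 1:3) {
      plane <- raster[, , ch]
      plane[sel] <- col[ch]
      raster[, , ch] <- plane
    }
  }
  optical <- optical_image(raster, pixel_size = 5)

  specs <- do.call(rbind, lapply(seq_along(ucombo), function(u) {
    parts <- strsplit(ucombo[u], "|", fixed = TRUE)[[1]]
    data.frame(label = parts, type = c("binder", "pigment"),
               r = combo_color[u, 1], g = combo_color[u, 2],
               b = combo_color[u, 3], tol = 10)
  }))

  ## exact ground truth (voids excluded)
  build_masks <- function(type) {
    cls <- unique(vapply(config$layers, `[[`, character(1), type))
    lapply(cls, function(cl) {
      sel <- matrix(FALSE, h, w)
      for (k in seq_along(config$layers)) {
        if (config$layers[[k]][[type]] == cl) sel <- sel | (region == k)
      }
      class_mask(cl, sel, type)
    })
  }
  masks <- mask_set(binder = build_masks("binder"),
                    pigment = build_masks("pigment"),
                    matrix_mask = class_mask("Matrix", region == 0L, "matrix"))

  dataset <- msi_dataset(out$spectra, out$coords, width = w, height = h,
                         mode = "processed", pixel_size = 5)
  list(id = id, dataset = dataset, optical = optical, masks = masks,
       color_specs = specs, layout = region, background_mz = out$bg_mz,
       config = config)
}

.in_cells <- function(region, cells) {
  m <- matrix(FALSE, nrow(region), ncol(region))
  m[cells] <- TRUE
  m
}

## Rows spanned by layer k (used to colour voids like their host layer).
.layer_rows <- function(config, k, h, w) {
  mb <- config$matrix_border
  r0 <- mb + c(0, cumsum(vapply(config$layers, `[[`, integer(1),
                                "thickness")))
  sel <- matrix(FALSE, h, w)
  sel[(r0[k] + 1):r0[k + 1], (mb + 1):(w - mb)] <- TRUE
  sel
}

#' Generate a train/validation/test benchmark of synthetic sections
#'
#' Independent stratigraphies are drawn by permuting layer classes and
#' thicknesses across datasets; binder and pigment classes are cycled
#' through the training layer slots so every class is guaranteed to appear
#' in at least one training dataset (validation/test classes are therefore a
#' subset of the training classes). Per-dataset seeds derive
#' deterministically from the master seed.
#'
#' @param library a [signature_library()].
#' @param n_train,n_validation,n_test dataset counts.
#' @param grid dataset dimensions `c(width, height)`.
#' @param seed master seed (default 42, the reference benchmark).
#' @param n_layers_range,thickness_range inclusive ranges the per-dataset
#'   layer count and per-layer thickness (pixels) are drawn from.
#' @param ... further arguments to [synth_config()] (noise, voids, ...).
#' @return list with elements `train`, `validation`, `test`, each a list of
#'   [generate_dataset()] results with ids `train1`, `val1`, `test1`, ...
#' @export
generate_benchmark <- function(library, n_train = 6, n_validation = 2,
                               n_test = 1, grid = c(64, 64), seed = 42,
                               n_layers_range = c(3, 5),
                               thickness_range = c(6, 10), ...) {
  fail_if(n_train < 1 || n_validation < 1 || n_test < 1,
          "dataset counts must be >= 1")
  binders <- library$classes$class[library$classes$type == "binder"]
  pigments <- library$classes$class[library$classes$type == "pigment"]
  n_total <- n_train + n_validation + n_test
  seeds <- derive_seeds(seed, n_total + 1)

  plan <- with_seed(seeds[n_total + 1], {
    n_layers <- sample(n_layers_range[1]:n_layers_range[2], n_total,
                       replace = TRUE)
    slots_train <- sum(n_layers[seq_len(n_train)])
    fail_if(slots_train < max(length(binders), length(pigments)),
            "class coverage impossible: %d training layer slots for %d classes",
            slots_train, max(length(binders), length(pigments)))
    b_seq <- rep(sample(binders), length.out = slots_train)
    p_seq <- rep(sample(pigments), length.out = slots_train)
    used <- 0L
    lapply(seq_len(n_total), function(i) {
      nl <- n_layers[i]
      if (i <= n_train) {
        b <- b_seq[used + seq_len(nl)]; p <- p_seq[used + seq_len(nl)]
        used <<- used + nl
      } else {
        b <- sample(binders, nl, replace = TRUE)
        p <- sample(pigments, nl, replace = TRUE)
      }
      lapply(seq_len(nl), function(j)
        layer_spec(sample(thickness_range[1]:thickness_range[2], 1),
                   b[j], p[j]))
    })
  })

  ids <- c(paste0("train", seq_len(n_train)),
           paste0("val", seq_len(n_validation)),
           paste0("test", seq_len(n_test)))
  sets <- lapply(seq_len(n_total), function(i) {
    cfg <- synth_config(grid = grid, layers = plan[[i]],
                        seed = seeds[i], ...)
    generate_dataset(cfg, library, id = ids[i])
  })
  list(train = sets[seq_len(n_train)],
       validation = sets[n_train + seq_len(n_validation)],
       test = sets[n_train + n_validation + seq_len(n_test)])
}

#' Write a generated section to disk
#'
#' Writes the imzML/ibd pair, the brightfield PNG, one PNG per ground-truth
#' mask and a delimited ground-truth table into `dir`.
#'
#' @param section a [generate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_section <- function(section, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_imzml(section$dataset, file.path(dir, paste0(section$id, ".imzML")))
  write_optical(section$optical, file.path(dir, paste0(section$id, "_bf.png")))
  all_masks <- c(section$masks$binder, section$masks$pigment,
                 list(section$masks$matrix_mask))
  for (m in all_masks) {
    write_optical(m$raster,
                  file.path(dir, sprintf("%s_mask_%s.png", section$id,
                                         gsub("[^A-Za-z0-9]", "_", m$label))))
  }
  layout <- section$layout
  truth <- data.frame(
    x = rep(seq_len(ncol(layout)), each = nrow(layout)),
    y = rep(seq_len(nrow(layout)), times = ncol(layout)),
    region = as.vector(layout))
  write.table(truth, file.path(dir, paste0(section$id, "_truth.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
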