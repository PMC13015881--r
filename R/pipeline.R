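## End-to-end benchmark pipeline: peak picking -> alignment -> normalization
## -> optical mask extraction and refinement -> balanced sampling ->
## shrinkage selection -> bootstrap LASSO -> GMM gating -> evaluation.
## Mirrors the workflow applied to replica paint boards: training and
## validation sections supervise the model through their brightfield masks;
## the held-out test section is scored against exact ground truth.

#' Subset a multi-dataset feature matrix by dataset id
#'
#' @param fm a [feature_matrix()].
#' @param ids dataset ids to keep.
#' @return a [feature_matrix()] with the selected pixel rows (bins shared).
#' @export
subset_feature_matrix <- function(fm, ids) {
  sel <- fm$pixels$dataset %in% ids
  fail_if(!any(sel), "no pixels for dataset(s) %s", paste(ids, collapse = ", "))
  out <- fm
  out$values <- fm$values[sel, , drop = FALSE]
  out$pixels <- fm$pixels[sel, , drop = FALSE]
  out
}

## Optical-mask supervision for one section: identity landmarks at the grid
## corners stand in for the operator's manual alignment (synthetic optical
## images are already on the MSI grid), then colour thresholding and
## shrink-only refinement against the ion images.
.section_masks <- function(section, fm, refine = TRUE) {
  w <- section$dataset$width; h <- section$dataset$height
  corners <- cbind(x = c(1, w, w, 1), y = c(1, 1, h, h))
  tr <- fit_similarity(corners, corners)
  reg <- apply_transform(section$optical, tr, grid = c(w, h),
                         sentinel = .sentinel_color)
  masks <- extract_masks_color(reg, section$color_specs,
                               sentinel = .sentinel_color)
  if (refine) {
    masks <- refine_masks(subset_feature_matrix(fm, section$id), masks)
  }
  masks
}

#' Run the full composition-prediction benchmark
#'
#' Executes the complete chain on a [generate_benchmark()] result: peak
#' picking (prominence 500, 10 ppm), 10 ppm alignment of the training and
#' validation sections onto one feature axis (the test section keeps its own
#' axis and is matched at prediction time), TIC normalization and per-ion
#' unit scaling, optical mask extraction and refinement, balanced sampling,
#' shrinkage selection on the validation split, bootstrap-averaged LASSO
#' (final fit on training plus validation samples), per-dataset GMMs averaged
#' over the training sections, 0.95 posterior gating, and per-class
#' specificity/sensitivity on the held-out test section against exact ground
#' truth. Binders and pigments are modelled independently (each with the
#' Matrix class), sharing all preprocessing.
#'
#' @param bench a [generate_benchmark()] result.
#' @param config a [model_config()].
#' @param n_per_class balanced-sampling size per class and section.
#' @param bin_ppm alignment bin width, ppm.
#' @param min_prominence,ppm_window peak-picking parameters.
#' @param refine apply regression refinement to the optical masks.
#' @param verbose log progress to stderr.
#' @return list with one element per model (`binder`, `pigment`), each
#'   holding `mu`, `model`, `gmm`, `maps` (classified test predictions) and
#'   `report` (an `evaluation_report`); plus `features` (the train+val
#'   feature matrix) and `features_test`.
#' @export
run_benchmark <- function(bench, config = model_config(), n_per_class = 1000,
                          bin_ppm = 10, min_prominence = 500, ppm_window = 10,
                          refine = TRUE, verbose = FALSE) {
  say <- function(...) if (verbose) log_msg(...)
  trainval <- c(bench$train, bench$validation)
  train_ids <- vapply(bench$train, `[[`, character(1), "id")
  val_ids <- vapply(bench$validation, `[[`, character(1), "id")
  test <- bench$test[[1]]

  say("peak picking (prominence ", min_prominence, ", ", ppm_window, " ppm)")
  peaks_trval <- lapply(trainval, function(s)
    pick_peaks_dataset(s$dataset, min_prominence = min_prominence,
                       ppm_window = ppm_window, id = s$id))
  peaks_test <- pick_peaks_dataset(test$dataset,
                                   min_prominence = min_prominence,
                                   ppm_window = ppm_window, id = test$id)

  say("aligning at ", bin_ppm, " ppm and normalizing")
  fm <- scale_unit(tic_normalize(align_peaks(peaks_trval, bin_ppm)))
  fm_test <- scale_unit(tic_normalize(align_peaks(peaks_test, bin_ppm)))

  say("extracting and refining optical masks")
  opt_masks <- lapply(trainval, .section_masks, fm = fm, refine = refine)
  names(opt_masks) <- vapply(trainval, `[[`, character(1), "id")

  seeds <- derive_seeds(config$seed, length(trainval))
  result <- list(features = fm, features_test = fm_test)
  for (type in c("binder", "pigment")) {
    say("model for ", type, "s")
    samples <- lapply(seq_along(trainval), function(i) {
      s <- sample_balanced(opt_masks[[trainval[[i]]$id]], n_per_class,
                           seed = seeds[i], which = type)
      training_rows(fm, s, trainval[[i]]$id)
    })
    names(samples) <- names(opt_masks)
    train_samples <- do.call(rbind, samples[train_ids])
    val_samples <- do.call(rbind, samples[val_ids])

    fm_val <- subset_feature_matrix(fm, val_ids)
    y_val <- truth_matrix(fm_val, opt_masks, which = type)
    mu <- select_mu(fm, train_samples, fm_val, y_val,
                    grid = config$mu_grid, seed = config$seed)
    say("selected mu = ", as.numeric(mu))

    model <- train_lasso(fm, rbind(train_samples, val_samples), as.numeric(mu),
                         n_bootstrap = config$n_bootstrap, seed = config$seed)

    gmm <- fit_gmm(lapply(train_ids, function(d) {
      sub <- subset_feature_matrix(fm, d)
      list(scores = predict_scores(model, sub)$scores,
           labels = truth_labels(sub, opt_masks, which = type))
    }))

    maps <- classify_pixels(predict_scores(model, fm_test), gmm,
                            threshold = config$posterior_threshold)
    report <- evaluate_predictions(
      maps, setNames(list(test$masks), test$id), fm = fm_test, which = type)
    result[[type]] <- list(mu = mu, model = model, gmm = gmm, maps = maps,
                           report = report, mse = attr(mu, "mse"))
  }
  result
}

#' Headline metrics of a benchmark run
#'
#' Minimum per-class specificity for binders and pigments, and the minimum
#' per-class sensitivity pooled over both, on the held-out section. The
#' Matrix class and classes with undefined metrics (absent from the test
#' section) are excluded from the minima.
#'
#' @param res a [run_benchmark()] result.
#' @return list with `binder_specificity_min`, `pigment_specificity_min`,
#'   `sensitivity_min`, and `n_test_pixels`.
#' @export
benchmark_metrics <- function(res) {
  pick <- function(report) report[report$class != "Matrix", ]
  b <- pick(res$binder$report)
  p <- pick(res$pigment$report)
  sens <- c(b$sensitivity, p$sensitivity)
  list(binder_specificity_min = min(b$specificity, na.rm = TRUE),
       pigment_specificity_min = min(p$specificity, na.rm = TRUE),
       sensitivity_min = min(sens, na.rm = TRUE),
       n_test_pixels = attr(res$binder$report, "n_evaluated"))
}

#' Planted-ion recovery of a trained model
#'
#' For each class, the fraction of its planted signature ion species that
#' carry nonzero averaged LASSO weight. Recovery is counted per ion species
#' (group): the isotopologues of one metal species are perfectly collinear
#' ion images, and a sparse model keeps at least one column of a collinear
#' set rather than all of them, so a species counts as recovered when any
#' of its isotopologues is selected. Planted ions below `min_intensity`
#' (undetectable at the peak-picking prominence) are excluded.
#'
#' @param model a `lasso_model`.
#' @param library the [signature_library()] the data came from.
#' @param min_intensity detectability threshold on planted mean intensity
#'   (default 500, the standard prominence cutoff).
#' @param tol_ppm m/z match tolerance between planted ions and feature bins.
#' @return data.frame with `class`, `n_planted`, `n_recovered`, `fraction`.
#' @export
signature_recovery <- function(model, library, min_intensity = 500,
                               tol_ppm = 10) {
  cls <- intersect(model$classes, library$classes$class)
  cls <- setdiff(cls, "Matrix")
  rows <- lapply(cls, function(k) {
    planted <- library$ions[[k]]
    planted <- planted[planted$intensity >= min_intensity, ]
    nz <- model$feature_mz[model$coefficients[, k] != 0]
    hit <- vapply(planted$mz, function(m)
      length(nz) > 0 && any(abs(nz - m) <= ppm_tol(m, tol_ppm)), logical(1))
    by_group <- tapply(hit, planted$group, any)
    data.frame(class = k, n_planted = length(by_group),
               n_recovered = sum(by_group),
               fraction = mean(by_group))
  })
  do.call(rbind, rows)
}

#' Reference synthetic benchmark
#'
#' The package's standard validation setting: the default signature library
#' (4 binders, 5 pigments, 15 signature ions per class), 6 training, 2
#' validation and 1 test sections of 64 x 64 pixels with 200 background
#' ions, all seeded from one master seed (42 by convention).
#'
#' @param seed master seed.
#' @param n_train,n_validation,n_test dataset counts.
#' @param grid section dimensions.
#' @return a [generate_benchmark()] result.
#' @export
default_benchmark <- function(seed = 42, n_train = 6, n_validation = 2,
                              n_test = 1, grid = c(64, 64)) {
  lib <- signature_library(seed = seed)
  generate_benchmark(lib, n_train = n_train, n_validation = n_validation,
                     n_test = n_test, grid = grid, seed = seed)
}
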