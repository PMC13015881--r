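## Composition classifier: per-class one-vs-rest LASSO on ion images with
## shrinkage selection on a validation split, bootstrap coefficient
## averaging, a per-class Gaussian model on prediction scores that converts
## scores into posteriors, gating of low-confidence pixels into an
## "Uncertain" class, and specificity/sensitivity evaluation.

#' Classifier configuration
#'
#' Bundles the tunable parameters of the composition model. The default
#' shrinkage grid, 10 bootstrap repetitions and the 0.95 posterior threshold
#' are the standard operating point for paint cross sections.
#'
#' @param mu shrinkage parameter; NULL until selected via [select_mu()].
#' @param mu_grid candidate shrinkage values.
#' @param n_bootstrap bootstrap repetitions for coefficient averaging.
#' @param posterior_threshold minimum class posterior below which a pixel is
#'   Uncertain.
#' @param seed RNG seed for resampling.
#' @return list of class `"model_config"`.
#' @export
model_config <- function(mu = NULL,
                         mu_grid = c(5e-5, 1e-4, 5e-4, 1e-3, 2e-3, 3e-3,
                                     4e-3, 5e-3, 1e-2, 5e-2),
                         n_bootstrap = 10, posterior_threshold = 0.95,
                         seed = 1) {
  fail_if(!is.null(mu) && mu <= 0, "mu must be positive")
  fail_if(posterior_threshold <= 0 || posterior_threshold > 1,
          "posterior_threshold must lie in (0, 1]")
  structure(list(mu = mu, mu_grid = mu_grid, n_bootstrap = n_bootstrap,
                 posterior_threshold = posterior_threshold, seed = seed),
            class = "model_config")
}

## The label used for gated pixels.
.uncertain <- "Uncertain"

## One-vs-rest L1 fit of every class at fixed shrinkage mu.
## Objective per class: (1/2n) sum (y - b0 - Xb)^2 + mu * sum|b|,
## which is glmnet's gaussian objective with standardize = FALSE.
.fit_classes <- function(X, labels, classes, mu) {
  ## a short warm-start path ending exactly at mu stabilizes the solver
  path <- mu * c(16, 8, 4, 2, 1)
  coefs <- matrix(0, ncol(X), length(classes),
                  dimnames = list(NULL, classes))
  intercepts <- setNames(numeric(length(classes)), classes)
  for (k in classes) {
    y <- as.numeric(labels == k)
    fit <- glmnet::glmnet(X, y, family = "gaussian", alpha = 1,
                          lambda = path, standardize = FALSE)
    b <- as.numeric(glmnet::coef.glmnet(fit, s = mu, exact = FALSE))
    intercepts[k] <- b[1]
    coefs[, k] <- b[-1]
  }
  list(coefficients = coefs, intercepts = intercepts)
}

#' Train the bootstrap-averaged LASSO model
#'
#' Per class, an L1-penalized least-squares fit of the 0/1 class indicator
#' on the (TIC-normalized, unit-scaled) feature matrix. The training pairs
#' are resampled with replacement within each class (class-balanced
#' bootstrap) `n_bootstrap` times; coefficient vectors and intercepts are
#' averaged elementwise across repetitions. Deterministic under `seed`.
#'
#' @param x a [feature_matrix()].
#' @param samples data.frame with columns `row` (row index into `x`) and
#'   `label`; see [training_rows()].
#' @param mu shrinkage parameter.
#' @param n_bootstrap bootstrap repetitions (set 1 to disable resampling
#'   beyond a single fit on the original sample).
#' @param seed RNG seed.
#' @return object of class `"lasso_model"` with `classes`, `coefficients`
#'   (bins x classes), `intercepts`, `feature_mz`, `mu`.
#' @export
train_lasso <- function(x, samples, mu, n_bootstrap = 10, seed = 1) {
  fail_if(mu <= 0, "mu must be positive")
  classes <- if (is.factor(samples$label)) levels(droplevels(samples$label))
             else sort(unique(samples$label))
  fail_if(length(classes) < 2, "need at least 2 classes")
  sizes <- table(samples$label)
  fail_if(any(sizes < 2), "singleton class '%s'",
          names(sizes)[which(sizes < 2)[1]])
  X <- x$values[samples$row, , drop = FALSE]
  labels <- as.character(samples$label)
  by_class <- split(seq_along(labels), labels)

  acc_coef <- matrix(0, ncol(X), length(classes),
                     dimnames = list(NULL, classes))
  acc_int <- setNames(numeric(length(classes)), classes)
  with_seed(seed, {
    for (b in seq_len(n_bootstrap)) {
      idx <- if (n_bootstrap == 1) seq_along(labels) else
        unlist(lapply(by_class, function(i)
          i[sample.int(length(i), length(i), replace = TRUE)]),
          use.names = FALSE)
      fit <- .fit_classes(X[idx, , drop = FALSE], labels[idx], classes, mu)
      acc_coef <- acc_coef + fit$coefficients
      acc_int <- acc_int + fit$intercepts
    }
  })
  structure(list(classes = classes,
                 coefficients = acc_coef / n_bootstrap,
                 intercepts = acc_int / n_bootstrap,
                 feature_mz = x$bin_mz, mu = mu,
                 n_bootstrap = n_bootstrap, seed = seed),
            class = "lasso_model")
}

#' @export
print.lasso_model <- function(x, ...) {
  cat(sprintf(
    "<lasso_model> %d classes (%s), %d features, mu = %g, %d nonzero coefs\n",
    length(x$classes), paste(x$classes, collapse = ", "),
    length(x$feature_mz), x$mu, sum(x$coefficients != 0)))
  invisible(x)
}

#' Helper: turn a balanced pixel sample into feature-matrix rows
#'
#' Maps per-dataset (pixel, label) samples from [sample_balanced()] onto row
#' indices of an aligned multi-dataset feature matrix.
#'
#' @param fm the [feature_matrix()].
#' @param samples data.frame from [sample_balanced()].
#' @param dataset the dataset id the samples refer to.
#' @return data.frame with columns `row`, `label`.
#' @export
training_rows <- function(fm, samples, dataset) {
  sel <- fm$pixels$dataset == dataset
  fail_if(!any(sel), "dataset '%s' not present in feature matrix", dataset)
  key <- paste(fm$pixels$x[sel], fm$pixels$y[sel])
  rows <- which(sel)[match(paste(samples$x, samples$y), key)]
  fail_if(anyNA(rows), "sampled pixels missing from the feature matrix")
  data.frame(row = rows, label = samples$label)
}

#' Select the shrinkage parameter on a validation split
#'
#' For each candidate, a (non-bootstrapped) model is trained on the training
#' sample and the mean squared error between the predicted class-score
#' images and the 0/1 validation mask images is computed, pooled over all
#' classes and validation pixels; the candidate with minimal MSE wins, ties
#' broken toward the larger (sparser) value. This exhaustive grid evaluation
#' is the selection rule by definition.
#'
#' @param x training [feature_matrix()].
#' @param samples training pairs (`row`, `label`).
#' @param x_val validation [feature_matrix()].
#' @param y_val validation 0/1 truth, pixels x classes (see [truth_matrix()]).
#' @param grid candidate shrinkage values.
#' @param per_class if TRUE, MSE is averaged per class before pooling.
#' @param seed RNG seed (unused when n_bootstrap is 1, kept for signature
#'   stability).
#' @return the selected mu; the full MSE table is in `attr(, "mse")`.
#' @export
select_mu <- function(x, samples, x_val, y_val,
                      grid = model_config()$mu_grid, per_class = FALSE,
                      seed = 1) {
  fail_if(length(grid) == 0, "empty mu grid")
  mse <- vapply(grid, function(mu) {
    m <- train_lasso(x, samples, mu, n_bootstrap = 1, seed = seed)
    sc <- predict_scores(m, x_val)$scores
    common <- intersect(colnames(y_val), colnames(sc))
    fail_if(length(common) == 0, "no common classes with validation truth")
    d <- (sc[, common, drop = FALSE] - y_val[, common, drop = FALSE])^2
    if (per_class) mean(colMeans(d)) else mean(d)
  }, numeric(1))
  best <- max(grid[mse <= min(mse) + 1e-15]) # ties toward larger mu
  structure(best, mse = data.frame(mu = grid, mse = mse))
}

#' Build the pixels x classes 0/1 truth matrix for one model
#'
#' @param fm the [feature_matrix()] whose pixel rows define the row order.
#' @param mask_sets named list (by dataset id) of [mask_set()]s.
#' @param which `"binder"` or `"pigment"`.
#' @return numeric matrix, one column per class (Matrix included).
#' @export
truth_matrix <- function(fm, mask_sets, which = c("binder", "pigment")) {
  which <- match.arg(which)
  labels <- truth_labels(fm, mask_sets, which)
  classes <- sort(unique(labels[!is.na(labels)]))
  out <- matrix(0, nrow(fm$values), length(classes),
                dimnames = list(NULL, classes))
  for (k in classes) out[, k] <- as.numeric(!is.na(labels) & labels == k)
  out
}

#' Ground-truth class label per feature-matrix pixel
#'
#' @inheritParams truth_matrix
#' @return character vector (NA for unlabelled pixels such as voids).
#' @export
truth_labels <- function(fm, mask_sets, which = c("binder", "pigment")) {
  which <- match.arg(which)
  labels <- rep(NA_character_, nrow(fm$values))
  for (d in unique(fm$pixels$dataset)) {
    ms <- mask_sets[[d]]
    fail_if(is.null(ms), "no mask set for dataset '%s'", d)
    sel <- which(fm$pixels$dataset == d)
    at <- cbind(fm$pixels$y[sel], fm$pixels$x[sel])
    group <- c(ms[[which]],
               if (!is.null(ms$matrix_mask)) list(ms$matrix_mask))
    for (m in group) labels[sel[m$raster[at]]] <- m$label
  }
  labels
}

#' Predict class scores for every pixel
#'
#' `score(pixel, class) = intercept + <coefficients, pixel features>`.
#' Model features are matched to the data's bins by m/z within
#' `match_tol_ppm`; model bins absent from the data contribute zero (their
#' ions were not observed). If no model bin can be matched at all the axes
#' are incompatible and an error is raised.
#'
#' @param model a [train_lasso()] model.
#' @param x a [feature_matrix()] (same preprocessing as training).
#' @param match_tol_ppm bin-matching tolerance, ppm.
#' @return object of class `"prediction_maps"` with `scores`
#'   (pixels x classes), `classes`, `pixels`; posteriors and assignments are
#'   filled by [classify_pixels()].
#' @export
predict_scores <- function(model, x, match_tol_ppm = 10) {
  j <- vapply(model$feature_mz, function(m) {
    d <- abs(x$bin_mz - m)
    jj <- which.min(d)
    if (length(jj) && d[jj] <= ppm_tol(m, match_tol_ppm)) jj else NA_integer_
  }, integer(1))
  fail_if(all(is.na(j)),
          "feature axes incompatible: none of %d model bins match the data",
          length(model$feature_mz))
  keep <- !is.na(j)
  Xm <- x$values[, j[keep], drop = FALSE]
  sc <- as.matrix(Xm %*% model$coefficients[keep, , drop = FALSE])
  sc <- sweep(sc, 2, model$intercepts, `+`)
  colnames(sc) <- model$classes
  structure(list(scores = sc, classes = model$classes, pixels = x$pixels,
                 posterior = NULL, assignment = NULL,
                 unmatched_bins = model$feature_mz[!keep]),
            class = "prediction_maps")
}

#' @export
print.prediction_maps <- function(x, ...) {
  cat(sprintf("<prediction_maps> %d pixels x %d classes%s\n",
              nrow(x$scores), length(x$classes),
              if (is.null(x$assignment)) " (scores only)" else ""))
  invisible(x)
}

#' Fit the per-class Gaussian score model
#'
#' Per training dataset, one Gaussian per class is fit to the score vectors
#' of that class's true pixels; the final model averages means and
#' covariances parameter-wise across the datasets in which the class occurs
#' (covariances regularized by +1e-6 on the diagonal). Class priors are
#' uniform: balanced sampling removed prevalence information.
#'
#' @param training_predictions list with one element per training dataset;
#'   each a list with `scores` (pixels x classes) and `labels` (character,
#'   NA allowed).
#' @return object of class `"gmm_model"`.
#' @export
fit_gmm <- function(training_predictions) {
  fail_if(length(training_predictions) == 0, "no training predictions")
  classes <- colnames(training_predictions[[1]]$scores)
  k <- length(classes)
  means <- covs <- setNames(vector("list", k), classes)
  n_sets <- setNames(integer(k), classes)
  for (tp in training_predictions) {
    for (cl in classes) {
      rows <- which(!is.na(tp$labels) & tp$labels == cl)
      if (length(rows) < 2) next
      s <- tp$scores[rows, , drop = FALSE]
      mu <- colMeans(s)
      sg <- cov(s)
      if (n_sets[cl] == 0) {
        means[[cl]] <- mu; covs[[cl]] <- sg
      } else {
        means[[cl]] <- means[[cl]] + mu; covs[[cl]] <- covs[[cl]] + sg
      }
      n_sets[cl] <- n_sets[cl] + 1L
    }
  }
  absent <- classes[n_sets == 0]
  fail_if(length(absent) > 0,
          "class(es) absent from all training datasets: %s",
          paste(absent, collapse = ", "))
  for (cl in classes) {
    means[[cl]] <- means[[cl]] / n_sets[cl]
    covs[[cl]] <- covs[[cl]] / n_sets[cl] + diag(1e-6, k)
  }
  structure(list(classes = classes, means = means, covariances = covs,
                 weights = setNames(rep(1 / k, k), classes)),
            class = "gmm_model")
}

## Log density of rows of x under a multivariate Gaussian.
.dmvnorm_log <- function(x, mean, sigma) {
  ch <- chol(sigma)
  z <- forwardsolve(t(ch), t(x) - mean)
  -0.5 * colSums(z^2) - sum(log(diag(ch))) - 0.5 * ncol(x) * log(2 * pi)
}

#' Gate predictions through the Gaussian score model
#'
#' Posterior probabilities follow Bayes' rule under uniform class priors;
#' a pixel is assigned its argmax class when the maximum posterior reaches
#' `threshold`, otherwise it is placed in the Uncertain class. Argmax ties
#' break toward the earlier class in the model's class order.
#'
#' @param maps a [predict_scores()] result.
#' @param gmm a [fit_gmm()] model.
#' @param threshold posterior threshold (default 0.95).
#' @return `maps` with `posterior` (rows sum to 1) and `assignment` filled.
#' @export
classify_pixels <- function(maps, gmm, threshold = 0.95) {
  fail_if(threshold < 0 || threshold > 1, "threshold must lie in [0, 1]")
  fail_if(!identical(colnames(maps$scores), gmm$classes),
          "score classes do not match the GMM classes")
  logd <- vapply(gmm$classes, function(cl)
    .dmvnorm_log(maps$scores, gmm$means[[cl]], gmm$covariances[[cl]]),
    numeric(nrow(maps$scores)))
  logd <- matrix(logd, ncol = length(gmm$classes),
                 dimnames = list(NULL, gmm$classes))
  m <- apply(logd, 1, max)
  p <- exp(logd - m)
  post <- p / rowSums(p)
  best <- max.col(post, ties.method = "first")
  maxp <- post[cbind(seq_len(nrow(post)), best)]
  maps$posterior <- post
  maps$assignment <- ifelse(maxp >= threshold, gmm$classes[best], .uncertain)
  maps$threshold <- threshold
  maps
}

#' Specificity / sensitivity evaluation against ground truth
#'
#' One-vs-rest confusion counts per class over pixels that have a
#' ground-truth label and were not gated Uncertain; sensitivity is
#' TP/(TP+FN), specificity TN/(TN+FP), both in percent.
#'
#' @param pred a classified [prediction_maps] (assignments filled).
#' @param truth ground-truth labels: a character vector per pixel (NA =
#'   unlabelled), or a named list of [mask_set()]s with `which` given.
#' @param fm,which used when `truth` is a list of mask sets.
#' @return data.frame of class `"evaluation_report"`: per class TP, FP, TN,
#'   FN, sensitivity, specificity; attribute `n_uncertain` counts gated
#'   labelled pixels.
#' @export
evaluate_predictions <- function(pred, truth, fm = NULL,
                                 which = c("binder", "pigment")) {
  fail_if(is.null(pred$assignment), "predictions not classified yet")
  if (!is.character(truth)) {
    which <- match.arg(which)
    fail_if(is.null(fm), "fm is required when truth is a mask-set list")
    truth <- truth_labels(fm, truth, which)
  }
  fail_if(length(truth) != nrow(pred$scores),
          "truth length does not match prediction grid")
  labelled <- !is.na(truth)
  confident <- pred$assignment != .uncertain
  use <- labelled & confident
  fail_if(!any(use), "no labelled, non-Uncertain pixels to evaluate")
  classes <- pred$classes
  rows <- lapply(classes, function(k) {
    tp <- sum(use & truth == k & pred$assignment == k)
    fp <- sum(use & truth != k & pred$assignment == k)
    fn <- sum(use & truth == k & pred$assignment != k)
    tn <- sum(use & truth != k & pred$assignment != k)
    data.frame(class = k, TP = tp, FP = fp, TN = tn, FN = fn,
               sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
               specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_)
  })
  out <- do.call(rbind, rows)
  attr(out, "n_uncertain") <- sum(labelled & !confident)
  attr(out, "n_evaluated") <- sum(use)
  class(out) <- c("evaluation_report", "data.frame")
  out
}

#' Serialize / restore a trained model pair as portable JSON
#'
#' Stores the LASSO coefficients and the Gaussian score model with
#' full-precision numbers so restored models predict identically.
#'
#' @param model a `lasso_model`.
#' @param gmm a `gmm_model` (optional).
#' @param path JSON path.
#' @return `path` (write) / list with `model` and `gmm` (read).
#' @export
write_model <- function(model, gmm = NULL, path) {
  payload <- list(
    format = "paintmsi-model", version = 1L,
    model = list(classes = model$classes,
                 coefficients = as.matrix(model$coefficients),
                 intercepts = model$intercepts,
                 feature_mz = model$feature_mz, mu = model$mu,
                 n_bootstrap = model$n_bootstrap, seed = model$seed),
    gmm = if (!is.null(gmm)) list(classes = gmm$classes, means = gmm$means,
                                  covariances = gmm$covariances))
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fail_if(!identical(p$format, "paintmsi-model"), "not a paintmsi model file")
  m <- p$model
  coefs <- as.matrix(m$coefficients)
  colnames(coefs) <- m$classes
  model <- structure(list(classes = m$classes, coefficients = coefs,
                          intercepts = setNames(as.numeric(m$intercepts),
                                                m$classes),
                          feature_mz = m$feature_mz, mu = m$mu,
                          n_bootstrap = m$n_bootstrap, seed = m$seed),
                     class = "lasso_model")
  gmm <- NULL
  if (!is.null(p$gmm) && length(p$gmm) > 0) {
    k <- length(p$gmm$classes)
    gmm <- structure(list(
      classes = p$gmm$classes,
      means = lapply(p$gmm$means, function(v) setNames(as.numeric(v),
                                                       p$gmm$classes)),
      covariances = lapply(p$gmm$covariances, as.matrix),
      weights = setNames(rep(1 / k, k), p$gmm$classes)),
      class = "gmm_model")
  }
  list(model = model, gmm = gmm)
}
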