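## Brightfield-to-MSI registration (closed-form similarity fit on landmark
## pairs), colour-threshold mask extraction, regression-based mask
## refinement, and balanced training-pixel sampling.
##
## Points are (x, y) pairs with x the column and y the row, 1-based, in the
## coordinate frame of the respective image.

#' Fit a similarity transform from landmark pairs
#'
#' Least-squares similarity transform (uniform scale, rotation, translation;
#' no reflection) mapping `source_points` onto `target_points`, computed in
#' closed form (Procrustes/Umeyama estimate). This is the reproducible
#' surrogate for manual co-registration: the user supplies corresponding
#' landmarks instead of dragging images.
#'
#' @param source_points,target_points n x 2 matrices or data.frames of (x, y)
#'   pairs, n >= 2.
#' @return object of class `"similarity_transform"` with fields `scale`,
#'   `rotation` (radians), `translation` (length-2), and `residual`
#'   (root-mean-square target residual).
#' @export
fit_similarity <- function(source_points, target_points) {
  s <- as.matrix(source_points); t <- as.matrix(target_points)
  fail_if(nrow(s) != nrow(t) || ncol(s) != 2 || ncol(t) != 2,
          "need matching n x 2 point sets")
  fail_if(nrow(s) < 2, "need at least 2 point pairs")
  mu_s <- colMeans(s); mu_t <- colMeans(t)
  sc <- sweep(s, 2, mu_s); tc <- sweep(t, 2, mu_t)
  var_s <- sum(sc^2)
  fail_if(var_s < 1e-12, "degenerate configuration: coincident source points")
  S <- crossprod(tc, sc) / nrow(s)
  sv <- svd(S)
  d <- sign(det(sv$u %*% t(sv$v)))
  D <- diag(c(1, d))
  R <- sv$u %*% D %*% t(sv$v)
  scale <- sum(sv$d * diag(D)) * nrow(s) / var_s
  translation <- as.numeric(mu_t - scale * R %*% mu_s)
  fitted <- sweep(scale * s %*% t(R), 2, translation, `+`)
  structure(list(scale = scale, rotation = atan2(R[2, 1], R[1, 1]),
                 translation = translation,
                 residual = sqrt(mean((fitted - t)^2))),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat(sprintf(
    "<similarity_transform> scale %.6g, rotation %.6g rad, translation (%.6g, %.6g), rms %.3g\n",
    x$scale, x$rotation, x$translation[1], x$translation[2], x$residual))
  invisible(x)
}

## Rotation matrix of a transform.
.rot_mat <- function(t) {
  matrix(c(cos(t$rotation), sin(t$rotation),
           -sin(t$rotation), cos(t$rotation)), 2, 2)
}

#' Apply a similarity transform to points
#'
#' @param transform a `similarity_transform`.
#' @param points n x 2 matrix of (x, y) points in the source frame.
#' @return n x 2 matrix in the target frame.
#' @export
transform_points <- function(transform, points) {
  p <- as.matrix(points)
  sweep(transform$scale * p %*% t(.rot_mat(transform)), 2,
        transform$translation, `+`)
}

#' Resample an optical image onto the MSI grid
#'
#' Nearest-neighbour resampling of the source image through the similarity
#' transform onto a `grid = c(width, height)` raster. Target pixels mapping
#' outside the source image are filled with the sentinel colour (which
#' downstream marks off-sample/Matrix pixels). Nearest-neighbour keeps
#' colour-threshold masks binary.
#'
#' @param image an [optical_image()].
#' @param transform a `similarity_transform` mapping source (x, y) to target
#'   grid (x, y).
#' @param grid target dimensions `c(width, height)`.
#' @param sentinel RGB triple used for out-of-bounds pixels.
#' @return height x width x 3 raster with attribute `"sentinel"`.
#' @export
apply_transform <- function(image, transform, grid,
                            sentinel = c(255, 0, 255)) {
  w <- grid[1]; h <- grid[2]
  src <- image$raster
  sh <- dim(src)[1]; sw <- dim(src)[2]
  tg <- as.matrix(expand.grid(x = seq_len(w), y = seq_len(h)))
  ## invert: p_src = R^-1 (p_tgt - translation) / scale
  R <- .rot_mat(transform)
  p <- sweep(tg, 2, transform$translation)
  p <- p %*% R / transform$scale # (R^-1)^T = R, applied from the right
  sx <- round(p[, 1]); sy <- round(p[, 2])
  inb <- sx >= 1 & sx <= sw & sy >= 1 & sy <= sh
  out <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    plane <- matrix(sentinel[ch], h, w)
    vals <- src[cbind(sy[inb], sx[inb], ch)]
    plane[cbind(tg[inb, 2], tg[inb, 1])] <- vals
    out[, , ch] <- plane
  }
  attr(out, "sentinel") <- sentinel
  out
}

#' Construct a class mask
#'
#' @param label class name.
#' @param raster logical height x width matrix.
#' @param type `"binder"`, `"pigment"` or `"matrix"`.
#' @return object of class `"class_mask"`.
#' @export
class_mask <- function(label, raster, type = c("binder", "pigment", "matrix")) {
  type <- match.arg(type)
  fail_if(!is.logical(raster) || !is.matrix(raster),
          "raster must be a logical matrix")
  structure(list(label = label, raster = raster, type = type),
            class = "class_mask")
}

#' Construct a mask set
#'
#' Binder masks must be pairwise disjoint, likewise pigment masks; the
#' Matrix (off-sample) mask must be disjoint from all others. Binder and
#' pigment masks may overlap each other (a paint layer carries one of each).
#'
#' @param binder,pigment lists of [class_mask()].
#' @param matrix_mask a [class_mask()] of type `"matrix"`, or NULL.
#' @return object of class `"mask_set"`.
#' @export
mask_set <- function(binder = list(), pigment = list(), matrix_mask = NULL) {
  check_disjoint <- function(masks, what) {
    if (length(masks) < 2) return(invisible())
    acc <- masks[[1]]$raster
    for (m in masks[-1]) {
      fail_if(any(acc & m$raster), "%s masks are not pairwise disjoint", what)
      acc <- acc | m$raster
    }
  }
  check_disjoint(binder, "binder")
  check_disjoint(pigment, "pigment")
  if (!is.null(matrix_mask)) {
    for (m in c(binder, pigment)) {
      fail_if(any(matrix_mask$raster & m$raster),
              "matrix mask overlaps class '%s'", m$label)
    }
  }
  structure(list(binder = binder, pigment = pigment,
                 matrix_mask = matrix_mask), class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set> %d binder, %d pigment%s\n", length(x$binder),
              length(x$pigment),
              if (is.null(x$matrix_mask)) "" else ", with Matrix mask"))
  invisible(x)
}

## Pull the mask of one label/type pair; NULL when absent.
mask_lookup <- function(masks, label, type) {
  if (type == "matrix") return(masks$matrix_mask)
  for (m in masks[[type]]) if (m$label == label) return(m)
  NULL
}

#' Extract class masks from a registered image by colour thresholding
#'
#' A pixel belongs to a class when every channel is within that class's
#' per-channel tolerance of the class colour centre. Multiple spec rows may
#' share a label (their pixels are unioned). Pixels equal to the sentinel
#' colour form the Matrix mask; on-sample pixels matching no spec stay
#' unlabelled.
#'
#' @param registered raster from [apply_transform()] (h x w x 3).
#' @param color_specs data.frame with columns `label`, `type` ("binder" or
#'   "pigment"), `r`, `g`, `b`, `tol`.
#' @param sentinel RGB triple of the off-sample colour; defaults to the
#'   raster's `"sentinel"` attribute.
#' @return a [mask_set()].
#' @export
extract_masks_color <- function(registered, color_specs, sentinel = NULL) {
  if (is.null(sentinel)) sentinel <- attr(registered, "sentinel")
  fail_if(is.null(sentinel), "sentinel colour unknown")
  cs <- color_specs
  need <- c("label", "type", "r", "g", "b", "tol")
  fail_if(!all(need %in% names(cs)), "color_specs needs columns: %s",
          paste(need, collapse = ", "))
  ## overlapping colour boxes between different labels of one problem
  ## (binder or pigment) are a config error; cross-type sharing is fine -
  ## one paint layer carries one binder and one pigment in the same colour
  if (nrow(cs) > 1) {
    for (i in seq_len(nrow(cs) - 1)) for (j in (i + 1):nrow(cs)) {
      if (cs$type[i] != cs$type[j]) next
      if (cs$label[i] == cs$label[j]) next
      ov <- all(abs(c(cs$r[i] - cs$r[j], cs$g[i] - cs$g[j],
                      cs$b[i] - cs$b[j])) <= cs$tol[i] + cs$tol[j])
      fail_if(ov, "colour specs for '%s' and '%s' overlap in colour space",
              cs$label[i], cs$label[j])
    }
  }
  h <- dim(registered)[1]; w <- dim(registered)[2]
  in_box <- function(center, tol) {
    abs(registered[, , 1] - center[1]) <= tol &
      abs(registered[, , 2] - center[2]) <= tol &
      abs(registered[, , 3] - center[3]) <= tol
  }
  is_sentinel <- in_box(sentinel, 0)
  build <- function(type) {
    labels <- unique(cs$label[cs$type == type])
    lapply(labels, function(lb) {
      rows <- which(cs$label == lb & cs$type == type)
      acc <- matrix(FALSE, h, w)
      for (i in rows) {
        acc <- acc | in_box(c(cs$r[i], cs$g[i], cs$b[i]), cs$tol[i])
      }
      class_mask(lb, acc & !is_sentinel, type)
    })
  }
  mask_set(binder = build("binder"), pigment = build("pigment"),
           matrix_mask = class_mask("Matrix", is_sentinel, "matrix"))
}

#' Refine an optical mask against the ion images
#'
#' Ordinary least squares of the 0/1 mask on all ion images; fitted values
#' are thresholded at 0.5 and the result may only remove pixels from the
#' optical mask, never add any (a shrink-only rule that stops regression
#' artifacts from leaking labels into neighbouring layers). Pixels the ions
#' cannot explain - e.g. voids under an overhanging optical mask - are
#' dropped.
#'
#' @param fm a single-dataset [feature_matrix()].
#' @param mask a [class_mask()] on the same grid.
#' @param threshold fitted-value threshold (default 0.5).
#' @return the refined [class_mask()].
#' @export
refine_mask <- function(fm, mask, threshold = 0.5) {
  fail_if(!any(mask$raster), "mask is empty")
  fitted <- .mask_fitted_values(fm, mask$raster)
  if (is.null(fitted)) {
    warning("all-zero feature matrix; mask returned unchanged")
    return(mask)
  }
  keep <- mask$raster
  keep[cbind(fm$pixels$y, fm$pixels$x)] <-
    mask$raster[cbind(fm$pixels$y, fm$pixels$x)] & (fitted >= threshold)
  class_mask(mask$label, keep, mask$type)
}

## OLS fitted values of a 0/1 raster on the ion images, via the normal
## equations with a vanishing ridge (numerical guard only). The Cholesky
## factor is cached on the feature matrix environment by .mask_solver so
## refining many masks of one dataset factors X'X once.
.mask_fitted_values <- function(fm, raster) {
  solver <- .mask_solver(fm)
  if (is.null(solver)) return(NULL)
  y <- as.numeric(raster[cbind(fm$pixels$y, fm$pixels$x)])
  solver(y)
}

.mask_solver <- function(fm) {
  if (!length(fm$values@x) || all(fm$values@x == 0)) return(NULL)
  cache <- attr(fm, ".solver_cache")
  if (!is.null(cache)) return(cache)
  X <- fm$values
  n <- nrow(X)
  xtx <- as.matrix(Matrix::crossprod(X))
  cm <- Matrix::colSums(X)
  A <- rbind(c(n, cm), cbind(cm, xtx)) # intercept-augmented normal matrix
  diag(A) <- diag(A) + 1e-8 * mean(diag(A))
  ch <- chol(A)
  function(y) {
    b <- c(sum(y), as.numeric(Matrix::crossprod(X, y)))
    beta <- backsolve(ch, forwardsolve(t(ch), b))
    as.numeric(beta[1] + X %*% beta[-1])
  }
}

## Refine every mask of a set, sharing one factorization.
refine_masks <- function(fm, masks, threshold = 0.5) {
  attr(fm, ".solver_cache") <- .mask_solver(fm)
  ref <- function(m) if (is.null(m) || !any(m$raster)) m
                     else refine_mask(fm, m, threshold)
  mask_set(binder = lapply(masks$binder, ref),
           pigment = lapply(masks$pigment, ref),
           matrix_mask = masks$matrix_mask)
}

#' Sample a balanced training set from a mask set
#'
#' Draws `min(n_per_class, class size)` pixels per class without
#' replacement, the same count target for every class, reproducibly under
#' `seed`. Empty classes are skipped with a warning.
#'
#' @param masks a [mask_set()].
#' @param n_per_class pixels per class (default 1000).
#' @param seed RNG seed.
#' @param which `"binder"` or `"pigment"`: which classification problem the
#'   sample is for; the Matrix mask is included in both.
#' @return data.frame with columns `pixel` (row-major index), `x`, `y`,
#'   `label`.
#' @export
sample_balanced <- function(masks, n_per_class = 1000, seed = 1,
                            which = c("binder", "pigment")) {
  which <- match.arg(which)
  fail_if(n_per_class < 1, "n_per_class must be >= 1")
  class_masks <- masks[[which]]
  if (!is.null(masks$matrix_mask)) {
    class_masks <- c(class_masks, list(masks$matrix_mask))
  }
  out <- list()
  with_seed(seed, {
    for (m in class_masks) {
      idx <- which(t(m$raster)) # row-major (y, x) pixel index
      if (length(idx) == 0) {
        warning(sprintf("class '%s' has no pixels; skipped", m$label))
        next
      }
      take <- sample(idx, min(n_per_class, length(idx)))
      w <- ncol(m$raster)
      out[[length(out) + 1]] <- data.frame(
        pixel = take, x = (take - 1) %% w + 1, y = (take - 1) %/% w + 1,
        label = m$label)
    }
  })
  do.call(rbind, out)
}
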