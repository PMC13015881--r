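## LASSO training, shrinkage selection, GMM gating, evaluation.

test_that("an informative binary ion is recovered, noise ions dropped", {
  toy <- toy_training()
  m <- train_lasso(toy$fm, toy$samples, mu = 1e-4, n_bootstrap = 3, seed = 1)
  for (i in seq_along(toy$classes)) {
    coefs <- m$coefficients[, toy$classes[i]]
    expect_gt(coefs[i], 0.5)
    ## all noise-ion coefficients exactly zero under the L1 penalty
    expect_true(all(coefs[-seq_along(toy$classes)] == 0))
  }
})

test_that("full shrinkage collapses to intercept = class prevalence", {
  toy <- toy_training(k = 2)
  m <- train_lasso(toy$fm, toy$samples, mu = 10, n_bootstrap = 1, seed = 1)
  expect_true(all(m$coefficients == 0))
  expect_equal(unname(m$intercepts["class1"]), 0.5, tolerance = 1e-9)
})

test_that("training is deterministic under a fixed seed and errors early", {
  toy <- toy_training()
  m1 <- train_lasso(toy$fm, toy$samples, 1e-3, n_bootstrap = 4, seed = 7)
  m2 <- train_lasso(toy$fm, toy$samples, 1e-3, n_bootstrap = 4, seed = 7)
  expect_identical(m1, m2)

  one <- toy$samples[toy$samples$label == "class1", ]
  expect_error(train_lasso(toy$fm, one, 1e-3), "2 classes")
  singleton <- rbind(toy$samples[toy$samples$label == "class1", ],
                     toy$samples[toy$samples$label == "class2", ][1, ])
  expect_error(train_lasso(toy$fm, singleton, 1e-3), "singleton")
})

test_that("coefficient support is monotone in the shrinkage", {
  toy <- toy_training(n_noise = 10)
  m_lo <- train_lasso(toy$fm, toy$samples, 5e-5, n_bootstrap = 1, seed = 1)
  m_hi <- train_lasso(toy$fm, toy$samples, 5e-2, n_bootstrap = 1, seed = 1)
  expect_lte(sum(m_hi$coefficients != 0), sum(m_lo$coefficients != 0))
})

test_that("select_mu equals exhaustive grid evaluation", {
  toy <- toy_training()
  val <- toy_training(seed = 6)
  y_val <- local({
    classes <- val$classes
    out <- matrix(0, nrow(val$fm$values), length(classes),
                  dimnames = list(NULL, classes))
    for (k in classes) out[, k] <- as.numeric(val$samples$label == k)
    out
  })
  expect_identical(as.numeric(select_mu(toy$fm, toy$samples, val$fm, y_val,
                                        grid = 3e-3)), 3e-3)

  grid <- c(5e-5, 1e-3, 5e-2)
  mu <- select_mu(toy$fm, toy$samples, val$fm, y_val, grid = grid)
  ## oracle: retrain per grid value independently and recompute the MSE
  mse_oracle <- vapply(grid, function(g) {
    m <- train_lasso(toy$fm, toy$samples, g, n_bootstrap = 1, seed = 1)
    sc <- predict_scores(m, val$fm)$scores
    mean((sc[, colnames(y_val)] - y_val)^2)
  }, numeric(1))
  expect_equal(attr(mu, "mse")$mse, mse_oracle, tolerance = 1e-12)
  expect_identical(as.numeric(mu), max(grid[mse_oracle <= min(mse_oracle) + 1e-15]))
})

test_that("score prediction anchors and equivariance", {
  toy <- toy_training()
  m <- train_lasso(toy$fm, toy$samples, 1e-4, n_bootstrap = 1, seed = 1)
  zero_fm <- feature_matrix(toy$fm$bin_mz,
                            matrix(0, 2, length(toy$fm$bin_mz)),
                            data.frame(dataset = "z", x = 1:2, y = 1L))
  sc <- predict_scores(m, zero_fm)$scores
  expect_equal(sc[1, ], m$intercepts, tolerance = 1e-12)

  ## pixel at a training centroid scores highest for its own class
  cen <- feature_matrix(toy$fm$bin_mz,
                        matrix(colMeans(as.matrix(
                          toy$fm$values[toy$samples$label == "class2", ])),
                          1, byrow = TRUE),
                        data.frame(dataset = "c", x = 1, y = 1))
  sc2 <- predict_scores(m, cen)$scores
  expect_identical(colnames(sc2)[which.max(sc2)], "class2")

  ## permuting pixels permutes score rows identically
  perm <- rev(seq_len(nrow(toy$fm$values)))
  fm_perm <- toy$fm
  fm_perm$values <- toy$fm$values[perm, ]
  fm_perm$pixels <- toy$fm$pixels[perm, ]
  expect_equal(predict_scores(m, fm_perm)$scores,
               predict_scores(m, toy$fm)$scores[perm, ])

  ## incompatible axes raise
  far <- feature_matrix(toy$fm$bin_mz + 50, as.matrix(toy$fm$values),
                        toy$fm$pixels)
  expect_error(predict_scores(m, far), "incompatible")
})

test_that("GMM fitting averages dataset models parameter-wise", {
  ## one dataset, two point masses per class: means equal those points
  sc1 <- rbind(c(0, 1), c(0, 1), c(1, 0), c(1, 0)) + 0
  colnames(sc1) <- c("A", "B")
  d1 <- list(scores = sc1, labels = c("B", "B", "A", "A"))
  g1 <- fit_gmm(list(d1))
  expect_equal(unname(g1$means$A), c(1, 0))
  expect_equal(unname(g1$means$B), c(0, 1))

  ## two datasets: averaged means
  sc2 <- sc1 + 0.5
  d2 <- list(scores = sc2, labels = c("B", "B", "A", "A"))
  g12 <- fit_gmm(list(d1, d2))
  expect_equal(unname(g12$means$A), c(1.25, 0.25))

  expect_error(fit_gmm(list(list(scores = sc1,
                                 labels = c("A", "A", "A", "A")))),
               "absent")
})

test_that("posterior gating: certainty, symmetry, thresholds", {
  classes <- c("A", "B")
  gmm <- structure(list(
    classes = classes,
    means = list(A = c(1, 0), B = c(0, 1)),
    covariances = list(A = diag(0.01, 2), B = diag(0.01, 2)),
    weights = c(A = 0.5, B = 0.5)), class = "gmm_model")
  sc <- rbind(c(1, 0), c(0.5, 0.5), c(0, 1))
  colnames(sc) <- classes
  maps <- structure(list(scores = sc, classes = classes,
                         pixels = data.frame(dataset = "d", x = 1:3, y = 1)),
                    class = "prediction_maps")
  out <- classify_pixels(maps, gmm, threshold = 0.95)
  expect_identical(out$assignment, c("A", "Uncertain", "B"))
  expect_equal(rowSums(out$posterior), rep(1, 3), tolerance = 1e-9)
  expect_gt(out$posterior[1, "A"], 0.999)
  ## exact symmetric midpoint: posterior 0.5 each
  expect_equal(unname(out$posterior[2, "A"]), 0.5, tolerance = 1e-12)
  ## threshold 0 leaves nothing Uncertain
  out0 <- classify_pixels(maps, gmm, threshold = 0)
  expect_false(any(out0$assignment == "Uncertain"))
})

test_that("evaluation computes the stated formulas and edge cases", {
  classes <- c("A", "B")
  mk_maps <- function(assignment) {
    structure(list(scores = matrix(0, length(assignment), 2,
                                   dimnames = list(NULL, classes)),
                   classes = classes, assignment = assignment,
                   posterior = NULL,
                   pixels = data.frame(dataset = "d",
                                       x = seq_along(assignment), y = 1)),
              class = "prediction_maps")
  }
  truth <- c(rep("A", 10), rep("B", 90))
  ## hand-built confusion for class A: TP=8, FN=2, FP=5, TN=85
  assign <- c(rep("A", 8), rep("B", 2), rep("A", 5), rep("B", 85))
  rep1 <- evaluate_predictions(mk_maps(assign), truth)
  a <- rep1[rep1$class == "A", ]
  expect_identical(c(a$TP, a$FP, a$TN, a$FN), c(8L, 5L, 85L, 2L))
  expect_equal(a$sensitivity, 80)
  expect_equal(a$specificity, 100 * 85 / 90, tolerance = 1e-9)

  perfect <- evaluate_predictions(mk_maps(truth), truth)
  expect_true(all(perfect$sensitivity == 100))
  expect_true(all(perfect$specificity == 100))

  ## Uncertain pixels are excluded from every count
  assign_u <- truth
  assign_u[1:5] <- "Uncertain"
  rep_u <- evaluate_predictions(mk_maps(assign_u), truth)
  expect_identical(attr(rep_u, "n_uncertain"), 5L)
  expect_identical(rep_u[rep_u$class == "A", "TP"], 5L)

  expect_error(evaluate_predictions(mk_maps(rep("Uncertain", 100)), truth),
               "no labelled")
})

test_that("model serialization round trips predictions exactly", {
  dir <- withr::local_tempdir()
  toy <- toy_training()
  m <- train_lasso(toy$fm, toy$samples, 1e-3, n_bootstrap = 2, seed = 3)
  sc <- predict_scores(m, toy$fm)$scores
  gmm <- fit_gmm(list(list(scores = sc, labels = toy$samples$label)))
  f <- file.path(dir, "model.json")
  write_model(m, gmm, f)
  back <- read_model(f)
  expect_equal(predict_scores(back$model, toy$fm)$scores, sc,
               tolerance = 1e-12)
  expect_equal(back$gmm$means, gmm$means, tolerance = 1e-12)
})
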