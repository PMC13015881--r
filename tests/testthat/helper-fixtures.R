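## Small shared fixtures, all generated in code.

## A compact signature library: 2 binders, 2 pigments (one carrying the iron
## cluster chemistry), Matrix; few ions so model fits stay fast.
tiny_library <- function(seed = 11, n_ions = 6) {
  signature_library(
    classes = data.frame(
      class = c("glue", "oil", "ochre", "ultramarine", "Matrix"),
      type = c("binder", "binder", "pigment", "pigment", "matrix")),
    metals = list(ochre = list(formula = "FeO4H5", adduct = "[M+H]+",
                               series_unit = "FeOOH", n_additions = 2,
                               n_losses = 2)),
    n_ions = n_ions, seed = seed)
}

tiny_bench <- function(seed = 11, lib = tiny_library(seed), ...) {
  generate_benchmark(lib, n_train = 2, n_validation = 1, n_test = 1,
                     grid = c(28, 36), seed = seed,
                     n_layers_range = c(2, 3), thickness_range = c(5, 7),
                     matrix_border = 3, ...)
}

## A two-layer noiseless section (no voids, no background, no noise):
## every in-layer pixel contains exactly the planted signature m/z set.
noiseless_section <- function(lib = tiny_library(), seed = 3) {
  cfg <- synth_config(
    grid = c(20, 24),
    layers = list(layer_spec(6, "glue", "ochre"),
                  layer_spec(6, "oil", "ultramarine")),
    matrix_border = 3, void_fraction = 0,
    noise = list(additive_sd = 0, multiplicative_sdlog = 0,
                 background_scale = 1),
    n_background_ions = 0, background_prob = 0, seed = seed)
  generate_dataset(cfg, lib, id = "noiseless")
}

mask_lookup_raster <- function(masks, label, type) {
  paintmsi:::mask_lookup(masks, label, type)$raster
}

## Tiny dense feature matrix for classifier unit tests: `k` well-separated
## classes, one perfectly informative binary ion per class plus noise ions.
toy_training <- function(n_per_class = 40, k = 3, n_noise = 5, seed = 5) {
  withr::with_seed(seed, {
    classes <- paste0("class", seq_len(k))
    labels <- rep(classes, each = n_per_class)
    n <- length(labels)
    X <- matrix(runif(n * (k + n_noise), 0, 1), n, k + n_noise)
    for (i in seq_len(k)) {
      X[, i] <- as.numeric(labels == classes[i])
    }
    fm <- feature_matrix(
      bin_mz = 100 + seq_len(k + n_noise),
      values = X,
      pixels = data.frame(dataset = "toy", x = seq_len(n), y = 1L))
    list(fm = fm, samples = data.frame(row = seq_len(n), label = labels),
         classes = classes)
  })
}
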