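# shared fixtures, built once per test run
fixture_env <- new.env(parent = emptyenv())

# default-design dataset (6400 spectra) after preprocessing
default_processed <- function() {
  if (is.null(fixture_env$pp))
    fixture_env$pp <- preprocess_pipeline(generate_dataset(design_config(seed = 1)))
  fixture_env$pp
}

default_gradients <- function() {
  if (is.null(fixture_env$gf))
    fixture_env$gf <- gradient_features(default_processed())
  fixture_env$gf
}

default_pca_scores <- function() {
  if (is.null(fixture_env$scores)) {
    model <- pca_fit(default_processed(), 40)
    fixture_env$pca_model <- model
    fixture_env$scores <- pca_transform(model, default_processed())
  }
  fixture_env$scores
}

# same design with every random-effect SD at zero (deterministic templates)
zero_noise_processed <- function() {
  if (is.null(fixture_env$pp0))
    fixture_env$pp0 <- preprocess_pipeline(
      generate_dataset(design_config(seed = 1),
                       default_tissue_profiles(noise_scale = 0)))
  fixture_env$pp0
}

# small noisy set for cheap smoke tests (400 spectra)
small_set <- function(seed = 7, noise_scale = 1) {
  generate_dataset(design_config(2, 1, 4, 2, seed = seed),
                   default_tissue_profiles(noise_scale))
}

# well-separated 2-D Gaussian blobs for classifier tests
make_blobs <- function(n_per = 30, K = 3, sep = 8, sd = 1, seed = 11) {
  set.seed(seed)
  centers <- cbind(sep * cos(2 * pi * seq_len(K) / K),
                   sep * sin(2 * pi * seq_len(K) / K))
  x <- do.call(rbind, lapply(seq_len(K), function(k)
    cbind(rnorm(n_per, centers[k, 1], sd), rnorm(n_per, centers[k, 2], sd))))
  list(x = x, y = factor(rep(LETTERS[seq_len(K)], each = n_per)))
}
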