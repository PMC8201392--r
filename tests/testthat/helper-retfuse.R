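# Shared fixtures, built once per test run. Heavy objects are memoised so
# independent test files can reuse them.

.fixtures <- new.env(parent = emptyenv())

# A small labelled dataset (32x32, 30 images/grade) and a model trained on
# it with a short schedule: enough signal for contract tests, cheap to fit.
small_data <- function() {
  if (is.null(.fixtures$small_data)) {
    .fixtures$small_data <- generate_dataset(
      30, synth_params(image_size = 32), seed = 101, test_frac = 1 / 3)
  }
  .fixtures$small_data
}

small_config <- function(seed = 101) {
  train_config(epochs = 4, learning_rate = 0.2, batch_size = 32,
               seed = seed)
}

small_model <- function() {
  if (is.null(.fixtures$small_model)) {
    .fixtures$small_model <- train_classifier(small_data(), small_config())
  }
  .fixtures$small_model
}

# Random affine multi-class classifier for attack oracles.
random_affine <- function(K, D, seed) {
  withr::with_seed(seed, {
    affine_classifier(matrix(rnorm(K * D), K, D), rnorm(K))
  })
}

# Random image in [0,1] of the given side (3 channels).
random_image <- function(side, seed) {
  withr::with_seed(seed, array(runif(side * side * 3), c(side, side, 3L)))
}

# Cross-entropy loss of a model at one image, via public predictions only.
model_loss <- function(model, image, label) {
  p <- predict_proba(model, image)
  -log(p[[label]])
}
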